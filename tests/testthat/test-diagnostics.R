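make_state <- function(grid, u = NULL, theta = NULL, phi = NULL, psi = NULL) {
  z <- matrix(0, grid$n_xi, grid$n_eta)
  s <- initial_state(grid)
  if (!is.null(u)) s$u <- matrix(rep(u, each = grid$n_xi), grid$n_xi, grid$n_eta)
  if (!is.null(theta)) s$theta <- matrix(rep(theta, each = grid$n_xi),
                                         grid$n_xi, grid$n_eta)
  if (!is.null(phi)) s$phi_c <- matrix(rep(phi, each = grid$n_xi),
                                       grid$n_xi, grid$n_eta)
  if (!is.null(psi)) s$psi <- matrix(rep(psi, each = grid$n_xi),
                                     grid$n_xi, grid$n_eta)
  s
}

test_that("skin friction matches direct substitution for the unit-mean parabola", {
  st <- straight_grid(21, 26)
  eta <- st$grid$eta
  p <- newtonian_params()
  co <- base_coeffs()
  s <- make_state(st$grid, u = 6 * eta * (1 - eta))
  cf <- skin_friction(s, st$metrics, st$grid, p, co, u_ref = 1)
  expect_equal(cf, rep(-6 / 800, 21), tolerance = 1e-12)
  expect_equal(skin_friction(s, st$metrics, st$grid, p, co, u_ref = 2),
               cf / 4, tolerance = 1e-12)
  s0 <- make_state(st$grid)
  expect_equal(skin_friction(s0, st$metrics, st$grid, p, co, 1), rep(0, 21))
  expect_error(skin_friction(s, st$metrics, st$grid, p, co, 0), "u_ref")
})

test_that("Nusselt and Sherwood numbers are exact on linear wall profiles", {
  st <- straight_grid(21, 26)
  eta <- st$grid$eta
  lin_state <- make_state(st$grid, theta = 1 - eta, phi = 1 - eta)
  p0 <- newtonian_params(Rd = 0)
  expect_equal(nusselt(lin_state, st$grid, base_coeffs(), p0), rep(1, 21),
               tolerance = 1e-12)
  # hybrid coefficients with radiation: Nu = c5 (1 + Rd)
  co <- mixture_coefficients()
  p <- flow_parameters()
  expect_equal(nusselt(lin_state, st$grid, co, p), rep(1.5242, 21),
               tolerance = 1e-4)
  expect_equal(sherwood(lin_state, st$metrics, st$grid), rep(1, 21),
               tolerance = 1e-12)
  # throat gap scaling on the constricted geometry: Dm(0) = 10/3
  spec <- geometry_spec()
  grid <- build_grid(spec, 201, 26)
  met <- build_metrics(grid, spec)
  s2 <- make_state(grid, phi = 1 - grid$eta)
  sh <- sherwood(s2, met, grid)
  expect_equal(sh[grid$xi == 0], 10 / 3, tolerance = 1e-12)
  # uniform scalars give zero transfer
  su <- make_state(st$grid, theta = rep(0.3, 26), phi = rep(0.3, 26))
  expect_equal(nusselt(su, st$grid, co, p), rep(0, 21))
  expect_equal(sherwood(su, st$metrics, st$grid), rep(0, 21))
})

test_that("wall shear stress is symmetric for symmetric flow and zero at rest", {
  st <- straight_grid(21, 26)
  p <- newtonian_params()
  co <- base_coeffs()
  s0 <- make_state(st$grid)
  w0 <- wall_shear_stress(s0, st$metrics, st$grid, p, co)
  expect_equal(w0$lower, rep(0, 21))
  # parabolic psi: both walls carry equal positive shear 6/(Re c3)
  eta <- st$grid$eta
  s <- make_state(st$grid, psi = eta^2 * (3 - 2 * eta))  # u = 6 eta (1-eta)
  w <- wall_shear_stress(s, st$metrics, st$grid, p, co)
  expect_equal(w$lower, rep(6 / 800, 21), tolerance = 1e-10)
  expect_equal(w$upper, w$lower, tolerance = 1e-10)
})

test_that("station profiles extract the nearest node column", {
  spec <- geometry_spec()
  grid <- build_grid(spec, 201, 26)
  s <- make_state(grid, u = 6 * grid$eta * (1 - grid$eta))
  pr <- extract_profile(s, grid, 0)
  expect_equal(attr(pr, "xi"), 0)
  expect_equal(pr$u, 6 * grid$eta * (1 - grid$eta))
  expect_equal(attr(extract_profile(s, grid, 2), "xi"), 2)
  expect_equal(attr(extract_profile(s, grid, 2.04), "xi"), 2)  # nearest node
  expect_error(extract_profile(s, grid, 15), "outside")
})

test_that("trend reports classify monotone sequences and reject bad input", {
  sw <- data.frame(M = c(0, 5, 10, 15), peak = c(1, 2, 3, 4))
  r <- trend_report(sw, "peak", "M", expected = "increasing")
  expect_identical(r$verdict, "increasing")
  expect_true(r$matches)
  sw$peak <- c(4, 3, 2, 1)
  expect_identical(trend_report(sw, "peak", "M")$verdict, "decreasing")
  sw$peak <- c(1, 3, 2, 4)
  r3 <- trend_report(sw, "peak", "M", expected = "increasing")
  expect_identical(r3$verdict, "non-monotone")
  expect_false(r3$matches)
  # order of rows must not matter
  expect_identical(trend_report(sw[c(3, 1, 4, 2), ], "peak", "M")$verdict,
                   "non-monotone")
  expect_error(trend_report(sw[1, , drop = FALSE], "peak", "M"), "two runs")
  expect_error(trend_report(sw, "nope", "M"), "nope")
  expect_error(trend_report(data.frame(M = c(1, 1), peak = c(1, 2)),
                            "peak", "M"), "distinct")
})
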