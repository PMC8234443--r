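test_that("tdma solves tridiagonal systems exactly", {
  expect_equal(tdma(0, 2, 0, 4), 2)
  n <- 20
  rhs <- rnorm(n)
  expect_equal(tdma(rep(0, n), rep(1, n), rep(0, n), rhs), rhs)
  set.seed(11)
  for (k in 1:10) {
    s <- random_dd_system(sample(2:50, 1))
    expect_equal(tdma(s$lower, s$diag, s$upper, s$rhs),
                 tridiag_dense_oracle(s$lower, s$diag, s$upper, s$rhs),
                 tolerance = 1e-12)
  }
  expect_error(tdma(c(0, 0), c(0, 1), c(0, 0), c(1, 1)), "pivot at row 1")
  expect_error(tdma(0, 1, 0, c(1, 2)), "length")
})

test_that("transformed Laplacian vanishes on linear/constant fields and is 2nd order", {
  st <- straight_grid(41, 21)
  fx <- matrix(rep(st$grid$xi, st$grid$n_eta), 41, 21)
  L <- transformed_laplacian(fx, st$metrics, st$grid)
  expect_equal(max(abs(L)), 0)
  # constant field, constricted metrics
  spec <- geometry_spec()
  grid <- build_grid(spec, 101, 26)
  met <- build_metrics(grid, spec)
  expect_equal(max(abs(transformed_laplacian(matrix(3, 101, 26), met, grid))), 0)
  # f = sin(pi eta): Laplacian -pi^2 sin(pi eta) to O(deta^2)
  errs <- vapply(c(21, 41), function(ny) {
    stn <- straight_grid(11, ny)
    f <- matrix(rep(sin(pi * stn$grid$eta), each = 11), 11, ny)
    L <- transformed_laplacian(f, stn$metrics, stn$grid)
    inner <- 2:(ny - 1)
    max(abs(L[5, inner] + pi^2 * sin(pi * stn$grid$eta[inner])))
  }, numeric(1))
  expect_equal(log2(errs[1] / errs[2]), 2, tolerance = 0.3)
})

test_that("Poisson solve reproduces the fully developed 1-D solution and zero", {
  # zero vorticity, zero boundary values -> zero field
  st <- straight_grid(41, 21)
  z <- matrix(0, 41, 21)
  sol <- solve_poisson_psi(z, z, st$metrics, st$grid)
  expect_equal(max(abs(sol$psi)), 0)
  # fully developed flow: omega = -u'(eta) replicated; psi cubic in eta is
  # an exact discrete solution, so the solver must recover it to tolerance
  co <- base_coeffs()
  ip <- inlet_profile(newtonian_params(), co, st$grid$eta, "paper_literal")
  omega <- matrix(rep(ip$omega, each = 41), 41, 21)
  psi0 <- matrix(0, 41, 21)
  psi0[1, ] <- ip$psi
  psi0[, 1] <- 0; psi0[, 21] <- ip$flux
  cfg <- solver_config(poisson_tol = 1e-10)
  sol2 <- solve_poisson_psi(omega, psi0, st$metrics, st$grid, cfg)
  expect_lt(max(abs(sol2$psi - matrix(rep(ip$psi, each = 41), 41, 21))), 1e-8)
  expect_lt(sol2$residual, 1e-10)
})

test_that("ADI transport of zero fields with zero boundaries stays exactly zero", {
  p <- flow_parameters()
  setup <- flow_setup(p, geometry_spec(), solver_config(dt = 5e-4),
                      n_xi = 51, n_eta = 16)
  z <- matrix(0, 51, 16)
  st0 <- initial_state(setup$grid)
  bc <- list(omega_in = rep(0, 16), omega_low = rep(0, 51),
             omega_up = rep(0, 51))
  om <- advance_omega(st0, setup$metrics, setup$grid, p, setup$coeffs,
                      setup$cfg, bc)
  expect_identical(max(abs(om)), 0)
})

test_that("porous drag alone decays vorticity like the exact exponential", {
  p <- suppressWarnings(flow_parameters(M = 0, Da = 0.002, eps = 0))
  cfg <- solver_config(dt = 5e-4, porous_vorticity_sign = -1)
  st <- straight_grid(31, 16)
  co <- mixture_coefficients()
  lam <- -p$Re * p$Da^2
  omega <- matrix(1, 31, 16)
  state <- list(psi = matrix(0, 31, 16), omega = omega,
                u = matrix(0, 31, 16), v = matrix(0, 31, 16))
  n_steps <- 200
  for (l in seq_len(n_steps)) {
    ex <- exp(lam * l * cfg$dt / p$St)
    bc <- list(omega_in = rep(ex, 16), omega_low = rep(ex, 31),
               omega_up = rep(ex, 31))
    state$omega <- advance_omega(state, st$metrics, st$grid, p, co, cfg, bc)
  }
  exact <- exp(lam * n_steps * cfg$dt / p$St)
  expect_lt(max(abs(state$omega - exact)), 1e-6 * exact)
})

test_that("a passive blob advects at the imposed uniform speed", {
  # uniform u in a straight channel; track the vorticity blob's centroid
  st <- straight_grid(201, 11)
  grid <- st$grid
  p <- suppressWarnings(flow_parameters(M = 0, Da = 0, eps = 0))
  co <- base_coeffs()
  cfg <- solver_config(dt = 1e-3)
  U0 <- 0.05
  blob <- exp(-((grid$xi + 5) / 0.8)^2)
  state <- list(psi = matrix(0, 201, 11),
                omega = outer(blob, rep(1, 11)),
                u = matrix(U0, 201, 11), v = matrix(0, 201, 11))
  zero_bc <- list(omega_in = rep(0, 11), omega_low = rep(0, 201),
                  omega_up = rep(0, 201))
  n_steps <- 400
  for (l in seq_len(n_steps))
    state$omega <- advance_omega(state, st$metrics, grid, p, co, cfg, zero_bc)
  mid <- state$omega[, 6]
  centroid <- sum(grid$xi * mid) / sum(mid)
  expect_equal(centroid, -5 + U0 * n_steps * cfg$dt / p$St, tolerance = 0.02)
})

test_that("pure conduction is a fixed point of the temperature step", {
  p <- flow_parameters()
  setup <- flow_setup(p, geometry_spec(h1 = 0, h2 = 0),
                      solver_config(dt = 5e-4), n_xi = 41, n_eta = 21)
  lin <- 1 - setup$grid$eta
  theta <- matrix(rep(lin, each = 41), 41, 21)
  state <- initial_state(setup$grid)
  state$theta <- theta
  bc <- list(theta_in = lin, theta_low = rep(1, 41), theta_up = rep(0, 41))
  for (l in 1:20)
    state$theta <- advance_theta(state, setup$metrics, setup$grid, p,
                                 setup$coeffs, setup$cfg, bc)
  expect_lt(max(abs(state$theta - theta)), 1e-12)
})

test_that("concentration relaxes to conduction with a linear Soret-free state", {
  p <- flow_parameters()   # Sr > 0; linear theta has zero Laplacian
  setup <- flow_setup(p, geometry_spec(h1 = 0, h2 = 0),
                      solver_config(dt = 5e-3), n_xi = 31, n_eta = 21)
  lin <- 1 - setup$grid$eta
  theta <- matrix(rep(lin, each = 31), 31, 21)
  state <- initial_state(setup$grid)
  state$theta <- theta
  state$phi_c <- matrix(rep(lin, each = 31), 31, 21) +
    0.2 * matrix(rep(sin(pi * setup$grid$eta), each = 31), 31, 21)
  bc <- list(phi_in = lin, phi_low = rep(1, 31), phi_up = rep(0, 31))
  for (l in 1:4000)
    state$phi_c <- advance_phi(state, setup$metrics, setup$grid, p,
                               setup$coeffs, setup$cfg, bc, theta)
  expect_lt(max(abs(state$phi_c - matrix(rep(lin, each = 31), 31, 21))), 1e-3)
  # spatially constant theta: Soret source is exactly zero
  S <- transformed_laplacian(matrix(0.7, 31, 21), setup$metrics, setup$grid)
  expect_equal(max(abs(S)), 0)
})

test_that("velocities recover exact fields from the stream function", {
  st <- straight_grid(31, 21)
  psi <- matrix(rep(st$grid$eta, each = 31), 31, 21)
  v <- velocity_from_psi(psi, st$metrics, st$grid)
  expect_equal(v$u, matrix(1, 31, 21), tolerance = 1e-12)
  expect_equal(v$v, matrix(0, 31, 21), tolerance = 1e-12)
  # xi-independent psi gives zero transverse velocity
  psi2 <- matrix(rep(sin(pi * st$grid$eta), each = 31), 31, 21)
  expect_equal(max(abs(velocity_from_psi(psi2, st$metrics, st$grid)$v)), 0)
})

test_that("a full time step is deterministic and preserves the quiescent state", {
  p <- flow_parameters()
  setup <- flow_setup(p, geometry_spec(),
                      solver_config(dt = 5e-4, n_cycles = 1),
                      n_xi = 101, n_eta = 16)
  s1 <- initial_state(setup$grid)
  s2 <- initial_state(setup$grid)
  for (l in 1:10) {
    s1 <- time_step(s1, setup)
    s2 <- time_step(s2, setup)
  }
  expect_identical(s1$psi, s2$psi)
  expect_identical(s1$omega, s2$omega)
  expect_identical(s1$phi_c, s2$phi_c)
})
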