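test_that("Poiseuille-limit inlet profile matches the classical closed forms", {
  eta <- seq(0, 1, 0.02)
  co <- base_coeffs()
  # Newtonian base fluid: g = 1
  pN <- newtonian_params()
  ip <- inlet_profile(pN, co, eta, mode = "paper_literal")
  expect_equal(ip$g, 1)
  expect_equal(ip$psi, (1 / 6) * (3 * eta^2 - 2 * eta^3), tolerance = 1e-12)
  expect_equal(ip$flux, 1 / 6, tolerance = 1e-12)
  expect_equal(ip$u[eta == 0.5], 0.25, tolerance = 1e-12)
  # Casson, particle-free: flux 1/(6g) with g = 1 + 1/beta
  pC <- suppressWarnings(flow_parameters(M = 0, Da = 0, beta = 0.5,
                                         phi1 = 0, phi2 = 0))
  ipC <- inlet_profile(pC, co, eta, mode = "paper_literal")
  expect_equal(ipC$flux, 1 / (6 * 3), tolerance = 1e-12)
  # unit-flux normalization: parabola with unit mean speed
  ipU <- inlet_profile(pN, co, eta, mode = "unit_flux")
  expect_equal(ipU$u, 6 * eta * (1 - eta), tolerance = 1e-12)
  expect_equal(ipU$flux, 1, tolerance = 1e-12)
})

test_that("hyperbolic inlet solution matches a fourth-order BVP oracle", {
  eta <- seq(0, 1, length.out = 1001)
  co <- mixture_coefficients()
  for (M in c(0, 5, 15)) for (Da in c(0, 0.008)) {
    p <- suppressWarnings(flow_parameters(M = M, Da = Da))
    ip <- inlet_profile(p, co, eta, mode = "paper_literal")
    g <- co$c2 * (1 + 1 / p$beta)
    M1sq <- M^2 + co$c1 * p$Re^2 * Da^2
    orc <- bvp_inlet_oracle(g, M1sq, -2, n = 1001)
    expect_lt(max(abs(ip$u - orc$u)), 1e-8)
  }
})

test_that("hyperbolic solution degenerates smoothly to the cubic as M1 -> 0", {
  eta <- seq(0, 1, 0.01)
  co <- base_coeffs()
  p0 <- newtonian_params()
  base <- inlet_profile(p0, co, eta, mode = "paper_literal")
  for (M in c(1e-4, 1e-2, 0.1)) {
    pM <- suppressWarnings(flow_parameters(M = M, Da = 0, beta = Inf,
                                           phi1 = 0, phi2 = 0, eps = 0))
    ipM <- inlet_profile(pM, co, eta, mode = "paper_literal")
    expect_lt(max(abs(ipM$u - base$u)), max(1e-8, M^2))
  }
  # the small-M1 series branch agrees with the dense BVP oracle
  pm <- suppressWarnings(flow_parameters(M = 5e-3, Da = 0, beta = Inf,
                                         phi1 = 0, phi2 = 0, eps = 0))
  eta2 <- seq(0, 1, length.out = 2001)
  us <- inlet_profile(pm, co, eta2, "paper_literal")$u
  orc <- bvp_inlet_oracle(1, (5e-3)^2, -2, n = 2001)
  expect_lt(max(abs(us - orc$u)), 1e-10)
})

test_that("inlet velocity integrates to the stream-function flux", {
  eta <- seq(0, 1, length.out = 201)
  co <- mixture_coefficients()
  p <- flow_parameters()
  ip <- inlet_profile(p, co, eta)
  expect_equal(ip$psi[length(eta)] - ip$psi[1], ip$flux, tolerance = 1e-14)
  w <- rep(1, length(eta)); w[c(1, length(eta))] <- 0.5
  quad <- sum(ip$u * w) * (eta[2] - eta[1])
  expect_equal(quad, ip$flux, tolerance = 1e-4)
})

test_that("pulsation factor hits the cycle landmarks", {
  expect_equal(pulsation_factor(0, 1), 1)
  expect_equal(pulsation_factor(0.25, 1), 2)
  expect_equal(pulsation_factor(0.75, 1), 0)
  expect_equal(pulsation_factor(0.6, 0), 1)
  expect_error(pulsation_factor(0.1, 1.5), "eps")
})

test_that("wall vorticity closure reproduces exact quadratics", {
  st <- straight_grid(11, 26)
  ny <- st$grid$n_eta
  psi0 <- matrix(0, 11, ny)
  expect_equal(wall_vorticity(psi0, st$metrics, st$grid)$lower, rep(0, 11))
  # psi = eta^2 near the lower wall: second derivative exactly 2
  psi <- matrix(rep(st$grid$eta^2, each = 11), 11, ny)
  wv <- wall_vorticity(psi, st$metrics, st$grid)
  expect_equal(wv$lower, rep(-2, 11), tolerance = 1e-10)
  # gap-width scaling: Dm = 2 doubles the metric factor to Dm^2 = 4
  m2 <- st$metrics
  m2$Dm <- rep(2, 11)
  expect_equal(wall_vorticity(psi, m2, st$grid)$lower, rep(-8, 11),
               tolerance = 1e-10)
})

test_that("wall vorticity closure is second-order accurate", {
  # trig field with no-slip-compatible wall behaviour: psi = 1 - cos(pi eta)
  err <- vapply(c(26, 51, 101), function(ny) {
    st <- straight_grid(5, ny)
    psi <- matrix(rep(1 - cos(pi * st$grid$eta), each = 5), 5, ny)
    wv <- wall_vorticity(psi, st$metrics, st$grid)
    abs(wv$lower[3] - (-pi^2))   # analytic psi''(0) = pi^2, Dm = 1
  }, numeric(1))
  orders <- log2(err[-3] / err[-1])
  expect_true(all(orders > 1.7 & orders < 2.3))
})

test_that("scalar walls, outflow copy and initial state follow the contracts", {
  st <- straight_grid(11, 6)
  w <- scalar_wall_values(st$grid)
  expect_equal(w$theta_lower, rep(1, 11))
  expect_equal(w$phi_upper, rep(0, 11))
  f <- matrix(seq_len(66) / 10, 11, 6)
  g1 <- apply_outflow(f)
  expect_equal(g1[11, ], g1[10, ])
  expect_equal(apply_outflow(g1), g1)   # idempotent
  expect_equal(apply_outflow(matrix(2, 4, 3)), matrix(2, 4, 3))
  s <- initial_state(st$grid)
  expect_true(all(s$psi == 0) && all(s$omega == 0) && all(s$theta == 0) &&
                all(s$phi_c == 0) && all(s$u == 0) && all(s$v == 0))
  expect_identical(s$t, 0)
})
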