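# Independent numerical oracles used across the suite.

# Fourth-order (Numerov) dense solve of the inlet boundary-value problem
#   g u'' - M1sq u = G,  u(0) = u(1) = 0
# on n nodes. Independent of the package's closed-form solution path.
bvp_inlet_oracle <- function(g, M1sq, G, n = 1001) {
  eta <- seq(0, 1, length.out = n)
  h <- eta[2] - eta[1]
  m <- n - 2
  # u'' = f, f = (M1sq u + G) / g ; Numerov:
  # u_{k-1} - 2 u_k + u_{k+1} = (h^2/12)(f_{k-1} + 10 f_k + f_{k+1})
  c1 <- M1sq * h^2 / (12 * g)
  A <- matrix(0, m, m)
  rhs <- rep(G * h^2 / g, m)   # (h^2/12) * 12 G / g
  for (k in seq_len(m)) {
    A[k, k] <- -2 - 10 * c1
    if (k > 1) A[k, k - 1] <- 1 - c1
    if (k < m) A[k, k + 1] <- 1 - c1
  }
  list(eta = eta, u = c(0, solve(A, rhs), 0))
}

# Dense linear-algebra solve of a tridiagonal system (oracle for tdma).
tridiag_dense_oracle <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  A <- matrix(0, n, n)
  for (k in seq_len(n)) {
    A[k, k] <- diag[k]
    if (k > 1) A[k, k - 1] <- lower[k]
    if (k < n) A[k, k + 1] <- upper[k]
  }
  solve(A, rhs)
}

# Random diagonally dominant tridiagonal system.
random_dd_system <- function(n) {
  lower <- c(0, runif(n - 1, -1, 1))
  upper <- c(runif(n - 1, -1, 1), 0)
  diag <- abs(lower) + abs(upper) + runif(n, 0.5, 2)
  rhs <- runif(n, -5, 5)
  list(lower = lower, diag = diag, upper = upper, rhs = rhs)
}

# Small straight-channel setup helpers.
straight_grid <- function(n_xi = 41, n_eta = 21) {
  spec <- geometry_spec(h1 = 0, h2 = 0)
  grid <- build_grid(spec, n_xi, n_eta)
  list(spec = spec, grid = grid, metrics = build_metrics(grid, spec))
}

newtonian_params <- function(...) {
  suppressWarnings(flow_parameters(M = 0, Da = 0, beta = Inf,
                                   phi1 = 0, phi2 = 0, eps = 0, ...))
}

base_coeffs <- function() mixture_coefficients(phi1 = 0, phi2 = 0)
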