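#' Steady fully developed inlet profile
#'
#' Solves the constant-coefficient two-point boundary-value problem for the
#' fully developed axial velocity at the channel inlet,
#' `g u'' - M1^2 u = G`, `u(0) = u(1) = 0`, with `g = c2 (1 + 1/beta)` the
#' effective Casson viscosity factor and `M1^2 = M^2 + c1 Re^2 Da^2` the
#' combined magnetic/porous drag scale. The solution is closed-form: a
#' hyperbolic (Hartmann-type) profile for `M1 > 0` that degenerates to the
#' plane Poiseuille parabola as `M1 -> 0` (a series expansion is used for
#' small `M1/sqrt(g)` to avoid cancellation).
#'
#' Two normalizations of the pressure-gradient constant `G` are available:
#' `"paper_literal"` (default) fixes `G = -2`, which reproduces the
#' classical `psi = (1/(6g))(3 eta^2 - 2 eta^3)` profile in the `M1 = 0`
#' limit (the inlet flux is then `1/(6g)` and depends on `beta`, the drag
#' scale `M1` and the volume fractions); `"unit_flux"` rescales `G` so the
#' steady mean inlet speed is 1. The default keeps the flow in the gently
#' convective regime where the pulsatile solution locks onto a periodic
#' cycle; at unit mean speed the effective Reynolds number is two orders
#' of magnitude larger and the constricted flow is aperiodic on practical
#' grids.
#'
#' @param params a [flow_parameters()] object.
#' @param coeffs a [mixture_coefficients()] object.
#' @param eta vector of wall-normal node coordinates in `[0, 1]`.
#' @param mode normalization mode, `"paper_literal"` or `"unit_flux"`.
#' @return An object of class `inlet_profile`: vectors `u`, `du` (du/deta),
#'   `psi`, `omega` (= -du, the fully developed vorticity), scalars `flux`,
#'   `G`, `g`, `M1`, and the mode.
#' @examples
#' ip <- inlet_profile(flow_parameters(M = 0, Da = 0, phi1 = 0, phi2 = 0),
#'                     mixture_coefficients(phi1 = 0, phi2 = 0),
#'                     seq(0, 1, 0.02), mode = "unit_flux")
#' max(abs(ip$u - 6 * ip$eta * (1 - ip$eta)))   # parabola with unit mean
#' @export
inlet_profile <- function(params, coeffs, eta,
                          mode = c("paper_literal", "unit_flux")) {
  mode <- match.arg(mode)
  g <- coeffs$c2 * (1 + 1 / params$beta)
  M1sq <- params$M^2 + coeffs$c1 * params$Re^2 * params$Da^2
  m <- sqrt(M1sq) / sqrt(g)
  prof <- function(G) hartmann_profile(G, g, m, eta)
  G <- -2
  p <- prof(G)
  if (mode == "unit_flux") {
    G <- -2 / p$flux          # flux is linear in G
    p <- prof(G)
  }
  structure(list(eta = eta, u = p$u, du = p$du, psi = p$psi,
                 omega = -p$du, flux = p$flux, G = G, g = g,
                 M1 = sqrt(M1sq), mode = mode),
            class = "inlet_profile")
}

# Closed-form solution of g u'' - (g m^2) u = G with no-slip at eta = 0, 1.
# For m below a threshold the series expansion in m^2 about the Poiseuille
# parabola is used (the direct hyperbolic form loses precision to
# cancellation as m -> 0).
hartmann_profile <- function(G, g, m, eta) {
  x <- eta - 0.5
  if (m > 1e-2) {
    M1sq <- g * m^2
    ch <- cosh(m / 2)
    u <- (G / M1sq) * (cosh(m * x) / ch - 1)
    du <- (G * m / M1sq) * sinh(m * x) / ch
    psi <- (G / M1sq) * ((sinh(m * x) + sinh(m / 2)) / (m * ch) - eta)
    flux <- (G / M1sq) * ((2 / m) * tanh(m / 2) - 1)
  } else {
    m2 <- m^2
    u <- (G / g) * ((x^2 / 2 - 1 / 8) + m2 * (x^4 / 24 - x^2 / 16 + 5 / 384))
    du <- (G / g) * (x + m2 * (x^3 / 6 - x / 8))
    psi <- (G / g) * ((x^3 / 6 - x / 8 - 1 / 24) +
                        m2 * (x^5 / 120 - x^3 / 48 + 5 * x / 384 + 1 / 240))
    flux <- (G / g) * (-1 / 12 + m2 / 120)
  }
  list(u = u, du = du, psi = psi, flux = flux)
}

#' Sinusoidal pulsation factor
#'
#' The instantaneous flow-rate multiplier `1 + eps sin(2 pi t)` applied to
#' the steady inlet profile; the pulse cycle has period 1, peak flow at
#' `t = 0.25` and zero instantaneous flow (for `eps = 1`) at `t = 0.75`.
#'
#' @param t cycle time (any real; only the fractional phase matters).
#' @param eps pulsation amplitude in `[0, 1]`.
#' @export
pulsation_factor <- function(t, eps = 1) {
  if (any(eps < 0) || any(eps > 1)) stop("pulsation_factor: eps must lie in [0, 1]")
  1 + eps * sin(2 * pi * t)
}

#' Wall vorticity closure
#'
#' Evaluates the no-slip wall vorticity `omega = -(Qm^2 + Dm^2)
#' d2psi/deta2` at both walls, with the second derivative from the
#' one-sided second-order three-point formula that uses the no-slip
#' condition `dpsi/deta = 0` at the wall:
#' `psi'' ~ (8 psi_2 - psi_3 - 7 psi_w) / (2 deta^2)`.
#'
#' @param psi stream-function matrix (`n_xi x n_eta`).
#' @param metrics a [build_metrics()] result.
#' @param grid the matching [build_grid()] result.
#' @return A list with vectors `lower` and `upper` over `xi`.
#' @export
wall_vorticity <- function(psi, metrics, grid) {
  ny <- grid$n_eta
  h2 <- 2 * grid$d_eta^2
  d2_low <- (8 * psi[, 2] - psi[, 3] - 7 * psi[, 1]) / h2
  d2_up  <- (8 * psi[, ny - 1] - psi[, ny - 2] - 7 * psi[, ny]) / h2
  list(lower = -(metrics$Qm[, 1]^2 + metrics$Dm^2) * d2_low,
       upper = -(metrics$Qm[, ny]^2 + metrics$Dm^2) * d2_up)
}

#' Scalar wall values
#'
#' Dirichlet wall values for the temperature and concentration: the lower
#' wall (`eta = 0`) is held at `theta = phi = 1` (heated/solute-rich), the
#' upper wall at 0, at all axial stations and times.
#'
#' @param grid a [build_grid()] result.
#' @return A list of four vectors over `xi`: `theta_lower`, `theta_upper`,
#'   `phi_lower`, `phi_upper`.
#' @export
scalar_wall_values <- function(grid) {
  ones <- rep(1, grid$n_xi); zeros <- rep(0, grid$n_xi)
  list(theta_lower = ones, theta_upper = zeros,
       phi_lower = ones, phi_upper = zeros)
}

#' Zero-gradient outflow condition
#'
#' Copies the penultimate axial column into the last one (fully developed
#' outflow, zero axial gradient); idempotent.
#'
#' @param field matrix (`n_xi x n_eta`).
#' @export
apply_outflow <- function(field) {
  field[nrow(field), ] <- field[nrow(field) - 1, ]
  field
}

#' Quiescent initial state
#'
#' All fields (`psi`, `omega`, `theta`, `phi_c`, `u`, `v`) identically zero
#' at `t = 0`; the boundary values switch on impulsively at the first step.
#'
#' @param grid a [build_grid()] result.
#' @return An object of class `field_state`.
#' @export
initial_state <- function(grid) {
  z <- matrix(0, grid$n_xi, grid$n_eta)
  structure(list(psi = z, omega = z, theta = z, phi_c = z, u = z, v = z,
                 t = 0),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("Field state at t = %g (%d x %d nodes)\n",
              x$t, nrow(x$psi), ncol(x$psi)))
  cat(sprintf("  max|psi| = %.4g, max|omega| = %.4g, theta in [%.3g, %.3g]\n",
              max(abs(x$psi)), max(abs(x$omega)),
              min(x$theta), max(x$theta)))
  invisible(x)
}
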