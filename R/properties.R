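#' Thermophysical constants of the base fluid and nanoparticle species
#'
#' Container for the material constants entering the nanofluid mixture
#' models: densities, specific heats and thermal conductivities of the base
#' fluid (water) and of the two nanoparticle species (species 1 = Cu,
#' species 2 = SWCNT), plus the kinematic viscosity of the base fluid.
#' Defaults are the standard room-temperature reference values for
#' water / Cu / SWCNT.
#'
#' @param rho_f,rho_s1,rho_s2 densities (kg/m^3).
#' @param cp_f,cp_s1,cp_s2 specific heats (J/(kg K)).
#' @param k_f,k_s1,k_s2 thermal conductivities (W/(m K)).
#' @param nu_f kinematic viscosity of the base fluid (m^2/s).
#' @return An object of class `material_table`.
#' @examples
#' material_table()
#' @export
material_table <- function(rho_f = 997.1, rho_s1 = 8933, rho_s2 = 10500,
                           cp_f = 4179, cp_s1 = 385, cp_s2 = 235,
                           k_f = 0.613, k_s1 = 401, k_s2 = 429,
                           nu_f = 9.009e-7) {
  mat <- list(rho_f = rho_f, rho_s1 = rho_s1, rho_s2 = rho_s2,
              cp_f = cp_f, cp_s1 = cp_s1, cp_s2 = cp_s2,
              k_f = k_f, k_s1 = k_s1, k_s2 = k_s2, nu_f = nu_f)
  for (nm in names(mat)) {
    v <- mat[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("material_table: field '", nm, "' must be a single positive number")
  }
  structure(mat, class = "material_table")
}

#' @export
print.material_table <- function(x, ...) {
  cat("Material table (base fluid / species 1 / species 2)\n")
  cat(sprintf("  rho (kg/m^3): %g / %g / %g\n", x$rho_f, x$rho_s1, x$rho_s2))
  cat(sprintf("  cp  (J/kgK) : %g / %g / %g\n", x$cp_f, x$cp_s1, x$cp_s2))
  cat(sprintf("  k   (W/mK)  : %g / %g / %g\n", x$k_f, x$k_s1, x$k_s2))
  cat(sprintf("  nu_f (m^2/s): %g\n", x$nu_f))
  invisible(x)
}

check_fractions <- function(phi1, phi2) {
  if (!is.numeric(phi1) || !is.numeric(phi2) ||
      any(!is.finite(c(phi1, phi2))))
    stop("volume fractions must be finite numbers")
  if (any(phi1 < 0) || any(phi2 < 0) || any(phi1 >= 1) || any(phi2 >= 1))
    stop("volume fractions must satisfy 0 <= phi < 1")
  invisible(TRUE)
}

#' Effective density coefficient of the hybrid mixture
#'
#' Ratio of the effective nanofluid density to the base-fluid density under
#' the two-stage volumetric mixture rule,
#' `(1 - phi2) * ((1 - phi1) + phi1 * rho_s1/rho_f) + phi2 * rho_s2/rho_f`.
#'
#' @param mat a [material_table()].
#' @param phi1,phi2 nanoparticle volume fractions (species 1, species 2).
#' @return Dimensionless density ratio (1 for the pure base fluid).
#' @export
density_coeff <- function(mat, phi1, phi2) {
  check_fractions(phi1, phi2)
  (1 - phi2) * ((1 - phi1) + phi1 * mat$rho_s1 / mat$rho_f) +
    phi2 * mat$rho_s2 / mat$rho_f
}

#' Effective viscosity coefficient of the hybrid mixture
#'
#' Brinkman-type ratio of the effective dynamic viscosity to the base-fluid
#' viscosity, `1 / ((1 - phi1)^2.5 * (1 - phi2)^2.5)`.
#'
#' @inheritParams density_coeff
#' @return Dimensionless viscosity ratio (>= 1).
#' @export
viscosity_coeff <- function(phi1, phi2) {
  check_fractions(phi1, phi2)
  1 / ((1 - phi1)^2.5 * (1 - phi2)^2.5)
}

#' Momentum coefficient: density over viscosity ratio
#'
#' The combination `c1 / c2` that scales the viscous diffusion term of the
#' vorticity equation.
#'
#' @param c1 density coefficient (see [density_coeff()]).
#' @param c2 viscosity coefficient (see [viscosity_coeff()]).
#' @export
momentum_coeff <- function(c1, c2) {
  if (any(c1 <= 0) || any(c2 <= 0)) stop("momentum_coeff: c1 and c2 must be positive")
  c1 / c2
}

#' Effective heat-capacity coefficient of the hybrid mixture
#'
#' Ratio of the effective volumetric heat capacity `(rho cp)` to that of the
#' base fluid, under the same two-stage volumetric rule as the density.
#'
#' @inheritParams density_coeff
#' @export
heat_capacity_coeff <- function(mat, phi1, phi2) {
  check_fractions(phi1, phi2)
  rc_f <- mat$rho_f * mat$cp_f
  (1 - phi2) * ((1 - phi1) + phi1 * mat$rho_s1 * mat$cp_s1 / rc_f) +
    phi2 * mat$rho_s2 * mat$cp_s2 / rc_f
}

maxwell_ratio <- function(ks, kf, phi, classic = FALSE) {
  if (any(c(ks, kf) <= 0)) stop("conductivity_coeff: conductivities must be positive")
  den_phi <- if (classic) phi else 2 * phi
  (ks + 2 * kf - 2 * phi * (kf - ks)) / (ks + 2 * kf + den_phi * (kf - ks))
}

#' Effective thermal-conductivity coefficient (two-step Maxwell chain)
#'
#' Sequential Maxwell mixture model: species 1 is first dispersed in the
#' base fluid giving the mono-nanofluid ratio `knf/kf`, then species 2 is
#' dispersed in that mono nanofluid. The hybrid ratio `c5 = khnf/kf` is the
#' product of the two stages. By default both the numerator and the
#' denominator of each stage carry the factor `2 phi`; `maxwell_classic =
#' TRUE` switches the denominator to the textbook Maxwell-Garnett factor
#' `phi` for comparison.
#'
#' @inheritParams density_coeff
#' @param maxwell_classic use the classical Maxwell-Garnett denominator.
#' @return A list with `knf_over_kf` (mono stage) and `c5` (hybrid ratio).
#' @export
conductivity_coeff <- function(mat, phi1, phi2, maxwell_classic = FALSE) {
  check_fractions(phi1, phi2)
  knf_over_kf <- maxwell_ratio(mat$k_s1, mat$k_f, phi1, maxwell_classic)
  knf <- knf_over_kf * mat$k_f
  khnf_over_knf <- maxwell_ratio(mat$k_s2, knf, phi2, maxwell_classic)
  list(knf_over_kf = knf_over_kf, c5 = knf_over_kf * khnf_over_knf)
}

#' All effective mixture coefficients of the nanofluid
#'
#' Computes the five dimensionless coefficients scaling the governing
#' equations: `c1` (density), `c2` (viscosity), `c3 = c1/c2` (momentum),
#' `c4` (heat capacity) and `c5` (thermal conductivity, two-step Maxwell
#' chain), plus the intermediate mono-nanofluid conductivity ratio.
#' All coefficients equal 1 for the pure base fluid.
#'
#' @inheritParams conductivity_coeff
#' @return An object of class `mixture_coefficients`.
#' @examples
#' mixture_coefficients(material_table(), 0.03, 0.03)
#' @export
mixture_coefficients <- function(mat = material_table(), phi1 = 0.03,
                                 phi2 = 0.03, maxwell_classic = FALSE) {
  check_fractions(phi1, phi2)
  c1 <- density_coeff(mat, phi1, phi2)
  c2 <- viscosity_coeff(phi1, phi2)
  kk <- conductivity_coeff(mat, phi1, phi2, maxwell_classic)
  structure(list(c1 = c1, c2 = c2, c3 = momentum_coeff(c1, c2),
                 c4 = heat_capacity_coeff(mat, phi1, phi2),
                 c5 = kk$c5, knf_over_kf = kk$knf_over_kf,
                 phi1 = phi1, phi2 = phi2),
            class = "mixture_coefficients")
}

#' @export
print.mixture_coefficients <- function(x, ...) {
  cat(sprintf("Mixture coefficients (phi1 = %g, phi2 = %g)\n", x$phi1, x$phi2))
  cat(sprintf("  density     c1 = %.6f\n", x$c1))
  cat(sprintf("  viscosity   c2 = %.6f\n", x$c2))
  cat(sprintf("  momentum    c3 = %.6f\n", x$c3))
  cat(sprintf("  heat cap.   c4 = %.6f\n", x$c4))
  cat(sprintf("  conduct.    c5 = %.6f (mono stage %.6f)\n", x$c5, x$knf_over_kf))
  invisible(x)
}

# Parameter ranges exercised by the one-factor studies; values outside these
# are legal but trigger a warning from validate_parameters().
.swept_ranges <- list(Re = c(800, 1400), St = c(0.02, 0.08), M = c(0, 15),
                      Da = c(0, 0.008), beta = c(0.5, 2), Rd = c(0.2, 1.4),
                      Peh = c(210, 630), Pem = c(220, 620), Sr = c(0.8, 2.5),
                      phi1 = c(0, 0.09), phi2 = c(0, 0.09))

#' Dimensionless flow parameters
#'
#' Bundles the dimensionless groups governing the pulsatile channel flow:
#' Reynolds `Re`, Strouhal `St` (pulsation frequency), Hartmann `M`
#' (magnetic drag), Darcy `Da` (porous drag enters as `Re Da^2`), Casson
#' `beta` (viscous terms scale with `1 + 1/beta`), radiation `Rd`, heat and
#' mass Peclet numbers `Peh = Pr Re`, `Pem = Sc Re`, Soret `Sr`, pulsation
#' amplitude `eps` (0 steady, 1 fully pulsatile) and nanoparticle volume
#' fractions `phi1` (Cu), `phi2` (SWCNT). Defaults are the baseline study
#' conditions.
#'
#' @param Re,St,M,Da,beta,Rd,Peh,Pem,Sr dimensionless groups.
#' @param eps pulsation amplitude in `[0, 1]`.
#' @param phi1,phi2 nanoparticle volume fractions in `[0, 1)`.
#' @return A validated object of class `flow_parameters`.
#' @examples
#' flow_parameters()                 # baseline conditions
#' flow_parameters(M = 0, eps = 0)   # steady, non-magnetic
#' @export
flow_parameters <- function(Re = 800, St = 0.02, M = 5, Da = 0.002,
                            beta = 0.5, Rd = 0.2, Peh = 490, Pem = 420,
                            Sr = 0.8, eps = 1, phi1 = 0.03, phi2 = 0.03) {
  p <- structure(list(Re = Re, St = St, M = M, Da = Da, beta = beta, Rd = Rd,
                      Peh = Peh, Pem = Pem, Sr = Sr, eps = eps,
                      phi1 = phi1, phi2 = phi2),
                 class = "flow_parameters")
  validate_parameters(p)
}

#' Validate a set of flow parameters
#'
#' Enforces the invariants of the dimensionless parameter set (`Re > 0`,
#' `beta > 0`, `Da >= 0`, `M >= 0`, `Peh > 0`, `Pem > 0`, `0 <= phi < 1`,
#' `eps` in `[0, 1]`) and warns when a value leaves the ranges exercised by
#' the standard one-factor studies.
#'
#' @param p a `flow_parameters` object (or plain named list).
#' @return The validated `flow_parameters` object.
#' @export
validate_parameters <- function(p) {
  num1 <- function(field) {
    v <- p[[field]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("flow_parameters: field '", field, "' must be a single finite number")
    v
  }
  positive <- c("Re", "St", "Peh", "Pem")
  nonneg <- c("M", "Da")
  for (f in positive) if (num1(f) <= 0)
    stop("flow_parameters: field '", f, "' must be > 0")
  # beta may be Inf (Newtonian limit, 1/beta = 0) but never 0 or negative
  if (!is.numeric(p$beta) || length(p$beta) != 1L || is.na(p$beta) ||
      p$beta <= 0)
    stop("flow_parameters: field 'beta' must be > 0 (Inf allowed)")
  for (f in nonneg) if (num1(f) < 0)
    stop("flow_parameters: field '", f, "' must be >= 0")
  num1("Rd"); num1("Sr")
  if (p$Rd < 0) stop("flow_parameters: field 'Rd' must be >= 0")
  if (num1("eps") < 0 || p$eps > 1)
    stop("flow_parameters: field 'eps' must lie in [0, 1]")
  for (f in c("phi1", "phi2")) {
    v <- num1(f)
    if (v < 0 || v >= 1)
      stop("flow_parameters: field '", f, "' must lie in [0, 1)")
  }
  for (f in names(.swept_ranges)) {
    r <- .swept_ranges[[f]]
    if (p[[f]] < r[1] || p[[f]] > r[2])
      warning("flow_parameters: '", f, "' = ", p[[f]],
              " lies outside the studied range [", r[1], ", ", r[2], "]",
              call. = FALSE)
  }
  if (!inherits(p, "flow_parameters")) class(p) <- "flow_parameters"
  p
}

#' @export
print.flow_parameters <- function(x, ...) {
  cat("Flow parameters:\n")
  cat(sprintf("  Re = %g, St = %g, M = %g, Da = %g, beta = %g\n",
              x$Re, x$St, x$M, x$Da, x$beta))
  cat(sprintf("  Rd = %g, Peh = %g, Pem = %g, Sr = %g\n",
              x$Rd, x$Peh, x$Pem, x$Sr))
  cat(sprintf("  eps = %g, phi1 = %g, phi2 = %g\n", x$eps, x$phi1, x$phi2))
  invisible(x)
}
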