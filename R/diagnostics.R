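#' Wall shear stress along both walls
#'
#' Dimensionless wall shear stress evaluated through the wall-vorticity
#' closure and scaled by the Casson viscosity factor
#' `(1/(Re c3))(1 + 1/beta)`. The sign convention makes forward flow give
#' positive shear on both walls.
#'
#' @param state a `field_state`.
#' @param metrics,grid geometry descriptors.
#' @param params,coeffs flow parameters and mixture coefficients.
#' @return List with vectors `lower` and `upper` over `xi`.
#' @export
wall_shear_stress <- function(state, metrics, grid, params, coeffs) {
  wv <- wall_vorticity(state$psi, metrics, grid)
  f <- (1 / (params$Re * coeffs$c3)) * (1 + 1 / params$beta)
  list(lower = -f * wv$lower, upper = f * wv$upper)
}

# one-sided second-order wall gradient d f / d eta at eta = 0
wall_gradient_lower <- function(f, d_eta) {
  (-3 * f[, 1] + 4 * f[, 2] - f[, 3]) / (2 * d_eta)
}

#' Skin-friction coefficient along the lower wall
#'
#' `Cf = (1/u_ref^2) * (-(1/(Re c3)) (1 + 1/beta) Dm du/deta)` at
#' `eta = 0`, with a one-sided second-order wall derivative. `u_ref` is
#' the reference speed; the natural choice is the mean inlet speed.
#'
#' @inheritParams wall_shear_stress
#' @param u_ref reference speed (> 0).
#' @return Vector of `Cf` over `xi` (negative for forward flow).
#' @export
skin_friction <- function(state, metrics, grid, params, coeffs, u_ref) {
  if (!is.numeric(u_ref) || u_ref == 0)
    stop("skin_friction: u_ref must be nonzero")
  due <- wall_gradient_lower(state$u, grid$d_eta)
  -(1 / (params$Re * coeffs$c3)) * (1 + 1 / params$beta) *
    metrics$Dm * due / u_ref^2
}

#' Nusselt number along the lower wall
#'
#' `Nu = -c5 (1 + Rd) dtheta/deta` at `eta = 0` (one-sided second-order
#' wall gradient): conductivity-scaled, radiation-augmented wall heat flux.
#'
#' @inheritParams wall_shear_stress
#' @export
nusselt <- function(state, grid, coeffs, params) {
  -coeffs$c5 * (1 + params$Rd) * wall_gradient_lower(state$theta, grid$d_eta)
}

#' Sherwood number along the lower wall
#'
#' `Sh = -Dm dphi/deta` at `eta = 0` (one-sided second-order wall
#' gradient): gap-scaled wall mass flux.
#'
#' @inheritParams wall_shear_stress
#' @export
sherwood <- function(state, metrics, grid) {
  -metrics$Dm * wall_gradient_lower(state$phi_c, grid$d_eta)
}

#' Wall diagnostics table
#'
#' Per-station wall series at one snapshot: wall shear stress on both
#' walls, skin friction, Nusselt and Sherwood numbers. The skin-friction
#' reference speed defaults to the steady mean inlet speed (the
#' instantaneous one vanishes at the zero-flow phase of the pulse).
#'
#' @param state a `field_state`.
#' @param setup the [flow_setup()] that produced it.
#' @param u_ref reference speed for `Cf`; default the steady mean inlet
#'   speed.
#' @return A data frame with columns `xi`, `wss_lower`, `wss_upper`, `cf`,
#'   `nu`, `sh`, `t`.
#' @export
wall_diagnostics <- function(state, setup, u_ref = NULL) {
  grid <- setup$grid; metrics <- setup$metrics
  if (is.null(u_ref)) u_ref <- setup$inlet$flux  # mean speed over unit height
  wss <- wall_shear_stress(state, metrics, grid, setup$params, setup$coeffs)
  out <- data.frame(xi = grid$xi,
                    wss_lower = wss$lower, wss_upper = wss$upper,
                    cf = skin_friction(state, metrics, grid, setup$params,
                                       setup$coeffs, u_ref),
                    nu = nusselt(state, grid, setup$coeffs, setup$params),
                    sh = sherwood(state, metrics, grid),
                    t = state$t)
  stopifnot(all(is.finite(as.matrix(out))))
  out
}

#' Extract a wall-normal station profile
#'
#' Velocity, temperature and concentration versus `eta` at the grid column
#' nearest to the requested axial station (the standard stations `x = 0`,
#' throat, and `x = 2`, lee of the constriction, are exact nodes on the
#' default grid).
#'
#' @param state a `field_state`.
#' @param grid the matching grid.
#' @param x_station axial location, inside the domain.
#' @return A data frame with columns `eta`, `u`, `theta`, `phi`, plus
#'   attributes `xi` (the node actually used) and `t`.
#' @export
extract_profile <- function(state, grid, x_station) {
  if (x_station < grid$xi[1] || x_station > grid$xi[grid$n_xi])
    stop("extract_profile: station ", x_station, " outside the domain")
  i <- which.min(abs(grid$xi - x_station))
  out <- data.frame(eta = grid$eta, u = state$u[i, ],
                    theta = state$theta[i, ], phi = state$phi_c[i, ])
  attr(out, "xi") <- grid$xi[i]
  attr(out, "t") <- state$t
  out
}

#' Scalar summaries of one run
#'
#' The quantities used by the sweep trend reports, all at the peak-flow
#' snapshot (phase 0.25) of the final cycle: peak upper-wall shear stress,
#' skin friction / Nusselt / Sherwood numbers at the constriction throat
#' (`x = 0`), and centreline (`eta = 0.5`) temperature and concentration at
#' the throat.
#'
#' @param history a [run_simulation()] result.
#' @return Named numeric vector.
#' @export
run_summary <- function(history) {
  phases <- vapply(history$snapshots, function(s) s$phase, numeric(1))
  k <- which(phases == 0.25)
  if (!length(k)) k <- length(history$snapshots)
  sn <- history$snapshots[[k[1]]]
  grid <- history$setup$grid
  i0 <- which.min(abs(grid$xi - 0))
  j5 <- which.min(abs(grid$eta - 0.5))
  c(peak_wss_upper = max(sn$wall$wss_upper),
    cf_throat = sn$wall$cf[i0],
    nu_throat = sn$wall$nu[i0],
    sh_throat = sn$wall$sh[i0],
    theta_centre = sn$state$theta[i0, j5],
    phi_centre = sn$state$phi_c[i0, j5])
}

#' Monotone-trend verdict over a one-parameter sweep
#'
#' Given per-run scalar summaries of runs differing only in one parameter,
#' reports whether the chosen quantity is monotone in the parameter and, if
#' an expected direction is supplied, whether it matches.
#'
#' @param sweep a data frame with a parameter-value column and summary
#'   columns (as produced by [sweep_parameter()]), or anything coercible.
#' @param quantity name of the summary column to examine.
#' @param parameter name of the parameter column.
#' @param expected optionally `"increasing"` or `"decreasing"`.
#' @return A list with `verdict` (`"increasing"`, `"decreasing"`,
#'   `"non-monotone"` or `"constant"`), `matches` (logical or `NA`),
#'   `values` and `parameter_values`.
#' @export
trend_report <- function(sweep, quantity, parameter,
                         expected = NULL) {
  sweep <- as.data.frame(sweep)
  if (!quantity %in% names(sweep))
    stop("trend_report: no summary column '", quantity, "'")
  if (!parameter %in% names(sweep))
    stop("trend_report: no parameter column '", parameter, "'")
  if (nrow(sweep) < 2)
    stop("trend_report: need at least two runs to assess a trend")
  o <- order(sweep[[parameter]])
  pv <- sweep[[parameter]][o]
  if (anyDuplicated(pv))
    stop("trend_report: parameter values must be distinct")
  qv <- sweep[[quantity]][o]
  d <- diff(qv)
  verdict <- if (all(d > 0)) "increasing" else if (all(d < 0)) "decreasing"
  else if (all(d == 0)) "constant" else "non-monotone"
  matches <- if (is.null(expected)) NA else identical(verdict, expected)
  list(verdict = verdict, matches = matches, values = qv,
       parameter_values = pv)
}
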