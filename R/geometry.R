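#' Constricted-channel geometry
#'
#' Describes a straight plane channel of unit height carrying one pair of
#' symmetric cosine-shaped constriction bumps centred at `x = 0`:
#' the lower wall is `y1(x) = (h1/2)(1 + cos(pi x / x0))` for `|x| <= x0`
#' and 0 outside, the upper wall `y2(x) = 1 - (h2/2)(1 + cos(pi x / x0))`
#' for `|x| <= x0` and 1 outside.
#'
#' @param h1,h2 constriction heights of the lower/upper bump (channel-height
#'   units); `h1 + h2 < 1` so the walls never touch.
#' @param x0 constriction half-length (the bump spans `[-x0, x0]`).
#' @param xi_min,xi_max axial domain bounds; must bracket the bump.
#' @return An object of class `geometry_spec`.
#' @examples
#' geometry_spec()            # default stenosed channel
#' geometry_spec(h1 = 0, h2 = 0)  # straight channel
#' @export
geometry_spec <- function(h1 = 0.35, h2 = 0.35, x0 = 1,
                          xi_min = -10, xi_max = 10) {
  if (h1 < 0 || h2 < 0) stop("geometry_spec: constriction heights must be >= 0")
  if (h1 + h2 >= 1) stop("geometry_spec: h1 + h2 must be < 1 (walls touch)")
  if (x0 <= 0) stop("geometry_spec: x0 must be > 0")
  if (!(xi_min < -x0 && x0 < xi_max))
    stop("geometry_spec: domain [xi_min, xi_max] must contain [-x0, x0]")
  structure(list(h1 = h1, h2 = h2, x0 = x0,
                 xi_min = xi_min, xi_max = xi_max),
            class = "geometry_spec")
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat(sprintf("Constricted channel: h1 = %g, h2 = %g, x0 = %g, xi in [%g, %g]\n",
              x$h1, x$h2, x$x0, x$xi_min, x$xi_max))
  invisible(x)
}

#' Lower wall height
#'
#' @param x axial coordinate(s).
#' @param spec a [geometry_spec()].
#' @return `y1(x)`, vectorized.
#' @export
wall_lower <- function(x, spec = geometry_spec()) {
  ifelse(abs(x) <= spec$x0,
         (spec$h1 / 2) * (1 + cos(pi * x / spec$x0)), 0)
}

#' Upper wall height
#'
#' @inheritParams wall_lower
#' @return `y2(x)`, vectorized.
#' @export
wall_upper <- function(x, spec = geometry_spec()) {
  ifelse(abs(x) <= spec$x0,
         1 - (spec$h2 / 2) * (1 + cos(pi * x / spec$x0)), 1)
}

#' Closed-form wall derivatives
#'
#' First and second derivatives of both cosine bumps, identically zero
#' outside `|x| <= x0`. The bump is C1 at `|x| = x0`; the second derivative
#' is one-sided there (no smoothing).
#'
#' @inheritParams wall_lower
#' @return A list with vectors `y1p`, `y1pp`, `y2p`, `y2pp`.
#' @export
wall_derivatives <- function(x, spec = geometry_spec()) {
  inb <- abs(x) <= spec$x0
  w <- pi / spec$x0
  s <- sin(w * x); cc <- cos(w * x)
  y1p  <- ifelse(inb, -(spec$h1 / 2) * w * s, 0)
  y1pp <- ifelse(inb, -(spec$h1 / 2) * w^2 * cc, 0)
  y2p  <- ifelse(inb,  (spec$h2 / 2) * w * s, 0)
  y2pp <- ifelse(inb,  (spec$h2 / 2) * w^2 * cc, 0)
  list(y1p = y1p, y1pp = y1pp, y2p = y2p, y2pp = y2pp)
}

#' Build a uniform computational grid
#'
#' Uniform node arrays over `[xi_min, xi_max] x [0, 1]`. The default
#' `401 x 51` nodes discretize the standard domain into 400 x 50 cells with
#' spacings `d_xi = 0.05`, `d_eta = 0.02`; `eta = 0` is the lower (heated)
#' wall and `eta = 1` the upper wall.
#'
#' @param spec a [geometry_spec()].
#' @param n_xi,n_eta node counts (>= 3).
#' @return An object of class `flow_grid` with fields `n_xi`, `n_eta`,
#'   `d_xi`, `d_eta`, `xi`, `eta`.
#' @export
build_grid <- function(spec = geometry_spec(), n_xi = 401, n_eta = 51) {
  if (n_xi < 3 || n_eta < 3) stop("build_grid: need at least 3 nodes per direction")
  xi <- seq(spec$xi_min, spec$xi_max, length.out = n_xi)
  eta <- seq(0, 1, length.out = n_eta)
  structure(list(n_xi = as.integer(n_xi), n_eta = as.integer(n_eta),
                 d_xi = xi[2] - xi[1], d_eta = eta[2] - eta[1],
                 xi = xi, eta = eta),
            class = "flow_grid")
}

#' @export
print.flow_grid <- function(x, ...) {
  cat(sprintf("Grid: %d x %d nodes, d_xi = %g, d_eta = %g, xi in [%g, %g]\n",
              x$n_xi, x$n_eta, x$d_xi, x$d_eta, x$xi[1], x$xi[x$n_xi]))
  invisible(x)
}

#' Metric coefficient fields of the wall-fitted mapping
#'
#' The mapping `xi = x`, `eta = (y - y1)/(y2 - y1)` straightens the
#' constricted channel. Its metric coefficients on the grid are
#' `Pm = (eta y2'' + (1-eta) y1'')/(y2-y1)` (curvature),
#' `Qm = (eta y2' + (1-eta) y1')/(y2-y1)` (slope),
#' `Rm = (y2'-y1')/(y2-y1)` (relative gap slope) and
#' `Dm = 1/(y2-y1)` (inverse gap width). `Pm` and `Qm` are `n_xi x n_eta`
#' matrices; `Rm` and `Dm` depend on `xi` only.
#'
#' @param grid a [build_grid()] result.
#' @param spec the matching [geometry_spec()].
#' @return An object of class `metric_fields` with `Pm`, `Qm` (matrices),
#'   `Rm`, `Dm`, `y1`, `y2` (vectors over `xi`).
#' @export
build_metrics <- function(grid, spec = geometry_spec()) {
  y1 <- wall_lower(grid$xi, spec)
  y2 <- wall_upper(grid$xi, spec)
  gap <- y2 - y1
  if (any(gap <= 0)) stop("build_metrics: walls touch or cross (y2 <= y1)")
  d <- wall_derivatives(grid$xi, spec)
  eta <- grid$eta
  # outer products: rows xi, cols eta
  Pm <- (outer(d$y2pp, eta) + outer(d$y1pp, 1 - eta)) / gap
  Qm <- (outer(d$y2p, eta) + outer(d$y1p, 1 - eta)) / gap
  Rm <- (d$y2p - d$y1p) / gap
  Dm <- 1 / gap
  structure(list(Pm = Pm, Qm = Qm, Rm = Rm, Dm = Dm, y1 = y1, y2 = y2),
            class = "metric_fields")
}
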