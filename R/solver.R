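#' Tridiagonal system solver (Thomas algorithm)
#'
#' Direct forward-elimination / back-substitution solve of a tridiagonal
#' system. `lower[1]` and `upper[n]` are ignored. A vanishing pivot raises
#' an error naming the row.
#'
#' @param lower,diag,upper coefficient sequences (length `n`).
#' @param rhs right-hand side (length `n`).
#' @return The solution vector.
#' @examples
#' tdma(c(0, 1), c(2, 2), c(1, 0), c(4, 4))
#' @export
tdma <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  if (length(lower) != n || length(upper) != n || length(rhs) != n)
    stop("tdma: all coefficient sequences must share the diagonal's length")
  tdma_cpp(as.numeric(lower), as.numeric(diag), as.numeric(upper),
           as.numeric(rhs))
}

#' Solver configuration
#'
#' Numerical settings of the time-marching scheme. The defaults are the
#' full-fidelity settings: time step `5e-5`, six pulse cycles, snapshots at
#' cycle phases 0, 0.25, 0.5, 0.75.
#'
#' @param dt time step (cycle-time units).
#' @param n_cycles number of pulse cycles to march.
#' @param poisson_tol maximum-residual tolerance of the stream-function
#'   Poisson solve.
#' @param poisson_max_iter sweep limit per Poisson solve.
#' @param relax line-relaxation factor; `NULL` selects an automatic SOR
#'   estimate from the grid.
#' @param porous_vorticity_sign sign of the linear porous drag term
#'   `Re Da^2 omega` in the vorticity equation: `-1` (default) is the
#'   derivation-consistent damping sign, `+1` the literal printed sign.
#' @param snapshot_times cycle phases at which diagnostics are recorded.
#' @param upwind use first-order upwind advection with an explicit deferred
#'   central correction (robustness option for coarse grids); default pure
#'   central differencing.
#' @param divergence_bound abort when any field magnitude exceeds this.
#' @param steady_tol for steady runs (`eps = 0`), stop early once the
#'   per-step relative field change falls below this; 0 disables.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = 5e-5, n_cycles = 6, poisson_tol = 1e-6,
                          poisson_max_iter = 20000, relax = NULL,
                          porous_vorticity_sign = -1,
                          snapshot_times = c(0, 0.25, 0.5, 0.75),
                          upwind = FALSE, divergence_bound = 1e6,
                          steady_tol = 0) {
  if (dt <= 0) stop("solver_config: dt must be > 0")
  if (poisson_tol <= 0) stop("solver_config: poisson_tol must be > 0")
  if (!porous_vorticity_sign %in% c(-1, 1))
    stop("solver_config: porous_vorticity_sign must be -1 or +1")
  if (any(snapshot_times < 0 | snapshot_times >= 1))
    stop("solver_config: snapshot_times are cycle phases in [0, 1)")
  structure(list(dt = dt, n_cycles = n_cycles, poisson_tol = poisson_tol,
                 poisson_max_iter = as.integer(poisson_max_iter),
                 relax = relax,
                 porous_vorticity_sign = porous_vorticity_sign,
                 snapshot_times = sort(snapshot_times), upwind = upwind,
                 divergence_bound = divergence_bound,
                 steady_tol = steady_tol),
            class = "solver_config")
}

# Estimated optimal SOR factor for eta-line relaxation of the Poisson
# equation: line-Jacobi spectral radius of the straight-channel model
# problem (the Dirichlet eta walls shift the lowest mode).
auto_relax <- function(grid) {
  shift <- 2 * (1 - cos(pi / (grid$n_eta - 1))) / grid$d_eta^2
  ax <- 2 / grid$d_xi^2
  mu <- ax * cos(pi / (grid$n_xi - 1)) / (ax + shift)
  min(2 / (1 + sqrt(max(1 - mu^2, 0))), 1.95)
}

metric_matrices <- function(metrics, grid) {
  nx <- grid$n_xi; ny <- grid$n_eta
  list(Dmat = matrix(metrics$Dm, nx, ny),
       Rmat = matrix(metrics$Rm, nx, ny))
}

#' Transformed Laplacian operator
#'
#' Central-difference evaluation of the mapped Laplacian
#' `f_xixi - (Pm - 2 Qm Rm) f_eta - 2 Qm f_xieta +
#' (Qm^2 + eta_eta_coeff * Dm^2) f_etaeta` on interior nodes (boundary
#' entries zero). `eta_eta_coeff = 1` for the stream function, vorticity
#' and concentration; the temperature operator uses `1 + Rd/c5`
#' (radiation-augmented wall-normal diffusion).
#'
#' @param f field matrix (`n_xi x n_eta`).
#' @param metrics a [build_metrics()] result.
#' @param grid the matching grid.
#' @param eta_eta_coeff multiplier of `Dm^2` in the `f_etaeta` coefficient.
#' @return Matrix of the same shape; interior nodes hold the operator value.
#' @export
transformed_laplacian <- function(f, metrics, grid, eta_eta_coeff = 1) {
  mm <- metric_matrices(metrics, grid)
  A <- metrics$Qm^2 + eta_eta_coeff * mm$Dmat^2
  B <- metrics$Pm - 2 * metrics$Qm * mm$Rmat
  laplacian_cpp(f, A, B, metrics$Qm, grid$d_xi, grid$d_eta)
}

#' Stream-function Poisson solve
#'
#' Solves the mapped Poisson equation `L[psi] = -omega` by iterative
#' eta-line relaxation: each axial sweep solves every wall-normal line by
#' the Thomas algorithm with the axial coupling taken Gauss-Seidel style
#' and the mixed derivative lagged, with over-relaxation. Boundary values
#' carried by `psi` (inlet column, wall rows) are held fixed; the outlet
#' column is zero-gradient.
#'
#' @param omega vorticity matrix (right-hand side).
#' @param psi initial guess carrying the boundary values.
#' @param metrics,grid geometry descriptors.
#' @param cfg a [solver_config()].
#' @return List with the converged `psi`, `iterations`, final `residual`
#'   and the residual `history`. Non-convergence raises an error quoting
#'   the tail of the residual history.
#' @export
solve_poisson_psi <- function(omega, psi, metrics, grid, cfg = solver_config()) {
  mm <- metric_matrices(metrics, grid)
  A <- metrics$Qm^2 + mm$Dmat^2
  B <- metrics$Pm - 2 * metrics$Qm * mm$Rmat
  relax <- if (is.null(cfg$relax)) auto_relax(grid) else cfg$relax
  res <- poisson_slor_cpp(psi, omega, A, B, metrics$Qm,
                          grid$d_xi, grid$d_eta, cfg$poisson_tol,
                          cfg$poisson_max_iter, relax)
  if (!res$converged && relax != 1) {
    # over-relaxation can limit-cycle on the lagged mixed term near the
    # bump; plain Gauss-Seidel line relaxation is slower but convergent
    res2 <- poisson_slor_cpp(res$psi, omega, A, B, metrics$Qm,
                             grid$d_xi, grid$d_eta, cfg$poisson_tol,
                             cfg$poisson_max_iter, 1.0)
    res2$iterations <- res2$iterations + res$iterations
    res2$history <- c(res$history, res2$history)
    res <- res2
  }
  if (!res$converged) {
    tl <- utils::tail(res$history, 5)
    stop("solve_poisson_psi: no convergence in ", res$iterations,
         " sweeps; residual history tail: ",
         paste(signif(tl, 4), collapse = ", "))
  }
  res
}

# Generic ADI transport step for the mapped convection-diffusion equation
#   St f_t + u f_xi + (v D - u Q) f_eta = nu L_a[f] + S + lam f
# with L_a the transformed Laplacian with eta-eta coefficient
# (Q^2 + a_eta D^2).
adi_transport <- function(f, state_u, state_v, metrics, grid, St, nu, a_eta,
                          S, lam, f_in, f_low, f_up, dt, upwind) {
  mm <- metric_matrices(metrics, grid)
  A <- nu * (metrics$Qm^2 + a_eta * mm$Dmat^2)
  W <- state_v * mm$Dmat - state_u * metrics$Qm +
    nu * (metrics$Pm - 2 * metrics$Qm * mm$Rmat)
  out <- adi_advance_cpp(f, state_u, W, A, metrics$Qm, S,
                         grid$d_xi, grid$d_eta, dt, St, nu, lam,
                         f_in, f_low, f_up, upwind)
  if (!is.finite(sum(out)))
    stop("adi_transport: non-finite field values (solution diverged)")
  out
}

#' Advance the vorticity field by one ADI step
#'
#' Vorticity transport with Casson-scaled viscous diffusion
#' `(1/c3)(1/Re)(1 + 1/beta)`, magnetic source
#' `(1/c1)(M^2/Re) Dm^2 psi_etaeta` and linear porous drag
#' `porous_vorticity_sign * Re Da^2 omega` (implicit in the diagonal).
#' Advection uses the level-`l` velocities in `state`; wall rows are the
#' Dirichlet closure values in `bc`.
#'
#' @param state a `field_state` at level `l`.
#' @param metrics,grid geometry descriptors.
#' @param params,coeffs flow parameters and mixture coefficients.
#' @param cfg a [solver_config()].
#' @param bc list with vectors `omega_in` (inlet column), `omega_low`,
#'   `omega_up` (wall rows).
#' @return The vorticity matrix at level `l + 1`.
#' @export
advance_omega <- function(state, metrics, grid, params, coeffs, cfg, bc) {
  nu <- (1 / coeffs$c3) * (1 / params$Re) * (1 + 1 / params$beta)
  mm <- metric_matrices(metrics, grid)
  psi_ee <- second_deriv_eta_cpp(state$psi, grid$d_eta)
  S <- (params$M^2 / (coeffs$c1 * params$Re)) * mm$Dmat^2 * psi_ee
  lam <- cfg$porous_vorticity_sign * params$Re * params$Da^2
  adi_transport(state$omega, state$u, state$v, metrics, grid, params$St,
                nu, 1, S, lam, bc$omega_in, bc$omega_low, bc$omega_up,
                cfg$dt, cfg$upwind)
}

#' Advance the temperature field by one ADI step
#'
#' Heat transport with diffusivity `(1/Peh)(c5/c4)` and
#' radiation-augmented wall-normal diffusion (eta-eta coefficient
#' `Qm^2 + (1 + Rd/c5) Dm^2`). Wall rows are the fixed scalar values
#' (1 at the lower wall, 0 at the upper).
#'
#' @inheritParams advance_omega
#' @param bc list with vectors `theta_in`, `theta_low`, `theta_up`.
#' @export
advance_theta <- function(state, metrics, grid, params, coeffs, cfg, bc) {
  nu <- (1 / params$Peh) * (coeffs$c5 / coeffs$c4)
  a_eta <- 1 + params$Rd / coeffs$c5
  S <- matrix(0, grid$n_xi, grid$n_eta)
  adi_transport(state$theta, state$u, state$v, metrics, grid, params$St,
                nu, a_eta, S, 0, bc$theta_in, bc$theta_low, bc$theta_up,
                cfg$dt, cfg$upwind)
}

#' Advance the concentration field by one ADI step
#'
#' Solute transport with diffusivity `1/Pem` and the Soret source
#' `(Sr/Re) L[theta]` (full transformed Laplacian of the temperature at the
#' new time level, unit eta-eta coefficient) treated explicitly.
#'
#' @inheritParams advance_omega
#' @param theta_new temperature at level `l + 1` (Soret coupling).
#' @param bc list with vectors `phi_in`, `phi_low`, `phi_up`.
#' @export
advance_phi <- function(state, metrics, grid, params, coeffs, cfg, bc,
                        theta_new = state$theta) {
  nu <- 1 / params$Pem
  S <- (params$Sr / params$Re) *
    transformed_laplacian(theta_new, metrics, grid, 1)
  adi_transport(state$phi_c, state$u, state$v, metrics, grid, params$St,
                nu, 1, S, 0, bc$phi_in, bc$phi_low, bc$phi_up,
                cfg$dt, cfg$upwind)
}

#' Velocities from the stream function
#'
#' `u = Dm psi_eta`, `v = Qm psi_eta - psi_xi`, with central differences in
#' the interior and one-sided second-order formulas on the boundary.
#'
#' @param psi stream-function matrix.
#' @param metrics,grid geometry descriptors.
#' @return List of matrices `u` and `v`.
#' @export
velocity_from_psi <- function(psi, metrics, grid) {
  mm <- metric_matrices(metrics, grid)
  pe <- deriv_eta_cpp(psi, grid$d_eta)
  px <- deriv_xi_cpp(psi, grid$d_xi)
  list(u = mm$Dmat * pe, v = metrics$Qm * pe - px)
}

#' Assemble a simulation context
#'
#' Precomputes everything a time step needs: grid, metric fields, mixture
#' coefficients and the steady inlet profile.
#'
#' @param params a [flow_parameters()].
#' @param geometry a [geometry_spec()].
#' @param cfg a [solver_config()].
#' @param mat a [material_table()].
#' @param n_xi,n_eta grid node counts.
#' @param inlet_mode inlet normalization (see [inlet_profile()]).
#' @param maxwell_classic passed to [mixture_coefficients()].
#' @return An object of class `flow_setup`.
#' @export
flow_setup <- function(params = flow_parameters(),
                       geometry = geometry_spec(),
                       cfg = solver_config(), mat = material_table(),
                       n_xi = 401, n_eta = 51,
                       inlet_mode = c("paper_literal", "unit_flux"),
                       maxwell_classic = FALSE) {
  inlet_mode <- match.arg(inlet_mode)
  grid <- build_grid(geometry, n_xi, n_eta)
  metrics <- build_metrics(grid, geometry)
  coeffs <- mixture_coefficients(mat, params$phi1, params$phi2,
                                 maxwell_classic)
  inlet <- inlet_profile(params, coeffs, grid$eta, inlet_mode)
  walls <- scalar_wall_values(grid)
  structure(list(params = params, geometry = geometry, cfg = cfg,
                 mat = mat, grid = grid, metrics = metrics,
                 coeffs = coeffs, inlet = inlet, walls = walls,
                 # inlet columns for the scalars: conduction profile,
                 # consistent with the wall values
                 theta_in = 1 - grid$eta, phi_in = 1 - grid$eta),
            class = "flow_setup")
}

#' Advance the coupled system by one time step
#'
#' Ordered sub-steps: (1) boundary values at the new time (pulsating inlet,
#' walls, outlet); (2) vorticity ADI step with level-`l` velocities;
#' (3) Poisson solve for the stream function; (4) wall-vorticity closure;
#' (5) velocity recovery; (6) temperature ADI step; (7) concentration ADI
#' step with the new-level Soret source.
#'
#' @param state a `field_state` at level `l`.
#' @param setup a [flow_setup()].
#' @param psi_prev stream function at level `l - 1`, used for the
#'   extrapolated Poisson warm start (optional).
#' @return The `field_state` at level `l + 1` (with the Poisson iteration
#'   count in attribute `"poisson_iterations"`).
#' @export
time_step <- function(state, setup, psi_prev = NULL) {
  cfg <- setup$cfg; params <- setup$params; grid <- setup$grid
  metrics <- setup$metrics; coeffs <- setup$coeffs; inlet <- setup$inlet
  ny <- grid$n_eta
  t1 <- state$t + cfg$dt
  pf <- pulsation_factor(t1, params$eps)
  psi_in <- inlet$psi * pf
  flux_t <- inlet$flux * pf

  wv <- wall_vorticity(state$psi, metrics, grid)
  bc_om <- list(omega_in = inlet$omega * pf,
                omega_low = wv$lower, omega_up = wv$upper)
  omega_new <- advance_omega(state, metrics, grid, params, coeffs, cfg, bc_om)

  psi_guess <- if (is.null(psi_prev)) state$psi else 2 * state$psi - psi_prev
  psi_guess[1, ] <- psi_in
  psi_guess[, 1] <- 0
  psi_guess[, ny] <- flux_t
  psi_guess[grid$n_xi, ] <- psi_guess[grid$n_xi - 1, ]
  sol <- solve_poisson_psi(omega_new, psi_guess, metrics, grid, cfg)
  psi_new <- sol$psi

  wv_new <- wall_vorticity(psi_new, metrics, grid)
  omega_new[, 1] <- wv_new$lower
  omega_new[, ny] <- wv_new$upper
  omega_new[1, ] <- bc_om$omega_in
  omega_new <- apply_outflow(omega_new)

  vel <- velocity_from_psi(psi_new, metrics, grid)
  state_mid <- state
  state_mid$u <- vel$u; state_mid$v <- vel$v

  bc_th <- list(theta_in = setup$theta_in,
                theta_low = setup$walls$theta_lower,
                theta_up = setup$walls$theta_upper)
  theta_new <- advance_theta(state_mid, metrics, grid, params, coeffs, cfg,
                             bc_th)
  bc_ph <- list(phi_in = setup$phi_in, phi_low = setup$walls$phi_lower,
                phi_up = setup$walls$phi_upper)
  phi_new <- advance_phi(state_mid, metrics, grid, params, coeffs, cfg,
                         bc_ph, theta_new)

  out <- structure(list(psi = psi_new, omega = omega_new, theta = theta_new,
                        phi_c = phi_new, u = vel$u, v = vel$v, t = t1),
                   class = "field_state")
  attr(out, "poisson_iterations") <- sol$iterations
  out
}

# eta-quadrature of the physical volume flux at every axial station:
# integral of u dy = integral of (u / Dm) d eta  (trapezoidal rule).
flux_by_quadrature <- function(u, metrics, grid) {
  w <- rep(1, grid$n_eta); w[1] <- w[grid$n_eta] <- 0.5
  as.numeric((u %*% w) * grid$d_eta) / metrics$Dm
}

#' Run a full simulation
#'
#' Marches the coupled vorticity / stream-function / temperature /
#' concentration system over `n_cycles` pulse cycles (period 1 in cycle
#' time) from a quiescent start, records field snapshots and wall
#' diagnostics at the configured phases of the final cycle, and measures
#' cycle-to-cycle periodicity (maximum relative change of the upper-wall
#' shear-stress curve at peak flow between the last two cycles) and mass
#' conservation (axial uniformity of the eta-quadrature flux, relative to
#' the steady inlet flux).
#'
#' For steady runs (`eps = 0`) with `steady_tol > 0` the march stops early
#' once the per-step relative field change drops below the tolerance.
#'
#' @inheritParams flow_setup
#' @param setup optionally a prebuilt [flow_setup()] (overrides the other
#'   arguments).
#' @param verbose print per-cycle progress.
#' @return An object of class `flow_history`: `snapshots` (list of
#'   `state`, `wall` diagnostics table, `phase`, `t`), `final_state`,
#'   `periodicity`, `mass_err` (per snapshot), `setup`, `steady`,
#'   `poisson_iter_mean`.
#' @examples
#' \donttest{
#' hist <- run_simulation(flow_parameters(), geometry_spec(),
#'                        solver_config(dt = 5e-4, n_cycles = 3),
#'                        n_xi = 201, n_eta = 26)
#' hist$periodicity
#' }
#' @export
run_simulation <- function(params = flow_parameters(),
                           geometry = geometry_spec(),
                           cfg = solver_config(), mat = material_table(),
                           n_xi = 401, n_eta = 51,
                           inlet_mode = c("paper_literal", "unit_flux"),
                           maxwell_classic = FALSE, setup = NULL,
                           verbose = FALSE) {
  if (is.null(setup))
    setup <- flow_setup(params, geometry, cfg, mat, n_xi, n_eta,
                        match.arg(inlet_mode), maxwell_classic)
  params <- setup$params; cfg <- setup$cfg; grid <- setup$grid
  metrics <- setup$metrics; coeffs <- setup$coeffs

  spc <- round(1 / cfg$dt)
  if (abs(spc * cfg$dt - 1) > 1e-9)
    stop("run_simulation: dt must divide the unit pulse cycle")
  n_steps <- spc * cfg$n_cycles
  # absolute step indices of the final-cycle snapshots
  snap_steps <- (cfg$n_cycles - 1) * spc + round(cfg$snapshot_times * spc)
  peak_step <- round(0.25 * spc)

  state <- initial_state(grid)
  psi_prev <- NULL
  snapshots <- list()
  if (any(snap_steps == 0L))   # phase 0 of a single-cycle run: t = 0 state
    snapshots[[1]] <- list(state = state, phase = 0, t = 0)
  wss_factor <- (1 / (params$Re * coeffs$c3)) * (1 + 1 / params$beta)
  peak_wss <- vector("list", cfg$n_cycles)   # upper-wall WSS at phase 0.25
  piter <- 0; delta <- Inf; steady <- FALSE
  t0 <- proc.time()[["elapsed"]]

  for (l in seq_len(n_steps)) {
    new_state <- time_step(state, setup, psi_prev)
    piter <- piter + attr(new_state, "poisson_iterations")
    if (l %% 25L == 0L) {
      mx <- max(abs(new_state$u), abs(new_state$omega))
      if (!is.finite(mx) || mx > cfg$divergence_bound)
        stop("run_simulation: divergence detected at step ", l,
             " (t = ", signif(new_state$t, 6), "), max field = ", signif(mx, 4))
    }
    if ((l - peak_step) %% spc == 0L && l >= peak_step) {
      cyc <- (l - peak_step) %/% spc + 1L
      wv <- wall_vorticity(new_state$psi, metrics, grid)
      peak_wss[[cyc]] <- wss_factor * wv$upper
    }
    hit <- which(snap_steps == l)
    if (length(hit))
      snapshots[[length(snapshots) + 1]] <-
        list(state = new_state, phase = cfg$snapshot_times[hit[1]],
             t = new_state$t)
    if (params$eps == 0 && cfg$steady_tol > 0) {
      delta <- max(abs(new_state$psi - state$psi)) /
        max(max(abs(new_state$psi)), 1e-12)
      if (delta < cfg$steady_tol) {
        steady <- TRUE
        psi_prev <- state$psi
        state <- new_state
        break
      }
    }
    psi_prev <- state$psi
    state <- new_state
    if (verbose && l %% spc == 0L)
      message(sprintf("cycle %d/%d done (t = %.3f, poisson iters/step = %.1f)",
                      l %/% spc, cfg$n_cycles, state$t, piter / l))
  }

  if (steady || length(snapshots) == 0L)
    snapshots <- list(list(state = state, phase = NA_real_, t = state$t))

  # periodicity: upper-wall WSS curve at peak flow, last two completed cycles
  have <- which(!vapply(peak_wss, is.null, TRUE))
  periodicity <- if (length(have) >= 2) {
    a <- peak_wss[[have[length(have) - 1]]]
    b <- peak_wss[[have[length(have)]]]
    max(abs(b - a)) / max(abs(b))
  } else if (steady) delta else NA_real_

  flux0 <- setup$inlet$flux
  # xi-uniformity of the stream-function jump across the channel,
  # relative to the steady inlet flux
  mass_err <- vapply(snapshots, function(sn) {
    jump <- sn$state$psi[, grid$n_eta] - sn$state$psi[, 1]
    max(abs(jump - jump[1])) / abs(flux0)
  }, numeric(1))
  # informational: uniformity of the eta-quadrature of u (carries the
  # O(deta^2) profile-integration bias of the trapezoidal rule)
  flux_uniformity_u <- vapply(snapshots, function(sn) {
    fq <- flux_by_quadrature(sn$state$u, metrics, grid)
    max(abs(fq - fq[1])) / abs(flux0)
  }, numeric(1))

  for (k in seq_along(snapshots))
    snapshots[[k]]$wall <- wall_diagnostics(snapshots[[k]]$state, setup)

  structure(list(snapshots = snapshots, final_state = state,
                 periodicity = periodicity, mass_err = mass_err,
                 flux_uniformity_u = flux_uniformity_u,
                 peak_wss = peak_wss, setup = setup, steady = steady,
                 poisson_iter_mean = piter / max(1, state$t / cfg$dt),
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "flow_history")
}

#' @export
print.flow_history <- function(x, ...) {
  cat(sprintf("Flow history: %d snapshot(s), t_end = %g%s\n",
              length(x$snapshots), x$final_state$t,
              if (x$steady) " (steady, early stop)" else ""))
  cat(sprintf("  periodicity = %.3g, mass conservation err = %.3g\n",
              x$periodicity, max(x$mass_err)))
  cat(sprintf("  mean Poisson sweeps/step = %.1f, elapsed = %.1f s\n",
              x$poisson_iter_mean, x$elapsed))
  invisible(x)
}
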