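#' Default run configuration
#'
#' The flat key-value configuration describing one simulation, filled with
#' the baseline study conditions: standard domain and constriction, the
#' default dimensionless parameter set, and the full-fidelity numerical
#' settings. Two grid presets exist: `"full"` (401 x 51 nodes, `dt = 5e-5`,
#' 6 cycles) and `"acceptance"` (201 x 26 nodes, `dt = 5e-4`, 3 cycles), a
#' reduced desk-scale preset for tests and sweeps.
#'
#' @param preset `"full"` (default) or `"acceptance"`.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(preset = c("full", "acceptance")) {
  preset <- match.arg(preset)
  cfg <- list(
    # geometry
    h1 = 0.35, h2 = 0.35, x0 = 1, xi_min = -10, xi_max = 10,
    # grid
    n_xi = 401, n_eta = 51,
    # dimensionless parameters
    Re = 800, St = 0.02, M = 5, Da = 0.002, beta = 0.5, Rd = 0.2,
    Peh = 490, Pem = 420, Sr = 0.8, eps = 1, phi1 = 0.03, phi2 = 0.03,
    # solver
    dt = 5e-5, n_cycles = 6, poisson_tol = 1e-6, poisson_max_iter = 20000,
    relax = NULL, porous_vorticity_sign = -1,
    snapshot_times = c(0, 0.25, 0.5, 0.75), upwind = FALSE,
    divergence_bound = 1e6, steady_tol = 0,
    # modes
    inlet_mode = "paper_literal", maxwell_classic = FALSE, preset = preset,
    out_dir = NULL,
    # material constants
    rho_f = 997.1, rho_s1 = 8933, rho_s2 = 10500,
    cp_f = 4179, cp_s1 = 385, cp_s2 = 235,
    k_f = 0.613, k_s1 = 401, k_s2 = 429, nu_f = 9.009e-7)
  if (preset == "acceptance") {
    cfg$n_xi <- 201; cfg$n_eta <- 26
    cfg$dt <- 5e-4; cfg$n_cycles <- 3
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Flat key-value document; keys not in [default_config()] are rejected by
#' name, missing keys take their defaults, and an empty file yields the
#' full default configuration. A `preset` key is applied before the other
#' overrides, so explicit keys win over preset values.
#'
#' @param path path to the YAML file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("load_config: expected a key-value document")
  base <- default_config(if (is.null(user$preset)) "full" else user$preset)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "))
  for (k in setdiff(names(user), "preset")) base[[k]] <- user[[k]]
  if (identical(base$relax, "auto")) base$relax <- NULL
  if (!is.null(base$snapshot_times))
    base$snapshot_times <- as.numeric(unlist(base$snapshot_times))
  validate_config(base)
}

validate_config <- function(cfg) {
  # constructors enforce the invariants and name the offending field
  config_pieces(cfg)
  cfg
}

config_pieces <- function(cfg) {
  mat <- material_table(cfg$rho_f, cfg$rho_s1, cfg$rho_s2,
                        cfg$cp_f, cfg$cp_s1, cfg$cp_s2,
                        cfg$k_f, cfg$k_s1, cfg$k_s2, cfg$nu_f)
  params <- flow_parameters(cfg$Re, cfg$St, cfg$M, cfg$Da, cfg$beta, cfg$Rd,
                            cfg$Peh, cfg$Pem, cfg$Sr, cfg$eps,
                            cfg$phi1, cfg$phi2)
  geom <- geometry_spec(cfg$h1, cfg$h2, cfg$x0, cfg$xi_min, cfg$xi_max)
  scfg <- solver_config(cfg$dt, cfg$n_cycles, cfg$poisson_tol,
                        cfg$poisson_max_iter, cfg$relax,
                        cfg$porous_vorticity_sign,
                        unlist(cfg$snapshot_times), cfg$upwind,
                        cfg$divergence_bound, cfg$steady_tol)
  list(mat = mat, params = params, geom = geom, scfg = scfg)
}

#' Save a run configuration as YAML
#'
#' @param cfg a `run_config`.
#' @param path destination file.
#' @export
save_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$relax <- if (is.null(out$relax)) "auto" else out$relax
  out$out_dir <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run a single configured case
#'
#' Builds all objects from the flat configuration, runs the simulation and
#' (if `out_dir` is set) writes the output file set.
#'
#' @param cfg a `run_config` (see [default_config()], [load_config()]).
#' @param verbose print per-cycle progress.
#' @return The [run_simulation()] history, with the configuration attached
#'   as attribute `"config"`.
#' @export
run_case <- function(cfg = default_config(), verbose = FALSE) {
  pieces <- config_pieces(cfg)
  hist <- run_simulation(pieces$params, pieces$geom, pieces$scfg,
                         pieces$mat, cfg$n_xi, cfg$n_eta,
                         inlet_mode = cfg$inlet_mode,
                         maxwell_classic = cfg$maxwell_classic,
                         verbose = verbose)
  attr(hist, "config") <- cfg
  if (!is.null(cfg$out_dir)) write_outputs(hist, cfg$out_dir)
  hist
}

write_csv_schema <- function(df, path, schema) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# stenoflow ", schema, " v1"), con)
  write.table(format(df, digits = 10, scientific = TRUE, trim = TRUE),
              con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the deterministic output file set of a run
#'
#' Writes, under `dir`: a configuration echo (`config.yaml`), one
#' wall-series CSV and one station-profile CSV (stations `x = 0` and
#' `x = 2`) per snapshot, one field-snapshot CSV per snapshot (long
#' format), a run summary (`summary.yaml` with the periodicity and mass
#' conservation metrics) and a short log. Re-running the same
#' configuration reproduces the CSVs byte for byte.
#'
#' @param history a [run_case()] / [run_simulation()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_outputs <- function(history, dir) {
  if (length(history$snapshots) == 0L)
    stop("write_outputs: empty results")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(history, "config")
  if (!is.null(cfg)) save_config(cfg, file.path(dir, "config.yaml"))
  grid <- history$setup$grid
  for (sn in history$snapshots) {
    tag <- if (is.na(sn$phase)) "steady" else
      sub("\\.", "p", sprintf("%.2f", sn$phase))
    write_csv_schema(sn$wall, file.path(dir, paste0("wall_t", tag, ".csv")),
                     "wall-series")
    profs <- do.call(rbind, lapply(c(0, 2), function(xs) {
      p <- extract_profile(sn$state, grid, xs)
      cbind(x_station = attr(p, "xi"), p)
    }))
    write_csv_schema(profs, file.path(dir, paste0("profiles_t", tag, ".csv")),
                     "station-profiles")
    fields <- data.frame(xi = rep(grid$xi, grid$n_eta),
                         eta = rep(grid$eta, each = grid$n_xi),
                         psi = as.vector(sn$state$psi),
                         omega = as.vector(sn$state$omega),
                         theta = as.vector(sn$state$theta),
                         phi = as.vector(sn$state$phi_c),
                         u = as.vector(sn$state$u),
                         v = as.vector(sn$state$v))
    write_csv_schema(fields, file.path(dir, paste0("fields_t", tag, ".csv")),
                     "field-snapshot")
  }
  yaml::write_yaml(list(periodicity = history$periodicity,
                        mass_conservation_err = max(history$mass_err),
                        steady = history$steady,
                        t_end = history$final_state$t),
                   file.path(dir, "summary.yaml"))
  writeLines(sprintf("stenoflow run: t_end=%g elapsed=%.1fs poisson_sweeps/step=%.1f",
                     history$final_state$t, history$elapsed,
                     history$poisson_iter_mean),
             file.path(dir, "log.txt"))
  invisible(dir)
}

#' One-parameter sweep
#'
#' Runs a family of cases differing only in one configuration key and
#' collects the scalar trend summaries into a tidy table.
#'
#' @param cfg base `run_config`.
#' @param param name of the configuration key to vary.
#' @param values vector of values (length >= 2).
#' @param out_dir optional directory; each run is written to a subdirectory
#'   and the summary table to `sweep_summary.csv`.
#' @param verbose print progress.
#' @return A data frame with `run`, the parameter column and the
#'   [run_summary()] quantities; the histories are attached as attribute
#'   `"histories"`.
#' @export
sweep_parameter <- function(cfg = default_config("acceptance"), param,
                            values, out_dir = NULL, verbose = FALSE) {
  if (!param %in% names(cfg)) stop("sweep_parameter: unknown parameter '",
                                   param, "'")
  if (length(values) < 2) stop("sweep_parameter: need at least two values")
  hists <- vector("list", length(values))
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    ci <- cfg
    ci[[param]] <- values[i]
    ci$out_dir <- if (is.null(out_dir)) NULL else
      file.path(out_dir, sprintf("run_%02d", i))
    if (verbose) message("sweep: ", param, " = ", values[i])
    hists[[i]] <- run_case(ci, verbose = FALSE)
    rows[[i]] <- data.frame(run = i, value = values[i],
                            t(run_summary(hists[[i]])))
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "value"] <- param
  if (!is.null(out_dir))
    write_csv_schema(out, file.path(out_dir, "sweep_summary.csv"),
                     "sweep-summary")
  attr(out, "histories") <- hists
  out
}

#' Plane-channel (Poiseuille) limit check
#'
#' Steady, unconstricted, non-magnetic, non-porous, Newtonian
#' (`1/beta = 0`), particle-free run; the converged mid-channel velocity
#' profile is compared with the analytic plane-channel solution of the
#' chosen inlet mode (`6 eta (1 - eta)` for unit flux).
#'
#' @param inlet_mode inlet normalization.
#' @param n_xi,n_eta grid node counts.
#' @param dt time step (a steady run tolerates a larger step than the
#'   pulsatile default).
#' @param steady_tol early-stop tolerance on the per-step relative change.
#' @return A list with `max_rel_err`, the profiles, and the run history.
#' @export
verify_poiseuille <- function(inlet_mode = c("unit_flux", "paper_literal"),
                              n_xi = 401, n_eta = 51, dt = 5e-4,
                              steady_tol = 1e-6) {
  inlet_mode <- match.arg(inlet_mode)
  params <- suppressWarnings(
    flow_parameters(M = 0, Da = 0, beta = Inf, eps = 0, phi1 = 0, phi2 = 0))
  cfg <- solver_config(dt = dt, n_cycles = 30, steady_tol = steady_tol)
  hist <- run_simulation(params, geometry_spec(h1 = 0, h2 = 0), cfg,
                         n_xi = n_xi, n_eta = n_eta,
                         inlet_mode = inlet_mode)
  grid <- hist$setup$grid
  i0 <- which.min(abs(grid$xi))
  u <- hist$final_state$u[i0, ]
  eta <- grid$eta
  g <- hist$setup$inlet$g
  ua <- if (inlet_mode == "unit_flux") 6 * eta * (1 - eta)
  else (1 / g) * eta * (1 - eta)
  list(max_rel_err = max(abs(u - ua)) / max(abs(ua)),
       u = u, u_analytic = ua, eta = eta, history = hist)
}

# analytic transformed Laplacian of the manufactured field
# psi* = sin(pi eta) sin(k (xi - xi_min)) with exact node metrics
mms_fields <- function(grid, metrics, a_eta = 1) {
  k <- pi / (grid$xi[grid$n_xi] - grid$xi[1])
  sx <- sin(k * (grid$xi - grid$xi[1])); cx <- cos(k * (grid$xi - grid$xi[1]))
  se <- sin(pi * grid$eta); ce <- cos(pi * grid$eta)
  psi <- outer(sx, se)
  p_x  <- k * outer(cx, se)
  p_xx <- -k^2 * psi
  p_e  <- pi * outer(sx, ce)
  p_ee <- -pi^2 * psi
  p_xe <- pi * k * outer(cx, ce)
  mm <- metric_matrices(metrics, grid)
  A <- metrics$Qm^2 + a_eta * mm$Dmat^2
  B <- metrics$Pm - 2 * metrics$Qm * mm$Rmat
  L <- p_xx - B * p_e - 2 * metrics$Qm * p_xe + A * p_ee
  list(psi = psi, L = L)
}

#' Manufactured-solution verification of the elliptic operators
#'
#' Exercises the discrete transformed Laplacian and the stream-function
#' Poisson solver against the closed-form manufactured field
#' `psi* = sin(pi eta) sin(pi (xi - xi_min)/L_xi)` on a sequence of grids,
#' on both straight and constricted geometry, and reports the observed
#' convergence orders. The error is measured in the max norm over
#' `xi <= xi_max - 2.5`: the zero-gradient outflow copy is a modelling
#' boundary condition, not part of the interior scheme; it deviates from
#' the manufactured field (whose outlet slope is nonzero) by an O(1) local
#' boundary layer decaying like `exp(-pi (xi_max - xi))`, which the 2.5-unit
#' exclusion bounds below the finest grid's truncation error.
#'
#' @param grids list of `c(n_xi, n_eta)` pairs, coarse to fine (spacings
#'   should halve).
#' @param geometry a [geometry_spec()].
#' @param poisson_tol,max_iter solver settings for the manufactured solves.
#' @return A list with per-grid solve errors, operator errors, the
#'   observed orders, and `pass` (all orders >= 1.7).
#' @export
verify_manufactured <- function(grids = list(c(101, 26), c(201, 51),
                                             c(401, 101)),
                                geometry = geometry_spec(),
                                poisson_tol = 1e-9, max_iter = 50000) {
  solve_err <- op_err <- numeric(length(grids))
  for (g in seq_along(grids)) {
    grid <- build_grid(geometry, grids[[g]][1], grids[[g]][2])
    metrics <- build_metrics(grid, geometry)
    mf <- mms_fields(grid, metrics)
    interior <- grid$xi <= grid$xi[grid$n_xi] - 2.5
    # operator truncation error
    Lh <- transformed_laplacian(mf$psi, metrics, grid, 1)
    inner <- 2:(grid$n_eta - 1)
    op_err[g] <- max(abs((Lh - mf$L)[interior, inner][-1, ]))
    # full Poisson solve with omega = -L[psi*]
    psi0 <- matrix(0, grid$n_xi, grid$n_eta)
    psi0[1, ] <- mf$psi[1, ]          # walls are zero for this field
    cfg <- solver_config(poisson_tol = poisson_tol,
                         poisson_max_iter = max_iter)
    sol <- solve_poisson_psi(-mf$L, psi0, metrics, grid, cfg)
    solve_err[g] <- max(abs((sol$psi - mf$psi)[interior, ]))
  }
  ord <- function(e) {
    if (length(e) < 2) return(NA_real_)
    mean(log2(e[-length(e)] / e[-1]))
  }
  orders <- c(solve = ord(solve_err), op = ord(op_err))
  list(solve_err = solve_err, op_err = op_err, orders = orders,
       pass = all(orders >= 1.7, na.rm = TRUE))
}
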