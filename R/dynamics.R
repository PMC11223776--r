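# Time integration of cancer cells, adipocyte vertices and the pressure wall.

#' Rotational diffusion of active directions
#'
#' Advances unit direction vectors by \eqn{d\hat n = (\chi dt) \times \hat n}
#' with Gaussian angular increments of per-component variance
#' \eqn{dt/\tau_p}, renormalizing after every step, so the ensemble
#' autocorrelation decays as \eqn{\exp(-t/\tau_p)}.
#'
#' @param dirs \eqn{N \times 3} matrix of unit vectors.
#' @param dt Time step.
#' @param taup Persistence time; `Inf` freezes the directions.
#' @param nsteps Number of steps to advance.
#' @return The rotated (renormalized) direction matrix.
#' @export
update_active_directions <- function(dirs, dt, taup, nsteps = 1L) {
  if (taup <= 0) stop("taup must be positive (taup = 0 selects the passive model)")
  .cpp_rotate_dirs(as_mat3(dirs), dt, taup, as.integer(nsteps))
}

#' Integrate the equations of motion
#'
#' Advances the whole system (cancer cells, adipocyte vertices, and the
#' mobile left wall when enabled) by `nsteps` synchronized velocity-Verlet
#' steps. Damping, and the thermal noise of the passive model, are applied
#' through the exact Ornstein-Uhlenbeck velocity map in the middle of the
#' step (BAOAB splitting), so the scheme is symplectic when damping and noise
#' vanish and stable at the default step for strong damping.
#'
#' @param state A `system_state`.
#' @param params A `sim_params`.
#' @param nsteps Number of steps.
#' @param record_every Record the scalar diagnostics every this many steps
#'   (`0` records nothing).
#' @param record_vel,record_dir Also snapshot cancer-cell velocities /
#'   active directions at the recording cadence.
#' @return List with the advanced `state` and `records` (matrix with columns
#'   `t`, `kT_c`, `kT_a`, `xl`, `vl`, `P_wall`, `U`; times are relative to
#'   the input state), plus `vel` / `dir` arrays when requested.
#' @export
step_system <- function(state, params, nsteps = 1L, record_every = 0L,
                        record_vel = FALSE, record_dir = FALSE) {
  res <- .cpp_run(cpp_state(state), cpp_params(params), as.integer(nsteps),
                  as.integer(record_every), record_vel, record_dir)
  out <- absorb_cpp_state(state, res$state)
  out$time <- state$time + nsteps * params$dt
  res$records[, "t"] <- res$records[, "t"] + state$time
  list(state = out, records = res$records,
       vel = res$vel, dir = res$dir)
}

#' Kinetic temperature of a species
#'
#' \eqn{k_bT = \frac{2}{3N}\sum_q \frac{m v_q^2}{2} = \frac{m}{3N}\sum_q
#' v_q^2}, evaluated for the cancer cells or the adipocyte vertices.
#'
#' @param state A `system_state`.
#' @param species `"cancer"` or `"adipocyte"`.
#' @return Temperature in \eqn{\epsilon_c}.
#' @export
measure_temperature <- function(state, species = c("cancer", "adipocyte")) {
  species <- match.arg(species)
  v <- if (species == "cancer") state$cell_vel else state$vert_vel
  if (nrow(v) == 0) return(0)
  sum(v^2) / (3 * nrow(v))
}

#' Map activity parameters to a kinetic temperature
#'
#' Simulates a dilute, interaction-free ensemble of active cells and returns
#' the steady-state kinetic temperature, the quantity the invasion analysis
#' uses on its abscissa. In this ideal limit the temperature scales as
#' \eqn{f_0^2} and increases with the persistence time.
#'
#' @param f0 Active force magnitude.
#' @param taup Persistence time.
#' @param gamma Damping coefficient.
#' @param n Number of cells in the ensemble.
#' @param t_relax Equilibration horizon (defaults to several velocity and
#'   persistence times).
#' @param t_sample Sampling horizon.
#' @param dt Time step.
#' @return Measured \eqn{k_bT} (attribute `se` holds the standard error over
#'   recorded frames).
#' @export
calibrate_activity <- function(f0, taup, gamma = 0.2, n = 500,
                               t_relax = NULL, t_sample = NULL, dt = 0.05) {
  if (f0 == 0) return(structure(0, se = 0))
  tg <- 1 / gamma
  if (is.null(t_relax)) t_relax <- 20 * max(tg, min(taup, 1e3))
  if (is.null(t_sample)) t_sample <- 10 * max(tg, min(taup, 1e3))
  st <- free_cell_state(n, L = max(10, n^(1 / 3) * 2))
  pp <- sim_params(dt = dt, gamma = gamma, model = "active", f0 = f0,
                   taup = taup, periodic_x = TRUE, pair_forces = FALSE,
                   walls_on = FALSE)
  st$cell_dir <- random_unit_vectors(n)
  eq <- step_system(st, pp, nsteps = ceiling(t_relax / dt))
  sm <- step_system(eq$state, pp, nsteps = ceiling(t_sample / dt),
                    record_every = max(1L, ceiling(1 / dt)))
  kt <- sm$records[, "kT_c"]
  structure(mean(kt), se = sd(kt) / sqrt(length(kt)))
}

free_cell_state <- function(n, L = 20) {
  new_system_state(
    cell_pos = matrix(runif(3 * n, 0, L), n, 3),
    cell_diam = rep(c(0.9, 1.1), length.out = n),
    xl = 0, xr = L, Ly = L, Lz = L
  )
}

random_unit_vectors <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

#' Run an invasion simulation and record the invasion trace
#'
#' Integrates a (typically jammed, de-mixed) configuration at constant
#' pressure and records, at the requested cadence, the Voronoi interfacial
#' area \eqn{A_t}, its normalization \eqn{A_n} (between the de-mixed minimum
#' of the reference frame, rescaled to the instantaneous transverse
#' cross-section, and the instantaneous total adipocyte Voronoi surface
#' area), the kinetic temperatures, the box length and the measured wall
#' pressure.
#'
#' @param state Initial `system_state`.
#' @param params A `sim_params` (the left wall is made mobile).
#' @param horizon Total simulated time.
#' @param cadence Time between recorded frames.
#' @param ref_state De-mixed reference used for \eqn{A_t^{min}}; defaults to
#'   the initial state. Pass the de-mixed twin when starting from a mixed
#'   configuration.
#' @param include_walls Count cancer-wall Voronoi faces in \eqn{A_t}.
#' @return List with `trace` (data.frame: `time`, `A_t`, `A_n`, `A_t_min`,
#'   `A_t_max`, `kT_c`, `kT_a`, `L_x`, `P_wall`, `U`) and the final `state`.
#' @export
run_invasion <- function(state, params, horizon, cadence = horizon / 50,
                         ref_state = state, include_walls = TRUE) {
  params$wall_mobile <- TRUE
  steps_per <- max(1L, round(cadence / params$dt))
  n_frames <- max(1L, floor(horizon / (steps_per * params$dt)))
  ref_At <- interfacial_area(ref_state, include_walls = include_walls)
  ref_cross <- ref_state$Ly * ref_state$Lz
  frame_row <- function(st, rec = NULL) {
    At <- interfacial_area(st, include_walls = include_walls)
    Atmax <- adipocyte_surface_area(st)
    Atmin <- as.numeric(ref_At) * (st$Ly * st$Lz) / ref_cross
    data.frame(time = st$time, A_t = as.numeric(At),
               A_n = normalize_interfacial_area(At, Atmin, Atmax),
               A_t_min = Atmin, A_t_max = Atmax,
               kT_c = if (is.null(rec)) measure_temperature(st, "cancer")
                      else rec[["kT_c"]],
               kT_a = if (is.null(rec)) measure_temperature(st, "adipocyte")
                      else rec[["kT_a"]],
               L_x = st$xr - st$xl,
               P_wall = if (is.null(rec)) NA_real_ else rec[["P_wall"]],
               U = if (is.null(rec)) NA_real_ else rec[["U"]])
  }
  rows <- vector("list", n_frames + 1L)
  rows[[1]] <- frame_row(state)
  for (k in seq_len(n_frames)) {
    chunk <- step_system(state, params, nsteps = steps_per,
                         record_every = steps_per)
    state <- chunk$state
    rows[[k + 1L]] <- frame_row(state, chunk$records[1, ])
  }
  trace <- do.call(rbind, rows)
  class(trace) <- c("invasion_trace", class(trace))
  list(trace = trace, state = state)
}
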