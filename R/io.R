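# Configuration files, trajectory/state serialization, fixtures, and sweeps.

#' Save run parameters to a YAML config file
#'
#' @param params A `sim_params`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
save_config <- function(params, file) {
  yaml::write_yaml(unclass(params), file,
                   precision = 15L)
  invisible(file)
}

#' Load run parameters from a YAML config file
#'
#' @param file Path written by [save_config()].
#' @return A `sim_params`; unknown keys are rejected.
#' @export
load_config <- function(file) {
  lst <- yaml::read_yaml(file)
  known <- names(formals(sim_params))
  bad <- setdiff(names(lst), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(sim_params, lst)
}

#' Write a state as an extended-XYZ frame
#'
#' One row per particle with a species label (`C` cancer cell, `V` adipocyte
#' vertex), position, velocity, and diameter; the comment line carries the
#' box geometry and time. Frames can be appended to build a trajectory.
#'
#' @param state A `system_state`.
#' @param file Output path.
#' @param append Append as an additional frame.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(state, file, append = FALSE) {
  n <- state_counts(state)
  ntot <- n$N_c + n$N_a * n$N_v
  con <- file(file, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(as.character(ntot), con)
  writeLines(sprintf(
    'Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" xl=%.10g xr=%.10g time=%.10g Properties=species:S:1:pos:R:3:velo:R:3:diameter:R:1',
    state$xr - state$xl, state$Ly, state$Lz, state$xl, state$xr, state$time),
    con)
  fmt <- function(label, pos, vel, diam) {
    sprintf("%s %.10g %.10g %.10g %.10g %.10g %.10g %.10g", label,
            pos[, 1], pos[, 2], pos[, 3], vel[, 1], vel[, 2], vel[, 3], diam)
  }
  if (n$N_c > 0)
    writeLines(fmt("C", state$cell_pos, state$cell_vel, state$cell_diam), con)
  if (n$N_a > 0)
    writeLines(fmt("V", state$vert_pos, state$vert_vel,
                   rep(state$sigma_vertex, nrow(state$vert_pos))), con)
  invisible(file)
}

#' Save a full system state as JSON text
#'
#' Self-describing plain-text dump that round-trips exactly (full double
#' precision).
#'
#' @param state A `system_state`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
save_state <- function(state, file) {
  payload <- unclass(state)
  payload$tethers <- unclass(payload$tethers)
  # digits = I(17) guarantees bit-exact round trips of doubles
  jsonlite::write_json(payload, file, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(file)
}

#' Load a system state saved by [save_state()]
#'
#' @param file JSON path.
#' @return A `system_state`.
#' @export
load_state <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  te <- p$tethers
  tethers <- structure(list(
    pairs = face_mat(if (length(te$pairs)) te$pairs else matrix(0L, 0, 2))[,
      seq_len(2), drop = FALSE],
    offsets = face_mat(if (length(te$offsets)) te$offsets
                       else matrix(0L, 0, 2))[, seq_len(2), drop = FALSE],
    l0 = as.numeric(te$l0), Kecm = as.numeric(te$Kecm),
    d_c = if (is.null(te$d_c)) NA_real_ else as.numeric(te$d_c)
  ), class = "tether_network")
  st <- new_system_state(
    vert_pos = matrix(p$vert_pos, ncol = 3),
    vert_vel = matrix(p$vert_vel, ncol = 3),
    faces = matrix(as.integer(p$faces), ncol = 3),
    v0 = p$v0, a0 = matrix(p$a0, nrow = length(p$v0)),
    sigma_vertex = as.numeric(p$sigma_vertex), eps_v = as.numeric(p$eps_v),
    eps_a = as.numeric(p$eps_a),
    cell_pos = matrix(p$cell_pos, ncol = 3),
    cell_vel = matrix(p$cell_vel, ncol = 3),
    cell_dir = matrix(p$cell_dir, ncol = 3),
    cell_diam = p$cell_diam,
    xl = as.numeric(p$xl), xr = as.numeric(p$xr), vl = as.numeric(p$vl),
    Ly = as.numeric(p$Ly), Lz = as.numeric(p$Lz),
    tethers = tethers,
    time = if (is.null(p$time)) 0 else as.numeric(p$time)
  )
  st
}

#' Deterministic small fixtures for tests and examples
#'
#' @param name One of `"single_adipocyte"` (a reference-calibrated shape with
#'   zero shape energy), `"cancer_dimer"` (two cells at the maximum-attraction
#'   separation, returned with the matching `sim_params`),
#'   `"mini_box"` (a dilute de-mixed state with 4 adipocytes and 120 cells),
#'   `"planar_interface"` (two lattice slabs of seeds meeting at a plane, for
#'   tessellation checks), or `"cubic_tether_lattice"` (centres on a cubic
#'   lattice).
#' @param seed RNG seed applied before stochastic construction.
#' @return The fixture object (type depends on `name`).
#' @export
make_fixture <- function(name = c("single_adipocyte", "cancer_dimer",
                                  "mini_box", "planar_interface",
                                  "cubic_tether_lattice"),
                         seed = 1L) {
  name <- match.arg(name)
  set.seed(seed)
  switch(name,
    single_adipocyte = {
      mesh <- build_icosphere(1, radius = 2)
      # calibrated to its own shape so the current mesh is the zero of energy
      make_reference_shape(mesh, target_A0 = shape_parameter(mesh))
    },
    cancer_dimer = {
      beta <- 1e-2
      sep <- (1 + beta)  # r_beta for two unit-diameter cells
      st <- new_system_state(
        cell_pos = rbind(c(10 - sep / 2, 10, 10), c(10 + sep / 2, 10, 10)),
        cell_diam = c(1, 1), xl = 0, xr = 20, Ly = 20, Lz = 20)
      list(state = st, params = sim_params(beta = beta))
    },
    mini_box = place_demixed(init_config(N_a = 4, N_c = 120)),
    planar_interface = {
      # slab of "cancer" seeds against a slab of "adipocyte" seeds; the
      # tessellated interface must approximate the Ly x Lz midplane
      sp <- 1
      gr <- as.matrix(expand.grid(x = sp * (1:8) - sp / 2,
                                  y = sp * (1:6) - sp / 2,
                                  z = sp * (1:6) - sp / 2))
      dimnames(gr) <- NULL
      grp <- ifelse(gr[, 1] < 4, -1L, 0L)
      list(points = gr, radii = rep(0.5, nrow(gr)), group = as.integer(grp),
           xl = 0, xr = 8, Ly = 6, Lz = 6, interface_x = 4)
    },
    cubic_tether_lattice = {
      sp <- 1
      gr <- as.matrix(expand.grid(x = sp * (1:4) - sp / 2,
                                  y = sp * (0:2),
                                  z = sp * (0:2)))
      dimnames(gr) <- NULL
      list(centers = gr, spacing = sp, Ly = 3 * sp, Lz = 3 * sp,
           xl = 0, xr = 4 * sp)
    })
}

#' Run an invasion sweep over a grid of conditions
#'
#' Executes one scaled invasion run per row of `grid` (columns may override
#' `f0`, `T0`, `taup`, `beta`, `gamma`, `Kecm`, `seed`), starting each run
#' from the supplied jammed state, and collects steady-state observables.
#'
#' @param grid data.frame of conditions; missing columns fall back to
#'   `base_params`.
#' @param state Jammed, de-mixed starting `system_state`.
#' @param base_params Baseline `sim_params`.
#' @param horizon,cadence Invasion run schedule (see [run_invasion()]).
#' @param steady_frac Final fraction of the trace averaged as "steady state".
#' @return data.frame: the grid plus `A_n`, `A_t`, `kT_c`, `kT_a`, `L_x`.
#' @export
sweep_conditions <- function(grid, state, base_params = sim_params(),
                             horizon = 500, cadence = horizon / 20,
                             steady_frac = 0.25) {
  if (nrow(grid) == 0)
    return(cbind(grid, A_n = numeric(0), A_t = numeric(0),
                 kT_c = numeric(0), kT_a = numeric(0), L_x = numeric(0)))
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    pp <- base_params
    for (f in intersect(names(grid), c("f0", "T0", "taup", "beta", "gamma")))
      pp[[f]] <- grid[[f]][r]
    pp$model <- if (pp$taup > 0) "active" else "passive"
    st <- state
    if ("Kecm" %in% names(grid)) st$tethers$Kecm <- grid[["Kecm"]][r]
    if ("seed" %in% names(grid)) set.seed(grid[["seed"]][r])
    run <- run_invasion(st, pp, horizon = horizon, cadence = cadence)
    tr <- run$trace
    tail_rows <- tr[tr$time >= max(tr$time) * (1 - steady_frac), ,
                    drop = FALSE]
    out[[r]] <- data.frame(A_n = mean(tail_rows$A_n),
                           A_t = mean(tail_rows$A_t),
                           kT_c = mean(tail_rows$kT_c),
                           kT_a = mean(tail_rows$kT_a),
                           L_x = mean(tail_rows$L_x))
  }
  cbind(grid, do.call(rbind, out))
}

#' Convert reduced units to physical units
#'
#' Helper for reporting only: given the physical cancer-cell diameter and
#' energy scale, prints conversions for length, energy, force and pressure.
#' Never enters any computation.
#'
#' @param sigma_um Mean cancer-cell diameter in micrometres.
#' @param eps_J Repulsive energy scale in joules.
#' @return Named vector of conversion factors.
#' @export
unit_conversions <- function(sigma_um = 15, eps_J = 1e-15) {
  c(length_um = sigma_um,
    area_um2 = sigma_um^2,
    volume_um3 = sigma_um^3,
    energy_J = eps_J,
    force_nN = eps_J / (sigma_um * 1e-6) * 1e9,
    pressure_Pa = eps_J / (sigma_um * 1e-6)^3)
}
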