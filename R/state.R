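# System state container and run parameters.

#' Construct a system state
#'
#' Assembles the full simulation configuration at one instant: adipocyte
#' vertex positions/velocities with their shared mesh topology and reference
#' shape, cancer-cell positions/velocities/diameters/active directions, wall
#' positions, transverse box lengths, and the tether network. Positions are
#' continuous (never wrapped); the minimum-image convention in the periodic
#' y and z directions is applied inside the force and tessellation kernels.
#'
#' @param vert_pos,vert_vel Vertex coordinate matrices
#'   (\eqn{N_a N_v \times 3}).
#' @param faces Shared \eqn{N_f \times 3} face index matrix (1-based).
#' @param v0 Preferred volumes (length \eqn{N_a}).
#' @param a0 Preferred face areas (\eqn{N_a \times N_f}).
#' @param sigma_vertex Vertex-sphere diameter.
#' @param eps_v,eps_a Volume and area stiffnesses.
#' @param cell_pos,cell_vel,cell_dir Cancer-cell coordinate matrices
#'   (\eqn{N_c \times 3}).
#' @param cell_diam Cancer-cell diameters (length \eqn{N_c}).
#' @param xl,xr,vl Wall positions and left-wall velocity.
#' @param Ly,Lz Periodic transverse box lengths.
#' @param tethers A `tether_network` or `NULL`.
#' @param time Elapsed simulation time.
#' @return A `system_state` object.
#' @export
new_system_state <- function(vert_pos = matrix(0, 0, 3),
                             vert_vel = matrix(0, nrow(vert_pos), 3),
                             faces = matrix(integer(0), 0, 3),
                             v0 = numeric(0),
                             a0 = matrix(0, length(v0), nrow(faces)),
                             sigma_vertex = 2, eps_v = 1e3, eps_a = 10,
                             cell_pos = matrix(0, 0, 3),
                             cell_vel = matrix(0, nrow(cell_pos), 3),
                             cell_dir = default_dirs(nrow(cell_pos)),
                             cell_diam = numeric(0),
                             xl = 0, xr = 1, vl = 0, Ly = 1, Lz = 1,
                             tethers = NULL, time = 0) {
  if (is.null(tethers)) tethers <- empty_tethers()
  st <- structure(list(
    vert_pos = as_mat3(vert_pos), vert_vel = as_mat3(vert_vel),
    faces = face_mat(faces), v0 = as.numeric(v0),
    a0 = matrix(as.numeric(a0), length(v0), nrow(face_mat(faces))),
    sigma_vertex = sigma_vertex, eps_v = eps_v, eps_a = eps_a,
    cell_pos = as_mat3(cell_pos), cell_vel = as_mat3(cell_vel),
    cell_dir = as_mat3(cell_dir), cell_diam = as.numeric(cell_diam),
    xl = xl, xr = xr, vl = vl, Ly = Ly, Lz = Lz,
    tethers = tethers, time = time
  ), class = "system_state")
  validate_state(st)
  st
}

as_mat3 <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  stopifnot(ncol(x) == 3 || nrow(x) == 0)
  if (nrow(x) == 0) x <- matrix(0, 0, 3)
  x
}

face_mat <- function(f) {
  f <- as.matrix(f)
  storage.mode(f) <- "integer"
  dimnames(f) <- NULL
  if (nrow(f) == 0) f <- matrix(integer(0), 0, 3)
  f
}

default_dirs <- function(n) {
  if (n == 0) return(matrix(0, 0, 3))
  matrix(rep(c(1, 0, 0), each = n), n, 3)
}

empty_tethers <- function() {
  structure(list(pairs = matrix(integer(0), 0, 2),
                 offsets = matrix(integer(0), 0, 2),
                 l0 = numeric(0), Kecm = 0, d_c = NA_real_),
            class = "tether_network")
}

validate_state <- function(st) {
  na <- length(st$v0)
  if (na > 0) {
    if (nrow(st$vert_pos) %% na != 0)
      stop("vertex count is not a multiple of the number of adipocytes")
  }
  if (st$xl >= st$xr) stop("left wall must lie below the right wall")
  if (nrow(st$cell_pos) != length(st$cell_diam))
    stop("cell_pos and cell_diam disagree on the number of cancer cells")
  invisible(st)
}

#' Counts of the constituents of a state
#'
#' @param state A `system_state`.
#' @return Named list: `N_a` adipocytes, `N_v` vertices per adipocyte,
#'   `N_f` faces per adipocyte, `N_c` cancer cells.
#' @export
state_counts <- function(state) {
  na <- length(state$v0)
  list(N_a = na,
       N_v = if (na > 0) nrow(state$vert_pos) %/% na else 0L,
       N_f = nrow(state$faces),
       N_c = nrow(state$cell_pos))
}

#' Adipocyte centres of mass
#'
#' Mean of the (unwrapped) vertex positions of each adipocyte.
#'
#' @param state A `system_state`.
#' @return \eqn{N_a \times 3} matrix.
#' @export
adipocyte_centers <- function(state) {
  n <- state_counts(state)
  if (n$N_a == 0) return(matrix(0, 0, 3))
  g <- rep(seq_len(n$N_a), each = n$N_v)
  out <- rowsum(state$vert_pos, g) / n$N_v
  dimnames(out) <- NULL
  out
}

#' Simulation run parameters
#'
#' Collects every knob of the equations of motion in reduced units
#' (\eqn{\epsilon_c = \sigma = m = 1}).
#'
#' @param dt Integration time step (default 0.05; larger values trigger a
#'   warning).
#' @param gamma Damping coefficient for cells, vertices and the mobile wall.
#' @param alpha Range of the cancer-cancer attraction (force is zero beyond
#'   \eqn{r_\alpha/\sigma_{qs} = 1 + \alpha}).
#' @param beta Depth of the cancer-cancer attraction (maximum attractive
#'   force \eqn{\epsilon_c \beta/\sigma_{qs}} at
#'   \eqn{r_\beta/\sigma_{qs} = 1+\beta}); `0` disables cohesion. Must be
#'   below `alpha`.
#' @param model `"auto"` (passive when `taup == 0`, active otherwise),
#'   `"active"` (self-propulsion `f0` along a rotationally diffusing
#'   direction) or `"passive"` (Langevin noise at target temperature `T0`).
#' @param f0 Active force magnitude.
#' @param T0 Target temperature of the passive thermostat.
#' @param taup Persistence time of the active direction; `0` selects the
#'   passive model.
#' @param P Imposed pressure on the mobile left wall.
#' @param wall_mobile Integrate the left wall (constant-pressure boundary)?
#' @param periodic_x Fully periodic box (no walls), used for dilute
#'   cancer-cell-only studies.
#' @param pair_forces Evaluate interparticle forces? (`FALSE` gives an ideal,
#'   interaction-free ensemble for activity calibration.)
#' @param walls_on Evaluate wall-particle repulsion?
#' @return A `sim_params` object.
#' @export
sim_params <- function(dt = 0.05, gamma = 0.2, alpha = 0.2, beta = 0,
                       model = c("auto", "active", "passive"),
                       f0 = 0, T0 = 0, taup = 0, P = 1.3e-3,
                       wall_mobile = FALSE, periodic_x = FALSE,
                       pair_forces = TRUE, walls_on = TRUE) {
  model <- match.arg(model)
  if (model == "auto") model <- if (taup > 0) "active" else "passive"
  if (beta < 0 || beta >= alpha)
    stop("attraction depth must satisfy 0 <= beta < alpha")
  if (model == "active" && taup <= 0)
    stop("the active model needs a positive persistence time taup")
  if (dt > 0.05 + 1e-12)
    warning("time step above 0.05 may be unstable for stiff shape energies")
  structure(list(dt = dt, gamma = gamma, alpha = alpha, beta = beta,
                 model = model, f0 = f0, T0 = T0, taup = taup, P = P,
                 wall_mobile = wall_mobile, periodic_x = periodic_x,
                 pair_forces = pair_forces, walls_on = walls_on),
            class = "sim_params")
}

# marshal params for the compiled kernels
cpp_params <- function(p) {
  list(dt = p$dt, gamma = p$gamma, alpha = p$alpha, beta = p$beta,
       model = if (p$model == "active") 1L else 0L,
       f0 = p$f0, T0 = p$T0, taup = p$taup, P = p$P,
       wall_mobile = isTRUE(p$wall_mobile),
       periodic_x = isTRUE(p$periodic_x),
       pair_forces = isTRUE(p$pair_forces),
       walls_on = isTRUE(p$walls_on))
}

# marshal a system_state for the compiled kernels (drops the time field)
cpp_state <- function(st) {
  st[c("vert_pos", "vert_vel", "faces", "v0", "a0", "sigma_vertex",
       "eps_v", "eps_a", "cell_pos", "cell_vel", "cell_dir", "cell_diam",
       "xl", "xr", "vl", "Ly", "Lz", "tethers")]
}

# fold a modified cpp state back into the R object
absorb_cpp_state <- function(st, cs) {
  keep_tethers <- st$tethers
  for (f in c("vert_pos", "vert_vel", "cell_pos", "cell_vel", "cell_dir",
              "xl", "xr", "vl")) st[[f]] <- cs[[f]]
  st$tethers <- keep_tethers
  st
}
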