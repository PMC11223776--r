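# De-mixed placement, athermal quasistatic compression, packing-fraction
# bookkeeping, and the heterogeneity protocol.

#' Initialization configuration
#'
#' Collects the de-mixed placement protocol: counts, the dilute starting
#' packing fraction that fixes the initial cubic box, and the placement bands
#' along x. The bands default to the fractions of the box corresponding to
#' cancer centres between 2 and 12 sigma and adipocyte centres between 16
#' and 68 sigma in a 70-sigma box, and scale with the box at other sizes.
#'
#' @param N_a,N_c Numbers of adipocytes and cancer cells.
#' @param phi_init Dilute starting packing fraction (default 0.01); the
#'   initial cubic box length follows from the particle volumes.
#' @param target_A0 Reference shape parameter for adipocytes.
#' @param mesh_radius Radius of the adipocyte icosphere; together with the
#'   vertex diameter this makes the adipocyte about 6 cancer diameters wide.
#' @param sigma_vertex Vertex-sphere diameter.
#' @param eps_v,eps_a Shape-energy stiffnesses.
#' @param cancer_band,adip_band x-placement bands as fractions of the box
#'   length.
#' @param compression_step Relative packing-fraction increment per
#'   compression step.
#' @param target_phi Final total packing fraction of the compression.
#' @param tol Force tolerance of the energy minimizer.
#' @return An `init_config` list.
#' @export
init_config <- function(N_a = 28, N_c = 1500, phi_init = 0.01,
                        target_A0 = 1.1, mesh_radius = 2, sigma_vertex = 2,
                        eps_v = 1e3, eps_a = 10,
                        cancer_band = c(2, 12) / 70,
                        adip_band = c(16, 68) / 70,
                        compression_step = 0.03, target_phi = 0.72,
                        tol = 1e-8) {
  stopifnot(N_a >= 0, N_c >= 0, phi_init > 0,
            cancer_band[1] < cancer_band[2],
            adip_band[1] < adip_band[2],
            cancer_band[2] <= adip_band[1])  # de-mixed bands must be disjoint
  structure(as.list(environment()), class = "init_config")
}

#' Place a dilute de-mixed configuration
#'
#' Rejection-samples non-overlapping positions: cancer cells (bidisperse,
#' exactly half 0.9 and half 1.1 sigma, order shuffled by the run seed) in
#' the low-x band, randomly oriented reference-shape adipocytes in the
#' high-x band. The cubic box length follows from `phi_init`; the smooth
#' planar interface between the bands is the de-mixed starting point of every
#' invasion run.
#'
#' @param cfg An [init_config()].
#' @param max_attempts Rejection-sampling cap per particle.
#' @return A `system_state` with zero velocities and zero potential energy
#'   (no overlaps).
#' @export
place_demixed <- function(cfg, max_attempts = 5e4) {
  mesh <- build_icosphere(1, radius = cfg$mesh_radius)
  shp <- make_reference_shape(mesh, cfg$target_A0, cfg$eps_v, cfg$eps_a,
                              cfg$sigma_vertex)
  # insert adipocytes at their zero-energy (buckled) reference configuration
  shp <- relax_shape(shp, tol = cfg$tol)
  shp$mesh$vertices <- sweep(shp$mesh$vertices, 2,
                             colMeans(shp$mesh$vertices))
  v_adip <- shp$v0 + nrow(mesh$vertices) * 0.5 * pi / 6 * cfg$sigma_vertex^3
  diam <- sample(rep(c(0.9, 1.1), length.out = cfg$N_c))
  v_tot <- cfg$N_a * v_adip + pi / 6 * sum(diam^3)
  L0 <- (v_tot / cfg$phi_init)^(1 / 3)

  # cancer cells: no mutual overlap
  cband <- cfg$cancer_band * L0
  cpos <- matrix(0, cfg$N_c, 3)
  nplaced <- 0
  for (q in seq_len(cfg$N_c)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- c(runif(1, max(cband[1], diam[q] / 2),
                   min(cband[2], L0 - diam[q] / 2)),
             runif(1, 0, L0), runif(1, 0, L0))
      if (nplaced > 0) {
        dx <- cpos[seq_len(nplaced), 1] - p[1]
        dy <- min_image_r(cpos[seq_len(nplaced), 2] - p[2], L0)
        dz <- min_image_r(cpos[seq_len(nplaced), 3] - p[3], L0)
        if (any(dx^2 + dy^2 + dz^2 <
                ((diam[seq_len(nplaced)] + diam[q]) / 2)^2)) next
      }
      cpos[q, ] <- p
      nplaced <- nplaced + 1
      ok <- TRUE
      break
    }
    if (!ok) stop("cancer-cell placement failed; lower phi_init or N_c")
  }

  # adipocytes: centres at least one adipocyte diameter apart
  R_out <- max(sqrt(rowSums(shp$mesh$vertices^2))) + cfg$sigma_vertex / 2
  aband <- cfg$adip_band * L0
  acent <- matrix(0, cfg$N_a, 3)
  for (i in seq_len(cfg$N_a)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- c(runif(1, max(aband[1], R_out), min(aband[2], L0 - R_out)),
             runif(1, 0, L0), runif(1, 0, L0))
      if (i > 1) {
        dx <- acent[seq_len(i - 1), 1] - p[1]
        dy <- min_image_r(acent[seq_len(i - 1), 2] - p[2], L0)
        dz <- min_image_r(acent[seq_len(i - 1), 3] - p[3], L0)
        if (any(dx^2 + dy^2 + dz^2 < (2 * R_out)^2)) next
      }
      acent[i, ] <- p
      ok <- TRUE
      break
    }
    if (!ok) stop("adipocyte placement failed; lower phi_init or N_a")
  }
  vert <- do.call(rbind, lapply(seq_len(cfg$N_a), function(i) {
    sweep(shp$mesh$vertices %*% random_rotation(), 2, acent[i, ], "+")
  }))
  if (cfg$N_a == 0) vert <- matrix(0, 0, 3)

  new_system_state(
    vert_pos = vert, faces = mesh$faces,
    v0 = rep(shp$v0, cfg$N_a),
    a0 = matrix(shp$a0, cfg$N_a, nrow(mesh$faces), byrow = TRUE),
    sigma_vertex = cfg$sigma_vertex, eps_v = cfg$eps_v, eps_a = cfg$eps_a,
    cell_pos = cpos, cell_dir = random_unit_vectors(cfg$N_c),
    cell_diam = diam,
    xl = 0, xr = L0, Ly = L0, Lz = L0
  )
}

min_image_r <- function(d, L) d - L * round(d / L)

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Packing fractions of a state
#'
#' Total particle volume over box volume, split by species:
#' \eqn{\phi = \phi_c + \phi_a} exactly. Each adipocyte contributes its mesh
#' volume plus the protruding halves of its vertex spheres.
#'
#' @param state A `system_state`.
#' @return Named vector `c(phi, phi_a, phi_c)`.
#' @export
packing_fractions <- function(state) {
  n <- state_counts(state)
  vbox <- (state$xr - state$xl) * state$Ly * state$Lz
  vc <- pi / 6 * sum(state$cell_diam^3)
  va <- 0
  if (n$N_a > 0) {
    for (i in seq_len(n$N_a)) {
      rows <- ((i - 1) * n$N_v + 1):(i * n$N_v)
      va <- va + .cpp_mesh_volume(state$vert_pos[rows, , drop = FALSE],
                                  state$faces)
    }
    va <- va + n$N_a * n$N_v * 0.5 * pi / 6 * state$sigma_vertex^3
  }
  c(phi = (va + vc) / vbox, phi_a = va / vbox, phi_c = vc / vbox)
}

#' Minimize the potential energy of a state
#'
#' FIRE minimization over all adipocyte vertices and cancer cells with the
#' walls held fixed, until the maximum per-degree-of-freedom force drops
#' below `tol`. Velocities are zeroed on exit.
#'
#' @param state A `system_state`.
#' @param params Interaction parameters (`sim_params`); damping/activity
#'   fields are ignored by the minimizer.
#' @param tol Force tolerance in \eqn{\epsilon_c/\sigma}.
#' @param max_iter Iteration cap; non-convergence is reported via the
#'   `converged`/`residual` attributes rather than an error.
#' @return The minimized state with attributes `residual`, `iterations`,
#'   `converged`, `potential`.
#' @export
minimize_energy <- function(state, params = sim_params(), tol = 1e-8,
                            max_iter = 2e5) {
  res <- .cpp_fire(cpp_state(state), cpp_params(params), tol,
                   as.integer(max_iter), 0.002, 0.05)
  out <- absorb_cpp_state(state, res$state)
  attr(out, "residual") <- res$residual
  attr(out, "iterations") <- res$iterations
  attr(out, "converged") <- res$converged
  attr(out, "potential") <- res$potential
  if (!res$converged)
    warning("energy minimization stopped at residual ", signif(res$residual, 3))
  out
}

#' Athermal quasistatic compression to a target packing fraction
#'
#' Alternates affine compression steps that raise the packing fraction by
#' `step` (relative) with FIRE energy minimizations, until the total packing
#' fraction reaches `target_phi`; the final step is truncated to land on the
#' target. Box lengths and walls shrink isotropically; adipocytes translate
#' rigidly with their centres (their shape is restored by the minimization),
#' cancer cells move affinely.
#'
#' @param state A dilute, de-mixed `system_state`.
#' @param target_phi Stopping packing fraction (default 0.72).
#' @param step Relative packing-fraction increment per step (default 0.03).
#' @param params Interaction parameters.
#' @param tol,max_iter Minimizer settings per step.
#' @return The jammed state; attribute `phi_history` traces the protocol.
#' @export
compress_to_phi <- function(state, target_phi = 0.72, step = 0.03,
                            params = sim_params(), tol = 1e-8,
                            max_iter = 2e5) {
  phi <- packing_fractions(state)[["phi"]]
  hist <- phi
  while (phi < target_phi - 1e-12) {
    phi_next <- min(phi * (1 + step), target_phi)
    s <- (phi / phi_next)^(1 / 3)
    state <- affine_rescale(state, sx = s, syz = s)
    state <- minimize_energy(state, params, tol, max_iter)
    phi <- packing_fractions(state)[["phi"]]
    hist <- c(hist, phi)
  }
  attr(state, "phi_history") <- hist
  state
}

# affine rescale of the box: x by sx about xl, y/z by syz about 0.
# Adipocytes translate rigidly with their centres of mass.
affine_rescale <- function(state, sx = 1, syz = 1) {
  n <- state_counts(state)
  if (n$N_a > 0) {
    cen <- adipocyte_centers(state)
    newc <- cbind(state$xl + (cen[, 1] - state$xl) * sx,
                  cen[, 2] * syz, cen[, 3] * syz)
    shift <- newc - cen
    state$vert_pos <- state$vert_pos +
      shift[rep(seq_len(n$N_a), each = n$N_v), ]
  }
  if (n$N_c > 0) {
    state$cell_pos[, 1] <- state$xl + (state$cell_pos[, 1] - state$xl) * sx
    state$cell_pos[, 2:3] <- state$cell_pos[, 2:3] * syz
  }
  state$xr <- state$xl + (state$xr - state$xl) * sx
  state$Ly <- state$Ly * syz
  state$Lz <- state$Lz * syz
  # rest lengths refer to the same material springs; rescaling the box does
  # not change them (they are re-set when a network is rebuilt)
  state
}

#' Rescale the box length to a target adipocyte packing fraction
#'
#' Changes the x-extent of the box affinely (walls, cancer cells, adipocyte
#' centres) and re-minimizes, so that \eqn{\phi_a} matches `target_phi_a`.
#'
#' @param state A jammed `system_state`.
#' @param target_phi_a Target adipocyte packing fraction.
#' @param params,tol,max_iter Minimizer settings.
#' @return The rescaled, minimized state.
#' @export
rescale_to_phi_a <- function(state, target_phi_a, params = sim_params(),
                             tol = 1e-8, max_iter = 2e5) {
  phia <- packing_fractions(state)[["phi_a"]]
  state <- affine_rescale(state, sx = phia / target_phi_a, syz = 1)
  minimize_energy(state, params, tol, max_iter)
}

#' Impose packing-fraction heterogeneity on a tether network
#'
#' Splits the adipocytes into two equal groups at the median z of their
#' centres and resets the rest lengths of springs lying wholly inside the
#' low-z (tight) group to \eqn{(1-\lambda)R_{ij}} and wholly inside the
#' high-z (loose) group to \eqn{(1+\lambda)R_{ij}}, where \eqn{R_{ij}} are
#' the current separations; springs crossing the groups keep \eqn{R_{ij}}
#' (configurable).
#'
#' @param network A `tether_network`.
#' @param state The `system_state` the network was built on.
#' @param lambda Heterogeneity amplitude in \eqn{[0, 1]}.
#' @param cross `"keep"` (rest length \eqn{R_{ij}}) or `"mean"` (scale by the
#'   mean of the two group factors, which equals `keep` for this symmetric
#'   split).
#' @return The network with updated rest lengths; attribute `groups` records
#'   the group label of every adipocyte.
#' @export
apply_heterogeneity <- function(network, state, lambda, cross = "keep") {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  centers <- adipocyte_centers(state)
  zrank <- rank(centers[, 3], ties.method = "first")
  tight <- zrank <= nrow(centers) / 2
  R <- current_tether_lengths(network, state)
  g1 <- tight[network$pairs[, 1]]
  g2 <- tight[network$pairs[, 2]]
  fac <- ifelse(g1 & g2, 1 - lambda, ifelse(!g1 & !g2, 1 + lambda, 1))
  network$l0 <- fac * R
  attr(network, "groups") <- ifelse(tight, "tight", "loose")
  network
}

current_tether_lengths <- function(network, state) {
  centers <- adipocyte_centers(state)
  if (nrow(network$pairs) == 0) return(numeric(0))
  dvec <- centers[network$pairs[, 1], , drop = FALSE] -
    centers[network$pairs[, 2], , drop = FALSE]
  dvec[, 2] <- dvec[, 2] + network$offsets[, 1] * state$Ly
  dvec[, 3] <- dvec[, 3] + network$offsets[, 2] * state$Lz
  sqrt(rowSums(dvec^2))
}

#' Standard deviation of the local adipocyte packing fraction
#'
#' Tessellates the adipocyte centres (unweighted Voronoi, periodic in y/z,
#' wall planes in x), assigns each adipocyte the local packing fraction
#' \eqn{V_i / V^{vor}_i}, and returns the population standard deviation.
#'
#' @param state A `system_state` with at least 2 adipocytes.
#' @return \eqn{\Delta\phi_a}; attribute `local_phi` carries the per-cell
#'   values.
#' @export
local_packing_std <- function(state) {
  n <- state_counts(state)
  if (n$N_a < 2) stop("local packing statistics need at least 2 adipocytes")
  centers <- adipocyte_centers(state)
  centers[, 2] <- centers[, 2] %% state$Ly
  centers[, 3] <- centers[, 3] %% state$Lz
  res <- .cpp_power_cells(centers, rep(0, n$N_a),
                          as.integer(seq_len(n$N_a) - 1L),
                          state$xl, state$xr, state$Ly, state$Lz, FALSE)
  if (any(res$volumes <= 0)) stop("degenerate tessellation of adipocyte centres")
  vi <- vapply(seq_len(n$N_a), function(i) {
    rows <- ((i - 1) * n$N_v + 1):(i * n$N_v)
    .cpp_mesh_volume(state$vert_pos[rows, , drop = FALSE], state$faces) +
      n$N_v * 0.5 * pi / 6 * state$sigma_vertex^3
  }, numeric(1))
  local_phi <- vi / res$volumes
  out <- sqrt(mean((local_phi - mean(local_phi))^2))
  attr(out, "local_phi") <- local_phi
  out
}
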