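# Pair forces, wall forces, the ECM tether network, and the force assembler.

#' Repulsive force between two adipocyte vertices
#'
#' Linear spring in the overlap: magnitude
#' \eqn{(\epsilon_c/\tilde\sigma)(1 - r/\tilde\sigma)} along the separation
#' for \eqn{r \le \tilde\sigma = (\sigma_{i\mu}+\sigma_{j\nu})/2}, zero
#' beyond; continuous at contact.
#'
#' @param r_vec Separation vector from the second to the first vertex.
#' @param sigma_i,sigma_j Vertex diameters.
#' @return Force on the first vertex (3-vector); the reaction on the second
#'   is equal and opposite. A zero separation yields a zero force with a
#'   warning (undefined direction).
#' @export
vertex_vertex_force <- function(r_vec, sigma_i, sigma_j) {
  st <- (sigma_i + sigma_j) / 2
  repulsive_force(r_vec, st)
}

#' Repulsive force on an adipocyte vertex from a cancer cell
#'
#' Same linear-spring form as [vertex_vertex_force()] with
#' \eqn{\tilde\sigma = (\sigma_{i\mu} + \sigma_q)/2}.
#'
#' @param r_vec Separation vector from the cancer cell to the vertex.
#' @param sigma_vertex Vertex diameter.
#' @param sigma_q Cancer-cell diameter.
#' @return Force on the vertex (3-vector).
#' @export
vertex_cancer_force <- function(r_vec, sigma_vertex, sigma_q) {
  repulsive_force(r_vec, (sigma_vertex + sigma_q) / 2)
}

repulsive_force <- function(r_vec, st) {
  r <- sqrt(sum(r_vec^2))
  if (r == 0) {
    warning("coincident centres: overlap pathology, returning zero force")
    return(c(0, 0, 0))
  }
  if (r > st) return(c(0, 0, 0))
  (1 / st) * (1 - r / st) * r_vec / r
}

#' Cohesive-repulsive force between two cancer cells
#'
#' Piecewise-linear force: the repulsive spring continues through contact into
#' an attractive branch down to the maximum attractive force
#' \eqn{\epsilon_c\beta/\sigma_{qs}} at \eqn{r_\beta = (1+\beta)\sigma_{qs}},
#' then returns linearly to zero at \eqn{r_\alpha = (1+\alpha)\sigma_{qs}};
#' continuous at every branch boundary.
#'
#' @param r_vec Separation vector from cell s to cell q.
#' @param sigma_q,sigma_s Diameters.
#' @param alpha Attraction range.
#' @param beta Attraction depth (`0 <= beta < alpha`).
#' @return Force on cell q (3-vector).
#' @export
cancer_cancer_force <- function(r_vec, sigma_q, sigma_s, alpha = 0.2,
                                beta = 0) {
  st <- (sigma_q + sigma_s) / 2
  r <- sqrt(sum(r_vec^2))
  if (r == 0) {
    warning("coincident centres: overlap pathology, returning zero force")
    return(c(0, 0, 0))
  }
  if (beta <= 0) return(repulsive_force(r_vec, st))
  r_beta <- st * (1 + beta)
  r_alpha <- st * (1 + alpha)
  if (r > r_alpha) return(c(0, 0, 0))
  g <- if (r <= r_beta) (1 / st) * (1 - r / st)
       else beta * (r - r_alpha) / ((alpha - beta) * st^2)
  g * r_vec / r
}

#' Wall force on a particle
#'
#' One-dimensional repulsive spring along x, active when the particle centre
#' is within one particle diameter of the wall plane and pushing away from it.
#'
#' @param x Particle x-coordinate.
#' @param wall_x Wall plane position.
#' @param diameter Particle diameter (sets both range and stiffness scale).
#' @param side `"left"` (wall below the particle, force in +x) or
#'   `"right"`.
#' @return Signed x-force on the particle; the reaction on the wall is equal
#'   and opposite.
#' @export
wall_force <- function(x, wall_x, diameter, side = c("left", "right")) {
  side <- match.arg(side)
  d <- if (side == "left") x - wall_x else wall_x - x
  if (d > diameter) return(0)
  g <- (1 / diameter) * (1 - d / diameter)
  if (side == "left") g else -g
}

#' Build the ECM tether network over adipocyte centres
#'
#' Connects adipocyte pairs whose centre-of-mass distance (minimum image in
#' the periodic directions) is below a threshold \eqn{d_c} calibrated so the
#' mean number of tethered neighbours per adipocyte is 6: the smallest
#' \eqn{d_c} whose mean degree is at least the target. Rest lengths are set
#' to the current separations, and each pair's periodic image offset is
#' frozen so long springs remain well defined.
#'
#' @param state A `system_state` with at least 2 adipocytes (fewer yields an
#'   empty network).
#' @param Kecm Spring stiffness in \eqn{\epsilon_c} (default 0.04).
#' @param target_degree Desired mean neighbours per adipocyte (default 6).
#' @return A `tether_network`: `pairs`, `offsets`, `l0`, `Kecm`, `d_c`.
#' @export
build_tether_network <- function(state, Kecm = 0.04, target_degree = 6) {
  centers <- adipocyte_centers(state)
  na <- nrow(centers)
  if (na < 2) return(empty_tethers())
  pr <- t(utils::combn(na, 2))
  dx <- centers[pr[, 1], 1] - centers[pr[, 2], 1]
  dy <- centers[pr[, 1], 2] - centers[pr[, 2], 2]
  dz <- centers[pr[, 1], 3] - centers[pr[, 2], 3]
  oy <- -round(dy / state$Ly)
  oz <- -round(dz / state$Lz)
  dy <- dy + oy * state$Ly
  dz <- dz + oz * state$Lz
  d <- sqrt(dx^2 + dy^2 + dz^2)
  n_edges <- min(nrow(pr), ceiling(target_degree * na / 2))
  d_c <- sort(d)[n_edges]
  keep <- which(d <= d_c)
  structure(list(pairs = face_mat(pr[keep, , drop = FALSE])[, 1:2,
                                                            drop = FALSE],
                 offsets = matrix(as.integer(cbind(oy[keep], oz[keep])),
                                  length(keep), 2),
                 l0 = d[keep], Kecm = Kecm, d_c = d_c),
            class = "tether_network")
}

#' Mean tether degree of a network
#'
#' @param network A `tether_network`.
#' @param N_a Number of adipocytes.
#' @return Mean number of tethered neighbours per adipocyte.
#' @export
mean_tether_degree <- function(network, N_a) {
  2 * nrow(network$pairs) / N_a
}

#' Per-vertex forces from the tether network
#'
#' Each spring acts between adipocyte centres of mass,
#' \eqn{U = \frac{K_{ecm}}{2}(R_{ij} - l^0_{ij})^2}, and is shared equally by
#' the \eqn{N_v} vertices of each tethered adipocyte.
#'
#' @param network A `tether_network`.
#' @param state A `system_state`.
#' @return List with `forces` (\eqn{N_a N_v \times 3}) and `energy`.
#' @export
tether_forces <- function(network, state) {
  n <- state_counts(state)
  fo <- matrix(0, nrow(state$vert_pos), 3)
  U <- 0
  if (nrow(network$pairs) == 0 || network$Kecm <= 0)
    return(list(forces = fo, energy = 0))
  centers <- adipocyte_centers(state)
  for (e in seq_len(nrow(network$pairs))) {
    i <- network$pairs[e, 1]; j <- network$pairs[e, 2]
    dvec <- centers[i, ] - centers[j, ] +
      c(0, network$offsets[e, 1] * state$Ly,
        network$offsets[e, 2] * state$Lz)
    r <- sqrt(sum(dvec^2))
    U <- U + network$Kecm / 2 * (r - network$l0[e])^2
    fi <- -network$Kecm * (r - network$l0[e]) * dvec / r / n$N_v
    rows_i <- ((i - 1) * n$N_v + 1):(i * n$N_v)
    rows_j <- ((j - 1) * n$N_v + 1):(j * n$N_v)
    fo[rows_i, ] <- sweep(fo[rows_i, , drop = FALSE], 2, fi, "+")
    fo[rows_j, ] <- sweep(fo[rows_j, , drop = FALSE], 2, fi, "-")
  }
  list(forces = fo, energy = U)
}

#' Assemble all forces acting in a state
#'
#' Evaluates the pair forces (vertex-vertex between different adipocytes,
#' vertex-cancer, cancer-cancer with cohesion), the wall repulsions, the
#' tether springs, and the shape-energy forces, using a linked-cell neighbour
#' list (or the all-pairs double loop when `brute = TRUE`, the reference
#' path).
#'
#' @param state A `system_state`.
#' @param params A `sim_params`.
#' @param brute Use the all-pairs evaluation instead of the cell list.
#' @return List with `vert_forces`, `cell_forces`, `potential`,
#'   `wall_force_left`, `wall_force_right` (x-forces exerted by the particles
#'   on each wall).
#' @export
total_forces <- function(state, params = sim_params(), brute = FALSE) {
  .cpp_total_forces(cpp_state(state), cpp_params(params), brute)
}
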