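# Geometry, energy, forces and spectra of the 3D deformable particle model.

#' Build a triangulated icosphere mesh
#'
#' Constructs a closed, consistently outward-oriented triangular mesh by
#' recursive midpoint subdivision of a regular icosahedron, projecting every
#' new vertex onto the circumscribed sphere. One subdivision yields the
#' 42-vertex / 80-face mesh used for adipocytes.
#'
#' @param subdivisions Number of midpoint subdivisions (`0` gives the bare
#'   icosahedron with 12 vertices and 20 faces; each subdivision quadruples
#'   the face count).
#' @param radius Sphere radius in units of \eqn{\sigma}.
#' @return A `tri_mesh` object: a list with `vertices` (\eqn{N_v \times 3}
#'   matrix) and `faces` (\eqn{N_f \times 3} integer matrix, 1-based,
#'   outward-oriented).
#' @examples
#' m <- build_icosphere(1)
#' nrow(m$vertices)  # 42
#' nrow(m$faces)     # 80
#' @export
build_icosphere <- function(subdivisions = 1L, radius = 1) {
  stopifnot(subdivisions >= 0, radius > 0)
  p <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
    c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1)
  )
  V <- V / sqrt(1 + p^2)
  FF <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    nv <- nrow(V)
    midkey <- new.env(hash = TRUE)
    newV <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- midkey[[key]]
      if (!is.null(id)) return(id)
      mp <- (V[i, ] + V[j, ]) / 2
      mp <- mp / sqrt(sum(mp^2))
      newV[[length(newV) + 1L]] <<- mp
      id <- nv + length(newV)
      midkey[[key]] <- id
      id
    }
    newF <- matrix(0L, 4L * nrow(FF), 3L)
    for (k in seq_len(nrow(FF))) {
      a <- FF[k, 1]; b <- FF[k, 2]; cc <- FF[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newF[4 * k - 3, ] <- c(a, ab, ca)
      newF[4 * k - 2, ] <- c(b, bc, ab)
      newF[4 * k - 1, ] <- c(cc, ca, bc)
      newF[4 * k, ] <- c(ab, bc, ca)
    }
    V <- rbind(V, do.call(rbind, newV))
    FF <- newF
  }
  storage.mode(FF) <- "integer"
  # enforce outward orientation (valid for a star-shaped mesh about 0)
  for (k in seq_len(nrow(FF))) {
    tri <- V[FF[k, ], , drop = FALSE]
    n <- crossprod_3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    if (sum(n * colMeans(tri)) < 0) FF[k, ] <- FF[k, c(1, 3, 2)]
  }
  mesh <- structure(list(vertices = V * radius, faces = FF),
                    class = "tri_mesh")
  validate_mesh(mesh)
  mesh
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Validate that a mesh is a closed orientable triangulated surface
#'
#' Checks that every edge is shared by exactly two faces with opposite
#' traversal direction, that the Euler characteristic \eqn{V - E + F} is 2,
#' and that the signed volume is positive (outward orientation).
#'
#' @param mesh A `tri_mesh`.
#' @return The mesh, invisibly; errors if any invariant fails.
#' @export
validate_mesh <- function(mesh) {
  FF <- mesh$faces
  e <- rbind(FF[, 1:2], FF[, 2:3], FF[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2)) stop("mesh is not closed: an edge is not shared by exactly 2 faces")
  dirkey <- paste(e[, 1], e[, 2])
  if (any(duplicated(dirkey)))
    stop("mesh orientation inconsistent: a directed edge appears twice")
  V <- nrow(mesh$vertices); E <- length(cnt); FFn <- nrow(FF)
  if (V - E + FFn != 2L) stop("mesh Euler characteristic is not 2")
  if (.cpp_mesh_volume(mesh$vertices, mesh$faces) <= 0)
    stop("mesh signed volume is not positive")
  invisible(mesh)
}

#' Enclosed volume of a closed triangulated mesh
#'
#' Signed sum of origin tetrahedra over the faces; positive for an
#' outward-oriented mesh and invariant under translation.
#'
#' @param mesh A `tri_mesh`.
#' @return Volume in \eqn{\sigma^3}.
#' @export
mesh_volume <- function(mesh) {
  validate_mesh(mesh)
  .cpp_mesh_volume(mesh$vertices, mesh$faces)
}

#' Areas of the triangular faces of a mesh
#'
#' @param mesh A `tri_mesh`.
#' @return Numeric vector of face areas in \eqn{\sigma^2}.
#' @export
mesh_face_areas <- function(mesh) {
  .cpp_face_areas(mesh$vertices, mesh$faces)
}

#' Dimensionless shape parameter of a closed mesh
#'
#' \eqn{\mathcal{A} = (\sum_k a_k)^{3/2} / (6\sqrt{\pi}\, v)}: 1 for a sphere
#' (in the refinement limit), larger for any aspherical shape, and invariant
#' under uniform rescaling.
#'
#' @param mesh A `tri_mesh` with positive volume.
#' @return The shape parameter (dimensionless).
#' @export
shape_parameter <- function(mesh) {
  v <- .cpp_mesh_volume(mesh$vertices, mesh$faces)
  if (v <= 0) stop("shape parameter requires a positive mesh volume")
  sum(.cpp_face_areas(mesh$vertices, mesh$faces))^1.5 / (6 * sqrt(pi) * v)
}

#' Calibrate an adipocyte reference shape
#'
#' Sets the preferred volume to the current mesh volume and the preferred face
#' areas to the current areas scaled by a single factor
#' \eqn{s = (\mathcal{A}_0 / \mathcal{A}_{mesh})^{2/3}} so that the reference
#' shape parameter \eqn{(\sum_k a^0_k)^{3/2}/(6\sqrt{\pi} v_0)} equals
#' `target_A0` exactly. Uniform scaling preserves the isotropy of the
#' reference; with \eqn{\mathcal{A}_0} above the mesh's own shape parameter
#' the calibrated shape energy has a zero-energy (buckled) minimum.
#'
#' @param mesh A `tri_mesh`.
#' @param target_A0 Reference shape parameter (default 1.1, the adipocyte
#'   value).
#' @param eps_v Volume stiffness in \eqn{\epsilon_c} (large, so volume is
#'   nearly conserved).
#' @param eps_a Face-area stiffness in \eqn{\epsilon_c}.
#' @param sigma_vertex Diameter of the vertex spheres in \eqn{\sigma}
#'   (about twice the mean cancer-cell diameter).
#' @return An `adipocyte_shape`: list with `mesh`, `v0`, `a0`,
#'   `sigma_vertex`, `eps_v`, `eps_a`.
#' @export
make_reference_shape <- function(mesh, target_A0 = 1.1, eps_v = 1e3,
                                 eps_a = 10, sigma_vertex = 2) {
  if (target_A0 <= 0) stop("target_A0 must be positive")
  areas <- mesh_face_areas(mesh)
  s <- (target_A0 / shape_parameter(mesh))^(2 / 3)
  structure(list(mesh = mesh, v0 = .cpp_mesh_volume(mesh$vertices, mesh$faces),
                 a0 = s * areas, sigma_vertex = sigma_vertex,
                 eps_v = eps_v, eps_a = eps_a),
            class = "adipocyte_shape")
}

#' Shape energy of a deformable particle
#'
#' \eqn{U = \frac{\epsilon_v}{2}(1 - v/v_0)^2 +
#' \frac{\epsilon_a}{2}\sum_k (1 - a_k/a^0_k)^2}. Non-negative, and zero only
#' when the volume and every face area sit at their preferred values.
#'
#' @param shape An `adipocyte_shape`.
#' @return Energy in \eqn{\epsilon_c}.
#' @export
shape_energy <- function(shape) {
  .cpp_shape_energy(shape$mesh$vertices, shape$mesh$faces, shape$v0,
                    shape$a0, shape$eps_v, shape$eps_a)
}

#' Forces conjugate to the shape energy
#'
#' Returns \eqn{-\partial U/\partial r_\mu} for every vertex. The energy is
#' internal, so the forces sum to zero and carry no net torque.
#'
#' @param shape An `adipocyte_shape`.
#' @return \eqn{N_v \times 3} matrix of forces in \eqn{\epsilon_c/\sigma}.
#' @export
shape_forces <- function(shape) {
  .cpp_shape_forces(shape$mesh$vertices, shape$mesh$faces, shape$v0,
                    shape$a0, shape$eps_v, shape$eps_a)
}

#' Hessian (dynamical matrix) of the shape energy
#'
#' Analytic second derivatives of the shape energy with respect to all vertex
#' coordinates. At a zero-energy reference configuration the matrix is
#' symmetric positive-semidefinite and its null space contains the 6
#' rigid-body modes plus the non-trivial zero modes of the floppy surface.
#'
#' @param shape An `adipocyte_shape`.
#' @return \eqn{3N_v \times 3N_v} symmetric matrix in
#'   \eqn{\epsilon_c/\sigma^2}.
#' @export
shape_hessian <- function(shape) {
  .cpp_shape_hessian(shape$mesh$vertices, shape$mesh$faces, shape$v0,
                     shape$a0, shape$eps_v, shape$eps_a)
}

#' Relax a deformable particle to its zero-energy reference configuration
#'
#' Minimizes the shape energy of an isolated particle with FIRE. With a
#' reference shape parameter above the mesh's own value the minimum has
#' \eqn{U = 0}: the surface buckles to reach the larger preferred areas at
#' fixed volume. Because the perfectly symmetric icosphere is a strained
#' critical point (the radial forces cannot break its symmetry), the vertices
#' are jiggled by `perturb` before minimizing; without this the minimizer
#' converges onto the symmetric saddle instead of the buckled minimum.
#'
#' @param shape An `adipocyte_shape`.
#' @param tol Convergence threshold on the maximum per-coordinate force.
#' @param max_iter Iteration cap.
#' @param perturb Standard deviation of the symmetry-breaking vertex jiggle
#'   (uses the current RNG state; `0` disables it).
#' @return The shape with relaxed vertex positions; attributes `residual`
#'   and `energy` report the final force residual and energy.
#' @export
relax_shape <- function(shape, tol = 1e-10, max_iter = 2e5, perturb = 1e-2) {
  if (perturb > 0)
    shape$mesh$vertices <- shape$mesh$vertices +
      matrix(rnorm(length(shape$mesh$vertices), 0, perturb),
             nrow(shape$mesh$vertices), 3)
  st <- single_shape_state(shape)
  pp <- sim_params(pair_forces = FALSE, walls_on = FALSE)
  res <- .cpp_fire(st, cpp_params(pp), tol, as.integer(max_iter), 0.01, 0.1)
  shape$mesh$vertices <- res$state$vert_pos
  attr(shape, "residual") <- res$residual
  attr(shape, "energy") <- res$potential
  shape
}

# embed one shape into a minimal system state (no cancer cells, no box)
single_shape_state <- function(shape) {
  L <- 100 * max(abs(shape$mesh$vertices)) + 100
  new_system_state(
    vert_pos = shape$mesh$vertices, faces = shape$mesh$faces,
    v0 = shape$v0, a0 = matrix(shape$a0, nrow = 1),
    sigma_vertex = shape$sigma_vertex, eps_v = shape$eps_v,
    eps_a = shape$eps_a,
    cell_pos = matrix(0, 0, 3), cell_diam = numeric(0),
    xl = -L, xr = L, Ly = 2 * L, Lz = 2 * L
  )
}

#' Count zero-energy modes of a dynamical matrix
#'
#' Diagonalizes the Hessian and counts eigenvalues below a tolerance. For a
#' floppy closed triangulated surface at a zero-energy reference, counting
#' constraints gives \eqn{(3N_v - 6) - (N_f + 1)} non-rigid-body zero modes
#' (39 for the 42-vertex / 80-face adipocyte mesh).
#'
#' @param hessian Symmetric matrix from [shape_hessian()].
#' @param tol Zero threshold; default `1e-8` times the largest eigenvalue.
#' @return List with `n_total` (eigenvalues below `tol`), `n_nontrivial`
#'   (`n_total - 6` rigid-body modes), `tol`, `gap_ratio` (ratio of the first
#'   retained to the last discarded eigenvalue magnitude), and `eigenvalues`.
#'   Warns when the spectral gap does not cleanly separate at `tol`.
#' @export
count_zero_modes <- function(hessian, tol = NULL) {
  ev <- eigen((hessian + t(hessian)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  lmax <- max(abs(ev))
  if (is.null(tol)) tol <- 1e-8 * lmax
  n_total <- sum(ev < tol)
  evs <- sort(abs(ev))
  gap_ratio <- if (n_total > 0 && n_total < length(ev))
    evs[n_total + 1] / max(evs[n_total], .Machine$double.eps) else NA_real_
  if (!is.na(gap_ratio) && gap_ratio < 100)
    warning("zero-mode tolerance does not fall in a clear spectral gap (ratio ",
            signif(gap_ratio, 3), "); counts may be ambiguous")
  list(n_total = n_total, n_nontrivial = n_total - 6L, tol = tol,
       gap_ratio = gap_ratio, eigenvalues = ev)
}

#' Write a mesh as an OFF text file
#'
#' @param mesh A `tri_mesh`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_mesh_off <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    sprintf("%.17g %.17g %.17g", v[1], v[2], v[3])), con)
  writeLines(apply(mesh$faces, 1, function(f)
    sprintf("3 %d %d %d", f[1] - 1, f[2] - 1, f[3] - 1)), con)
  invisible(file)
}

#' Read a mesh from an OFF text file
#'
#' @param file Path to an OFF file with triangular faces.
#' @return A `tri_mesh`.
#' @export
read_mesh_off <- function(file) {
  ln <- readLines(file)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  stopifnot(trimws(ln[1]) == "OFF")
  hdr <- scan(text = ln[2], quiet = TRUE)
  nv <- hdr[1]; nf <- hdr[2]
  V <- matrix(scan(text = ln[3:(2 + nv)], quiet = TRUE), nv, 3, byrow = TRUE)
  Fdat <- matrix(scan(text = ln[(3 + nv):(2 + nv + nf)], quiet = TRUE),
                 nf, 4, byrow = TRUE)
  stopifnot(all(Fdat[, 1] == 3))
  structure(list(vertices = V, faces = matrix(as.integer(Fdat[, 2:4] + 1),
                                              nf, 3)),
            class = "tri_mesh")
}
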