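# Shared fixtures built in code. Jammed packings are expensive, so they are
# generated once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# jammed de-mixed packing at total phi = 0.72 (reduced N for test budgets)
jammed_state <- function(N_a = 4, N_c = 100, seed = 42, tol = 1e-6) {
  cached(paste("jam", N_a, N_c, seed), {
    set.seed(seed)
    st <- place_demixed(init_config(N_a = N_a, N_c = N_c, tol = tol))
    compress_to_phi(st, 0.72, tol = tol)
  })
}

orient_outward <- function(mesh) {
  for (k in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[k, ], , drop = FALSE]
    a <- tri[2, ] - tri[1, ]
    b <- tri[3, ] - tri[1, ]
    n <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    if (sum(n * colMeans(tri)) < 0) mesh$faces[k, ] <- mesh$faces[k, c(1, 3, 2)]
  }
  mesh
}

regular_tetrahedron <- function() {
  orient_outward(structure(list(
    vertices = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                     c(-1, -1, 1)) / sqrt(3),
    faces = rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))),
    class = "tri_mesh"))
}

regular_octahedron <- function() {
  orient_outward(structure(list(
    vertices = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1)),
    faces = rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
                  c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))),
    class = "tri_mesh"))
}

# relax a mesh at an inflated reference and count nontrivial zero modes
relaxed_zero_modes <- function(mesh, inflate = 1.01, seed = 1) {
  set.seed(seed)
  sh <- make_reference_shape(mesh, inflate * shape_parameter(mesh))
  shr <- relax_shape(sh, tol = 1e-11)
  suppressWarnings(count_zero_modes(shape_hessian(shr)))
}

# a random single-adipocyte shape perturbed off its reference
perturbed_shape <- function(sd = 0.1, radius = 2, seed = 1) {
  set.seed(seed)
  m <- build_icosphere(1, radius = radius)
  sh <- make_reference_shape(m, 1.1)
  sh$mesh$vertices <- sh$mesh$vertices +
    matrix(rnorm(length(sh$mesh$vertices), 0, sd), nrow(sh$mesh$vertices), 3)
  sh
}

# a small random mixed state (cells + optionally adipocytes) in a periodic-ish
# box, used for brute-force/neighbour-list equivalence
random_mini_state <- function(N_c = 25, N_a = 1, L = 12, seed = 1) {
  set.seed(seed)
  mesh <- build_icosphere(1, radius = 2)
  sh <- make_reference_shape(mesh, 1.1)
  na <- N_a
  vert <- if (na > 0) {
    do.call(rbind, lapply(seq_len(na), function(i)
      sweep(mesh$vertices, 2, runif(3, 3, L - 3), "+")))
  } else matrix(0, 0, 3)
  new_system_state(
    vert_pos = vert, faces = mesh$faces, v0 = rep(sh$v0, na),
    a0 = matrix(rep(sh$a0, each = na), na, nrow(mesh$faces)),
    cell_pos = matrix(runif(3 * N_c, 0.6, L - 0.6), N_c, 3),
    cell_diam = sample(rep(c(0.9, 1.1), length.out = N_c)),
    cell_dir = if (N_c > 0) {
      d <- matrix(rnorm(3 * N_c), N_c, 3); d / sqrt(rowSums(d^2))
    } else matrix(0, 0, 3),
    xl = 0, xr = L, Ly = L, Lz = L
  )
}

expect_equal_bare <- function(object, expected, tolerance = 1e-12) {
  expect_equal(as.numeric(object), as.numeric(expected),
               tolerance = tolerance)
}
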