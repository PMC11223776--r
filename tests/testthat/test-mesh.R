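# Deformable-particle geometry, energetics and spectra.

test_that("icosphere construction gives closed oriented meshes of the right size", {
  m0 <- build_icosphere(0)
  expect_equal(nrow(m0$vertices), 12L)
  expect_equal(nrow(m0$faces), 20L)
  m1 <- build_icosphere(1)
  expect_equal(nrow(m1$vertices), 42L)
  expect_equal(nrow(m1$faces), 80L)
  # Euler characteristic via the validator (errors if violated)
  expect_silent(validate_mesh(m1))
  # inscribed polyhedron: volume below the sphere, approaching it on refinement
  expect_lt(mesh_volume(m1), 4 * pi / 3)
  expect_lt(abs(mesh_volume(build_icosphere(3)) - 4 * pi / 3), 0.01 * 4 * pi / 3)
  expect_gt(mesh_volume(build_icosphere(2)), mesh_volume(m1))
})

test_that("mesh volume matches closed forms and is rigid-motion invariant", {
  tet <- regular_tetrahedron()
  edge <- sqrt(sum((tet$vertices[1, ] - tet$vertices[2, ])^2))
  expect_equal(mesh_volume(tet) / edge^3, 1 / (6 * sqrt(2)), tolerance = 1e-12)

  m <- build_icosphere(1, radius = 2)
  v0 <- mesh_volume(m)
  a0 <- mesh_face_areas(m)
  mt <- m
  mt$vertices <- sweep(m$vertices, 2, c(17.3, -42.1, 5.9), "+")
  expect_equal(mesh_volume(mt), v0, tolerance = 1e-12)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mr <- m
  mr$vertices <- m$vertices %*% R
  expect_equal(mesh_volume(mr), v0, tolerance = 1e-12)
  expect_equal(mesh_face_areas(mr), a0, tolerance = 1e-12)
})

test_that("shape parameter: sphere limit, icosahedron closed form, scale invariance", {
  # refinement limit of the sphere is 1, approached from above
  As <- vapply(0:3, function(s) shape_parameter(build_icosphere(s)), numeric(1))
  expect_true(all(diff(As) < 0))
  expect_lt(As[4] - 1, 5e-3)
  expect_gt(As[4], 1)
  # regular icosahedron: area 5*sqrt(3) a^2, volume (5/12)(3+sqrt(5)) a^3
  A_icosa <- (5 * sqrt(3))^1.5 / (6 * sqrt(pi) * (5 / 12) * (3 + sqrt(5)))
  expect_equal(shape_parameter(build_icosphere(0)), A_icosa, tolerance = 1e-10)
  m <- build_icosphere(1)
  m2 <- m
  m2$vertices <- 2 * m$vertices
  expect_equal(shape_parameter(m2), shape_parameter(m), tolerance = 1e-12)
})

test_that("reference-shape calibration hits the target exactly and is scale invariant", {
  m <- build_icosphere(1, radius = 2)
  # identity: calibrating to the mesh's own shape keeps the current areas
  sh0 <- make_reference_shape(m, shape_parameter(m))
  expect_equal(sh0$a0, mesh_face_areas(m), tolerance = 1e-12)
  sh <- make_reference_shape(m, 1.1)
  expect_equal(sum(sh$a0)^1.5 / (6 * sqrt(pi) * sh$v0), 1.1, tolerance = 1e-10)
  # the single area scale factor s depends only on the shape, not the size
  mb <- m
  mb$vertices <- 3.7 * m$vertices
  shb <- make_reference_shape(mb, 1.1)
  s_small <- sh$a0 / mesh_face_areas(m)
  s_big <- shb$a0 / mesh_face_areas(mb)
  expect_equal(s_big, s_small, tolerance = 1e-10)
  expect_error(make_reference_shape(m, -1), "positive")
})

test_that("shape energy is zero at its reference and matches hand plug-ins", {
  m <- build_icosphere(1, radius = 2)
  sh <- make_reference_shape(m, shape_parameter(m))
  expect_equal(shape_energy(sh), 0, tolerance = 1e-20)
  # volume at twice its preferred value: U = eps_v / 2
  sh2 <- sh
  sh2$v0 <- sh$v0 / 2
  expect_equal(shape_energy(sh2), sh$eps_v / 2, tolerance = 1e-10)
  # one face area at half its preferred value: U = eps_a / 8
  sh3 <- sh
  sh3$a0[1] <- 2 * sh$a0[1]
  expect_equal(shape_energy(sh3), sh$eps_a / 8, tolerance = 1e-10)
})

test_that("shape forces are the exact gradient and carry no net force or torque", {
  sh <- make_reference_shape(build_icosphere(1, radius = 2),
                             shape_parameter(build_icosphere(1, radius = 2)))
  expect_lt(max(abs(shape_forces(sh))), 1e-12)

  h <- 1e-6
  for (seed in 1:5) {
    shp <- perturbed_shape(sd = 0.15, seed = seed)
    f <- shape_forces(shp)
    set.seed(seed)
    for (k in 1:6) {
      i <- sample(42, 1)
      d <- sample(3, 1)
      sp <- shp; sp$mesh$vertices[i, d] <- sp$mesh$vertices[i, d] + h
      sm <- shp; sm$mesh$vertices[i, d] <- sm$mesh$vertices[i, d] - h
      fd <- -(shape_energy(sp) - shape_energy(sm)) / (2 * h)
      expect_equal(f[i, d], fd, tolerance = 1e-6)
    }
    expect_lt(max(abs(colSums(f))), 1e-11)
    trq <- colSums(cbind(
      shp$mesh$vertices[, 2] * f[, 3] - shp$mesh$vertices[, 3] * f[, 2],
      shp$mesh$vertices[, 3] * f[, 1] - shp$mesh$vertices[, 1] * f[, 3],
      shp$mesh$vertices[, 1] * f[, 2] - shp$mesh$vertices[, 2] * f[, 1]))
    expect_lt(max(abs(trq)), 1e-10)
  }
})

test_that("analytic Hessian is symmetric, PSD at the reference, and matches force differences", {
  shp <- perturbed_shape(sd = 0.1, seed = 3)
  H <- shape_hessian(shp)
  expect_lt(max(abs(H - t(H))), 1e-10)
  h <- 1e-5
  set.seed(3)
  for (k in 1:6) {
    i <- sample(42, 1)
    d <- sample(3, 1)
    sp <- shp; sp$mesh$vertices[i, d] <- sp$mesh$vertices[i, d] + h
    sm <- shp; sm$mesh$vertices[i, d] <- sm$mesh$vertices[i, d] - h
    fd <- -(as.vector(t(shape_forces(sp))) - as.vector(t(shape_forces(sm)))) / (2 * h)
    expect_lt(max(abs(fd - H[, 3 * (i - 1) + d])) / max(abs(H)), 1e-7)
  }
  set.seed(4)
  shr <- relax_shape(make_reference_shape(build_icosphere(1, radius = 2), 1.1),
                     tol = 1e-11)
  ev <- eigen(shape_hessian(shr), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
})

test_that("zero-mode counts follow the floppy-surface constraint count", {
  zm <- relaxed_zero_modes(regular_tetrahedron())
  expect_equal(zm$n_nontrivial, (3 * 4 - 6) - (4 + 1))
  zm <- relaxed_zero_modes(build_icosphere(0))
  expect_equal(zm$n_nontrivial, (3 * 12 - 6) - (20 + 1))
  zm <- relaxed_zero_modes(build_icosphere(1, radius = 2))
  expect_equal(zm$n_nontrivial, 39L)
  expect_gt(zm$gap_ratio, 1e4)
  # octahedron: the constraint count gives 3, but one constraint gradient is
  # (near-)dependent at the relaxed reference, so the numerical spectrum shows
  # an extra marginal zero mode
  zm <- relaxed_zero_modes(regular_octahedron(), inflate = 1.05)
  expect_true(zm$n_nontrivial %in% c(3L, 4L))
})

test_that("meshes round-trip through OFF text files", {
  m <- build_icosphere(1, radius = 2)
  f <- withr::local_tempfile(fileext = ".off")
  write_mesh_off(m, f)
  m2 <- read_mesh_off(f)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-15)
  expect_identical(m2$faces, m$faces)
})
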