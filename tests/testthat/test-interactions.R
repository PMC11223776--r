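# Pair forces, walls, tethers, and the force assembler.

test_that("repulsive pair forces match plug-in values and Newton's third law", {
  # vertex-vertex: contact boundary, half-overlap magnitude, reaction
  st <- 2  # two sigma_imu = 2 vertices
  expect_equal_bare(vertex_vertex_force(c(st, 0, 0), 2, 2), c(0, 0, 0))
  f <- vertex_vertex_force(c(st / 2, 0, 0), 2, 2)
  expect_equal_bare(f, c(0.5 / st, 0, 0), tolerance = 1e-14)
  expect_equal_bare(vertex_vertex_force(-c(st / 2, 0, 0), 2, 2), -f)
  # vertex-cancer
  stc <- (2 + 1) / 2
  expect_equal_bare(vertex_cancer_force(c(2 * stc, 0, 0), 2, 1), c(0, 0, 0))
  expect_equal_bare(vertex_cancer_force(c(0.9 * stc, 0, 0), 2, 1),
                    c(0.1 / stc, 0, 0), tolerance = 1e-14)
  expect_warning(vertex_vertex_force(c(0, 0, 0), 2, 2), "coincident")
})

test_that("cancer-cancer force has the attractive well with the printed extrema", {
  alpha <- 0.2
  beta <- 1e-2
  sqs <- 1  # two unit-diameter cells
  r_beta <- sqs * (1 + beta)
  r_alpha <- sqs * (1 + alpha)
  # maximum attraction eps_c * beta / sigma_qs at r_beta
  f <- cancer_cancer_force(c(r_beta, 0, 0), 1, 1, alpha, beta)
  expect_equal_bare(f, c(-beta / sqs, 0, 0), tolerance = 1e-12)
  expect_equal_bare(cancer_cancer_force(c(r_alpha, 0, 0), 1, 1, alpha, beta),
                    c(0, 0, 0))
  expect_equal_bare(cancer_cancer_force(c(0.5, 0, 0), 1, 1, alpha, beta),
                    c(0.5 / sqs, 0, 0), tolerance = 1e-12)
  # beta = 0 recovers the purely repulsive law
  expect_equal_bare(cancer_cancer_force(c(1.05, 0, 0), 1, 1, alpha, 0),
                    c(0, 0, 0))
})

test_that("every pair force is continuous across its branch boundaries", {
  alpha <- 0.2
  beta <- 5e-3
  mag <- function(r) cancer_cancer_force(c(r, 0, 0), 1, 1, alpha, beta)[1]
  for (rb in c(1, 1 + beta, 1 + alpha)) {
    expect_lt(abs(mag(rb - 1e-9) - mag(rb + 1e-9)), 1e-6)
  }
  magv <- function(r) vertex_vertex_force(c(r, 0, 0), 2, 2)[1]
  expect_lt(abs(magv(2 - 1e-9) - magv(2 + 1e-9)), 1e-6)
  # fine grid: no jumps anywhere in the supported range
  r <- seq(0.4, 1.3, by = 1e-3)
  m <- vapply(r, mag, numeric(1))
  expect_lt(max(abs(diff(m))), 2e-3 * max(abs(m)))
})

test_that("wall forces act within one diameter and push away from the wall", {
  expect_equal(wall_force(1 + 1e-9, 0, 1, "left"), 0)
  expect_equal(wall_force(0.5, 0, 1, "left"), 0.5, tolerance = 1e-14)
  expect_equal(wall_force(9.5, 10, 1, "right"), -0.5, tolerance = 1e-14)
  # assembled wall reaction balances the particle forces
  st <- new_system_state(cell_pos = rbind(c(0.4, 5, 5), c(9.7, 4, 4)),
                         cell_diam = c(1, 1), xl = 0, xr = 10,
                         Ly = 10, Lz = 10)
  fo <- total_forces(st, sim_params())
  expect_equal(fo$wall_force_left, -fo$cell_forces[1, 1], tolerance = 1e-14)
  expect_equal(fo$wall_force_right, -fo$cell_forces[2, 1], tolerance = 1e-14)
})

test_that("tether networks calibrate to the target degree and exert Hooke forces", {
  st <- jammed_state()
  n <- state_counts(st)
  net <- build_tether_network(st, Kecm = 0.04)
  # with N_a = 4 the complete graph caps the degree at N_a - 1 = 3
  expect_equal(mean_tether_degree(net, n$N_a), min(6, n$N_a - 1))
  expect_equal(net$l0, adipoinvade:::current_tether_lengths(net, st),
               tolerance = 1e-10)
  # at rest length: zero forces
  tf <- tether_forces(net, st)
  expect_lt(max(abs(tf$forces)), 1e-12)
  expect_equal(tf$energy, 0, tolerance = 1e-20)
  # stretch one pair by rigidly displacing one adipocyte
  delta <- 0.05
  st2 <- st
  rows <- 1:n$N_v
  cen <- adipocyte_centers(st)
  i <- net$pairs[1, 1]; j <- net$pairs[1, 2]
  dvec <- cen[i, ] - cen[j, ] + c(0, net$offsets[1, 1] * st$Ly,
                                  net$offsets[1, 2] * st$Lz)
  u <- dvec / sqrt(sum(dvec^2))
  net1 <- net
  net1$pairs <- net$pairs[1, , drop = FALSE]
  net1$offsets <- net$offsets[1, , drop = FALSE]
  net1$l0 <- net$l0[1]
  rows_i <- ((i - 1) * n$N_v + 1):(i * n$N_v)
  st2$vert_pos[rows_i, ] <- sweep(st2$vert_pos[rows_i, ], 2, delta * u, "+")
  tf2 <- tether_forces(net1, st2)
  Fi <- colSums(tf2$forces[rows_i, ])
  expect_equal(sqrt(sum(Fi^2)), net$Kecm * delta, tolerance = 1e-6)
  expect_lt(sum(Fi * u), 0)  # restoring, pointing back toward j
  # energy/force consistency along a small displacement
  h <- 1e-6
  st3 <- st2
  st3$vert_pos[rows_i, ] <- sweep(st3$vert_pos[rows_i, ], 2, h * u, "+")
  dU <- tether_forces(net1, st3)$energy - tf2$energy
  expect_equal(dU / h, -sum(Fi * u), tolerance = 1e-4)
  # Kecm = 0 networks exert nothing downstream
  net0 <- net
  net0$Kecm <- 0
  st4 <- st
  st4$tethers <- net0
  stK <- st
  stK$tethers <- net
  f0 <- total_forces(st4, sim_params())
  fK <- total_forces(stK, sim_params())
  expect_equal(f0$vert_forces, fK$vert_forces, tolerance = 1e-12)
})

test_that("tether degree is exactly 6 on a cubic lattice with d_c between shells", {
  fx <- make_fixture("cubic_tether_lattice")
  d_c <- 1.2 * fx$spacing  # between the first (1) and second (sqrt(2)) shells
  # enumerate neighbours (periodic y/z, open x) for interior-x sites
  deg <- vapply(seq_len(nrow(fx$centers)), function(i) {
    dx <- fx$centers[, 1] - fx$centers[i, 1]
    dy <- fx$centers[, 2] - fx$centers[i, 2]
    dy <- dy - fx$Ly * round(dy / fx$Ly)
    dz <- fx$centers[, 3] - fx$centers[i, 3]
    dz <- dz - fx$Lz * round(dz / fx$Lz)
    sum(sqrt(dx^2 + dy^2 + dz^2) <= d_c) - 1L
  }, integer(1))
  interior <- fx$centers[, 1] > fx$xl + fx$spacing &
    fx$centers[, 1] < fx$xr - fx$spacing
  expect_true(all(deg[interior] == 6L))
})

test_that("small networks degrade gracefully", {
  st <- random_mini_state(N_c = 0, N_a = 1, seed = 9)
  net <- build_tether_network(st)
  expect_equal(nrow(net$pairs), 0L)
})

test_that("neighbour-list forces equal the all-pairs double loop on random states", {
  pp <- sim_params(beta = 8e-3)
  for (seed in 1:50) {
    st <- random_mini_state(N_c = 25, N_a = if (seed %% 3 == 0) 1 else 0,
                            L = 9, seed = seed)
    a <- total_forces(st, pp, brute = FALSE)
    b <- total_forces(st, pp, brute = TRUE)
    expect_lt(max(abs(a$cell_forces - b$cell_forces)), 1e-12)
    if (nrow(st$vert_pos) > 0)
      expect_lt(max(abs(a$vert_forces - b$vert_forces)), 1e-12)
    expect_equal(a$potential, b$potential, tolerance = 1e-12)
  }
})

test_that("net force vanishes for a fully periodic system without walls", {
  st <- random_mini_state(N_c = 40, N_a = 1, L = 14, seed = 5)
  pp <- sim_params(beta = 5e-3, periodic_x = TRUE, walls_on = FALSE)
  fo <- total_forces(st, pp)
  net <- colSums(fo$cell_forces) + colSums(fo$vert_forces)
  expect_lt(max(abs(net)), 1e-10)
  # an isolated cell feels nothing
  st1 <- new_system_state(cell_pos = matrix(c(5, 5, 5), 1), cell_diam = 1,
                          xl = 0, xr = 10, Ly = 10, Lz = 10)
  expect_equal_bare(total_forces(st1, sim_params())$cell_forces, c(0, 0, 0))
})
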