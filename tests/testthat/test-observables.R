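# Interfacial area, velocity statistics, sigmoid fit, energy-scale collapse.

test_that("the tessellated slab interface recovers the planar cross-section", {
  fx <- make_fixture("planar_interface")
  res <- adipoinvade:::.cpp_power_cells(fx$points, fx$radii, fx$group,
                                        fx$xl, fx$xr, fx$Ly, fx$Lz, TRUE)
  cc <- fx$group == -1L
  At <- sum(res$areas[cc, "other_adip"])
  expect_equal(At, fx$Ly * fx$Lz, tolerance = 1e-9)
  # tessellation partitions the box volume exactly
  expect_equal(sum(res$volumes), (fx$xr - fx$xl) * fx$Ly * fx$Lz,
               tolerance = 1e-9)
})

test_that("interfacial area limits: no cancer cells, and a fully surrounded cell", {
  st <- random_mini_state(N_c = 0, N_a = 2, L = 14, seed = 2)
  expect_equal(as.numeric(interfacial_area(st)), 0)
  # one cancer cell at an adipocyte centre: every face of its Voronoi cell is
  # shared with that adipocyte's vertex seeds
  sta <- random_mini_state(N_c = 0, N_a = 1, L = 14, seed = 3)
  cen <- adipocyte_centers(sta)
  st1 <- sta
  st1$cell_pos <- matrix(cen[1, ], 1)
  st1$cell_vel <- matrix(0, 1, 3)
  st1$cell_dir <- matrix(c(1, 0, 0), 1)
  st1$cell_diam <- 1
  sd <- adipoinvade:::voronoi_seeds(st1)
  res <- adipoinvade:::.cpp_power_cells(sd$pts, sd$rad, sd$group, st1$xl,
                                        st1$xr, st1$Ly, st1$Lz, TRUE)
  total_cell_area <- unname(res$areas[1, "total"])
  expect_equal(as.numeric(interfacial_area(st1)), total_cell_area,
               tolerance = 1e-9)
})

test_that("normalization maps the de-mixed and fully mixed bounds to 0 and 1", {
  expect_equal(normalize_interfacial_area(470, 470, 2000), 0)
  expect_equal(normalize_interfacial_area(2000, 470, 2000), 1)
  expect_equal(normalize_interfacial_area(1235, 470, 2000), 0.5)
  expect_warning(normalize_interfacial_area(2400, 470, 2000), "clamped")
  expect_error(normalize_interfacial_area(1, 5, 5), "invalid")
})

test_that("velocity autocorrelation is 1 for constant velocities and handles layout", {
  vel <- matrix(rep(c(0.1, -0.3, 0.2, 0.05, 0.0, -0.1), each = 20), 20, 6)
  cv <- velocity_autocorrelation(vel, dt_frame = 0.5, max_lag = 8)
  expect_equal(cv$C_vv, rep(1, 9), tolerance = 1e-12)
  expect_equal(cv$t, seq(0, 4, by = 0.5))
  expect_error(velocity_autocorrelation(vel[1, , drop = FALSE], 0.5),
               "insufficient")
})

test_that("free active cells reproduce the closed-form velocity autocorrelation", {
  set.seed(8)
  n <- 250
  st <- adipoinvade:::free_cell_state(n, L = 30)
  st$cell_dir <- adipoinvade:::random_unit_vectors(n)
  pp <- sim_params(dt = 0.02, gamma = 0.2, model = "active", f0 = 0.01,
                   taup = 25, periodic_x = TRUE, pair_forces = FALSE,
                   walls_on = FALSE)
  eq <- step_system(st, pp, nsteps = 40000)
  sm <- step_system(eq$state, pp, nsteps = 80000, record_every = 25,
                    record_vel = TRUE)
  cv <- velocity_autocorrelation(sm$vel, dt_frame = 0.5, max_lag = 250)
  th <- cvv_free_active(cv$t, tau_gamma = 1 / 0.2, tau_p = 25)
  expect_lt(max(abs(cv$C_vv - th)), 0.05)
  # decorrelation time against the numerical root of the closed form
  td <- decorrelation_time(cv$t, cv$C_vv)
  td_th <- uniroot(function(t) cvv_free_active(t, 5, 25) - exp(-1),
                   c(0.1, 500))$root
  expect_equal(td, td_th, tolerance = 0.1)
})

test_that("decorrelation time interpolates the e^-1 crossing of known curves", {
  tg <- 3
  t <- seq(0, 30, by = 0.05)
  expect_equal(decorrelation_time(t, exp(-t / tg)), tg, tolerance = 1e-3)
  # closed form at arbitrary parameters vs root finding
  for (taup in c(0.5, 5, 80)) {
    C <- cvv_free_active(t, tg, taup)
    td_th <- uniroot(function(x) cvv_free_active(x, tg, taup) - exp(-1),
                     c(1e-6, 1000))$root
    if (td_th < max(t))
      expect_equal(decorrelation_time(t, C), td_th, tolerance = 1e-3)
  }
  # taup >> tau_gamma: decorrelation follows the persistence time
  td <- uniroot(function(x) cvv_free_active(x, 5, 2500) - exp(-1),
                c(1, 1e5))$root
  expect_equal(td / 2500, 1, tolerance = 0.15)
  # no crossing: NA with a lower bound
  out <- decorrelation_time(t[t < 1], exp(-t[t < 1] / tg))
  expect_true(is.na(out))
  expect_gt(attr(out, "lower_bound"), 0)
})

test_that("sigmoid fit recovers known parameters and pins A_n = 1/2 at its midpoint", {
  set.seed(11)
  a <- 0.1
  b <- 1.5
  x <- 10^seq(-2.5, 1, length.out = 15)
  an <- 0.5 * (tanh(b * log10(x / a)) + 1) + rnorm(15, 0, 0.01)
  fit <- fit_sigmoid(x, an)
  expect_equal(fit$a, a, tolerance = 0.05)
  expect_equal(fit$b, b, tolerance = 0.05)
  expect_gt(fit$b, 0)  # A_n increasing in temperature
  # midpoint identity by construction of the model
  newdf <- data.frame(lx = log10(fit$a))
  expect_equal(as.numeric(predict(fit$fit, newdata = newdf)), 0.5,
               tolerance = 1e-10)
  expect_error(fit_sigmoid(x[1:5], rep(0.9, 5)), "transition")
})

test_that("the energy scale and the midpoint model identify (c1, c2)", {
  expect_equal(energy_scale(0.3 * 1.3e-3, 1.3e-3, 0.06), 5, tolerance = 1e-12)
  # synthetic midpoints generated from the model with known constants
  set.seed(12)
  c1 <- 0.06
  c2 <- 0.02
  beta <- c(1e-4, 1e-3, 5e-3, 1e-2, 1e-2, 1e-3)
  P <- rep(1.3e-3, 6)
  tg <- rep(5, 6)
  td <- c(5, 30, 30, 250, 30, 5)
  a <- c1 * (1 + c2 * beta / P) * tg / td * (1 + rnorm(6, 0, 0.02))
  fit <- fit_collapse(a, beta, P, tg, td)
  expect_equal(fit$c1, c1, tolerance = 0.1)
  expect_equal(fit$c2, c2, tolerance = 0.1)
  expect_error(fit_collapse(a[1], beta[1], P[1], tg[1], td[1]), "conditions")
  # beta -> 0 limit: the midpoint depends only on tau_gamma / tau_d
  expect_equal(c1 * (1 + c2 * 0 / 1) * 5 / 30, c1 * 5 / 30)
})

test_that("collapse residual is small for data on a common master curve", {
  set.seed(13)
  b <- 1.2
  Ec <- 10^runif(80, -1.5, 1.5)
  An <- 0.5 * (tanh(log10(Ec^b)) + 1) + rnorm(80, 0, 0.02)
  expect_lt(collapse_residual(Ec^b, An), 0.25)
  # scattered data do not collapse
  An_bad <- runif(80)
  expect_gt(collapse_residual(Ec^b, An_bad), collapse_residual(Ec^b, An))
})
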