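# Invasion metrics, velocity statistics, sigmoid fits and the energy-scale
# collapse.

#' Interfacial area between cancer cells and adipocytes
#'
#' Performs a radical (Laguerre) tessellation with the cancer-cell centres
#' (weight \eqn{\sigma_q/2}) and the adipocyte vertex centres (weight
#' \eqn{\sigma_{i\mu}/2}) as seeds, periodic in y and z and bounded by the
#' wall planes in x, and sums the areas of the Voronoi faces shared between a
#' cancer seed and an adipocyte seed, plus (by default) the cancer faces on
#' the wall planes.
#'
#' @param state A `system_state`.
#' @param include_walls Count cancer-wall faces.
#' @param radical Use radii as power weights (`FALSE` gives the unweighted
#'   tessellation for sensitivity checks).
#' @return \eqn{A_t} in \eqn{\sigma^2}; attribute `breakdown` reports the
#'   cancer-adipocyte and cancer-wall contributions.
#' @export
interfacial_area <- function(state, include_walls = TRUE, radical = TRUE) {
  sd <- voronoi_seeds(state)
  if (nrow(sd$pts) == 0 || !any(sd$group == -1L))
    return(structure(0, breakdown = c(cancer_adip = 0, cancer_wall = 0)))
  res <- .cpp_power_cells(sd$pts, sd$rad, sd$group, state$xl, state$xr,
                          state$Ly, state$Lz, radical)
  cc <- sd$group == -1L
  a_ca <- sum(res$areas[cc, "other_adip"])
  a_cw <- sum(res$areas[cc, "wall_l"] + res$areas[cc, "wall_r"])
  structure(a_ca + if (include_walls) a_cw else 0,
            breakdown = c(cancer_adip = a_ca, cancer_wall = a_cw))
}

#' Total adipocyte Voronoi surface area
#'
#' The instantaneous upper bound \eqn{A_t^{max}} on the interfacial area: the
#' summed surface area of every adipocyte's group of Voronoi cells (faces
#' towards cancer cells, other adipocytes, or the walls; internal faces
#' between vertices of the same adipocyte are excluded).
#'
#' @inheritParams interfacial_area
#' @return \eqn{A_t^{max}} in \eqn{\sigma^2}.
#' @export
adipocyte_surface_area <- function(state, radical = TRUE) {
  sd <- voronoi_seeds(state)
  av <- sd$group >= 0L
  if (!any(av)) return(0)
  res <- .cpp_power_cells(sd$pts, sd$rad, sd$group, state$xl, state$xr,
                          state$Ly, state$Lz, radical)
  sum(res$areas[av, c("cancer", "other_adip", "wall_l", "wall_r")])
}

voronoi_seeds <- function(state) {
  n <- state_counts(state)
  pts <- rbind(state$cell_pos, state$vert_pos)
  rad <- c(state$cell_diam / 2,
           rep(state$sigma_vertex / 2, nrow(state$vert_pos)))
  group <- c(rep(-1L, n$N_c),
             if (n$N_a > 0) rep(seq_len(n$N_a) - 1L, each = n$N_v)
             else integer(0))
  if (nrow(pts) > 0) {
    pts[, 2] <- pts[, 2] %% state$Ly
    pts[, 3] <- pts[, 3] %% state$Lz
    # co-spherical/coincident seeds break the clipping: jitter deterministically
    key <- paste(round(pts[, 1], 8), round(pts[, 2], 8), round(pts[, 3], 8))
    dup <- duplicated(key)
    if (any(dup)) {
      warning(sum(dup), " coincident Voronoi seeds jittered by 1e-9")
      pts[dup, ] <- pts[dup, ] + 1e-9 * seq_len(sum(dup))
    }
  }
  list(pts = pts, rad = rad, group = group)
}

#' Normalize an interfacial area between its de-mixed and mixed bounds
#'
#' \eqn{A_n = (A_t - A_t^{min}) / (A_t^{max} - A_t^{min})}, clamped to
#' \eqn{[0, 1]} (small numerical excursions are clamped silently within
#' `slack`, larger ones with a warning).
#'
#' @param A_t Interfacial area(s).
#' @param A_t_min De-mixed (planar) bound at the same box geometry.
#' @param A_t_max Total adipocyte surface bound at the same box geometry.
#' @param slack Tolerated relative excursion before warning.
#' @return \eqn{A_n} in \eqn{[0, 1]}.
#' @export
normalize_interfacial_area <- function(A_t, A_t_min, A_t_max, slack = 0.05) {
  if (any(A_t_max <= A_t_min)) stop("invalid geometry: A_t_max <= A_t_min")
  an <- (as.numeric(A_t) - A_t_min) / (A_t_max - A_t_min)
  if (any(an < -slack) || any(an > 1 + slack))
    warning("A_n excursion beyond [0,1] by more than ", slack, "; clamped")
  pmin(1, pmax(0, an))
}

#' Velocity autocorrelation function
#'
#' \eqn{C_{vv}(t) = \langle v_q(t') \cdot v_q(t'+t) / v_q^2(t')
#' \rangle_{q,t'}}: each origin is normalized by its own squared speed before
#' averaging over cells and time origins, so \eqn{C_{vv}(0) = 1}.
#'
#' @param vel Matrix of recorded velocities, one frame per row and `3 N`
#'   columns (the `vel` output of [step_system()]), or a `frames x N x 3`
#'   array.
#' @param dt_frame Time between recorded frames.
#' @param max_lag Largest lag (in frames) to evaluate; defaults to half the
#'   history.
#' @return data.frame with columns `t` and `C_vv`.
#' @export
velocity_autocorrelation <- function(vel, dt_frame, max_lag = NULL) {
  if (is.matrix(vel)) {
    # recorded layout: one frame per row, (x,y,z) triples per cell
    nT <- nrow(vel)
    N <- ncol(vel) %/% 3
    arr <- array(0, c(nT, N, 3))
    for (k in 1:3) arr[, , k] <- vel[, seq(k, 3 * N, by = 3), drop = FALSE]
    vel <- arr
  }
  nT <- dim(vel)[1]
  if (nT < 2) stop("insufficient velocity history")
  if (is.null(max_lag)) max_lag <- nT %/% 2
  max_lag <- min(max_lag, nT - 1)
  den <- vel[, , 1]^2 + vel[, , 2]^2 + vel[, , 3]^2  # |v(t')|^2, frames x N
  cvv <- vapply(0:max_lag, function(l) {
    i1 <- seq_len(nT - l)
    i2 <- i1 + l
    num <- vel[i1, , 1] * vel[i2, , 1] + vel[i1, , 2] * vel[i2, , 2] +
      vel[i1, , 3] * vel[i2, , 3]
    mean(num / den[i1, ])
  }, numeric(1))
  data.frame(t = (0:max_lag) * dt_frame, C_vv = cvv)
}

#' Velocity decorrelation time
#'
#' First crossing of \eqn{C_{vv}(t) = e^{-1}}, linearly interpolated between
#' samples. If the correlation never decays below \eqn{e^{-1}} within the
#' window, returns `NA` with the largest measured lag as the attribute
#' `lower_bound`.
#'
#' @param t,C_vv Lag times and autocorrelation values (e.g. from
#'   [velocity_autocorrelation()]).
#' @return \eqn{\tau_d} in reduced time units.
#' @export
decorrelation_time <- function(t, C_vv) {
  target <- exp(-1)
  below <- which(C_vv < target)
  if (length(below) == 0)
    return(structure(NA_real_, lower_bound = max(t)))
  k <- below[1]
  if (k == 1) return(t[1])
  t[k - 1] + (t[k] - t[k - 1]) * (C_vv[k - 1] - target) /
    (C_vv[k - 1] - C_vv[k])
}

#' Closed-form velocity autocorrelation of a free active particle
#'
#' \eqn{C_{vv}(t) = (\tau_\gamma e^{-t/\tau_\gamma} - \tau_p e^{-t/\tau_p}) /
#' (\tau_\gamma - \tau_p)} with \eqn{\tau_\gamma = m/\gamma}; reduces to
#' \eqn{e^{-t/\tau_\gamma}} as \eqn{\tau_p \to 0} and handles the degenerate
#' \eqn{\tau_p = \tau_\gamma} limit.
#'
#' @param t Lag times.
#' @param tau_gamma Velocity damping time \eqn{m/\gamma}.
#' @param tau_p Persistence time.
#' @return \eqn{C_{vv}(t)}.
#' @export
cvv_free_active <- function(t, tau_gamma, tau_p) {
  if (tau_p <= 0) return(exp(-t / tau_gamma))
  if (abs(tau_p - tau_gamma) < 1e-10 * tau_gamma)
    return((1 + t / tau_gamma) * exp(-t / tau_gamma))
  (tau_gamma * exp(-t / tau_gamma) - tau_p * exp(-t / tau_p)) /
    (tau_gamma - tau_p)
}

#' Fit the sigmoidal invasion curve
#'
#' Least-squares fit of
#' \eqn{A_n = \frac{1}{2}\left(\tanh\left[b \log_{10}\frac{k_bT}{a P
#' \sigma^3}\right] + 1\right)} to steady-state invasion data. By
#' construction the fitted curve passes through \eqn{A_n = 1/2} at
#' \eqn{k_bT/(P\sigma^3) = a}.
#'
#' @param x Values of \eqn{k_bT/(P\sigma^3)} (at least 5, spanning the
#'   transition).
#' @param A_n Normalized interfacial areas.
#' @return List with `a`, `b`, the `fit` object, and `fitted` values. Errors
#'   if the data do not span the transition (unidentifiable fit).
#' @export
fit_sigmoid <- function(x, A_n) {
  stopifnot(length(x) == length(A_n), length(x) >= 5)
  if (max(A_n) < 0.5 || min(A_n) > 0.5)
    stop("no transition in data range: sigmoid midpoint unidentifiable")
  la0 <- log10(x[which.min(abs(A_n - 0.5))])
  df <- data.frame(lx = log10(x), y = A_n)
  fit <- minpack.lm::nlsLM(y ~ 0.5 * (tanh(b * (lx - la)) + 1),
                           data = df, start = list(la = la0, b = 1),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  list(a = 10^cf[["la"]], b = cf[["b"]], fit = fit,
       fitted = as.numeric(predict(fit)))
}

#' Dimensionless invasion energy scale
#'
#' \eqn{E_c = k_bT / (a P \sigma^3)}: above 1 the fitted sigmoid predicts
#' invasion (\eqn{A_n > 1/2}), below 1 de-mixing.
#'
#' @param kT Measured kinetic temperature(s).
#' @param P Imposed pressure.
#' @param a Sigmoid midpoint from [fit_sigmoid()].
#' @return \eqn{E_c}.
#' @export
energy_scale <- function(kT, P, a) kT / (a * P)

#' Fit the activity-cohesion model for the sigmoid midpoint
#'
#' Across conditions, the midpoint follows
#' \eqn{a = c_1 (1 + c_2 \beta\epsilon_c/(P\sigma^3))\, \tau_\gamma/\tau_d}.
#' Dividing by \eqn{\tau_\gamma/\tau_d} makes the model linear in
#' \eqn{\beta/(P\sigma^3)}, so \eqn{c_1} is the intercept and
#' \eqn{c_2} the slope/intercept ratio of an ordinary least-squares fit.
#'
#' @param a Fitted sigmoid midpoints, one per condition.
#' @param beta Attraction depths.
#' @param P Pressures.
#' @param tau_gamma Damping times \eqn{m/\gamma}.
#' @param tau_d Velocity decorrelation times.
#' @return List with `c1`, `c2` and the `lm` fit. With a single condition the
#'   constants are unidentifiable and an error is raised.
#' @export
fit_collapse <- function(a, beta, P, tau_gamma, tau_d) {
  if (length(unique(beta / P)) < 2)
    stop("need at least two distinct beta/P conditions to identify c1, c2")
  y <- a * tau_d / tau_gamma
  x <- beta / P
  fit <- lm(y ~ x)
  c1 <- unname(coef(fit)[1])
  list(c1 = c1, c2 = unname(coef(fit)[2]) / c1, fit = fit)
}

#' Residual spread of the energy-scale collapse
#'
#' Bins \eqn{A_n} against \eqn{E_c^b} across conditions and reports the mean
#' within-bin spread (max - min), the overlay quality of the master curve.
#'
#' @param Ecb \eqn{E_c^b} values (all conditions pooled).
#' @param A_n Normalized interfacial areas.
#' @param bins Number of logarithmic bins.
#' @return Mean within-bin range of `A_n` over populated bins.
#' @export
collapse_residual <- function(Ecb, A_n, bins = 8) {
  br <- cut(log10(Ecb), breaks = bins)
  spread <- tapply(A_n, br, function(v) diff(range(v)))
  mean(spread[!is.na(spread) & tabulate(br, bins) > 1])
}
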