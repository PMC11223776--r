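#include "dem.h"
using namespace Rcpp;

// rotational diffusion of the active directions: dn = (chi dt) x n with
// Gaussian angular increments of per-component variance dt/taup, followed by
// renormalization; gives <n(0).n(t)> = exp(-t/taup)
static void rotate_dirs(std::vector<double> &dir, int Nc, double dt,
                        double taup) {
  if (!(taup > 0.0) || !std::isfinite(taup)) return;
  double sd = std::sqrt(dt / taup);
  for (int q = 0; q < Nc; ++q) {
    double cx = sd * R::norm_rand(), cy = sd * R::norm_rand(),
           cz = sd * R::norm_rand();
    double nx = dir[3 * q], ny = dir[3 * q + 1], nz = dir[3 * q + 2];
    double dx = cy * nz - cz * ny;
    double dy = cz * nx - cx * nz;
    double dz = cx * ny - cy * nx;
    nx += dx;
    ny += dy;
    nz += dz;
    double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
    dir[3 * q] = nx / nn;
    dir[3 * q + 1] = ny / nn;
    dir[3 * q + 2] = nz / nn;
  }
}

// [[Rcpp::export(name = ".cpp_rotate_dirs")]]
NumericMatrix cpp_rotate_dirs(NumericMatrix dirs, double dt, double taup,
                              int nsteps = 1) {
  int Nc = dirs.nrow();
  std::vector<double> d(3 * Nc);
  for (int i = 0; i < Nc; ++i)
    for (int k = 0; k < 3; ++k) d[3 * i + k] = dirs(i, k);
  for (int s = 0; s < nsteps; ++s) rotate_dirs(d, Nc, dt, taup);
  NumericMatrix out(Nc, 3);
  for (int i = 0; i < Nc; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = d[3 * i + k];
  return out;
}

// Velocity-Verlet/BAOAB integration: conservative + active forces enter the
// half kicks; damping (and, for passive cancer cells, the thermal noise) is
// applied through the exact Ornstein-Uhlenbeck flow in the middle O step.
// [[Rcpp::export(name = ".cpp_run")]]
List cpp_run(List state, List params, int nsteps, int rec_every,
             bool record_vel = false, bool record_dir = false) {
  SimState s = state_from_list(state);
  RunParams p = params_from_list(params);
  int nvert = s.Na * s.Nv;
  bool active = (p.model == 1);
  double h = p.dt, half = 0.5 * p.dt;
  double c = std::exp(-p.gamma * h);          // m = 1
  double nsd = std::sqrt((1.0 - c * c) * p.T0);
  double wallA = 0.0;

  ForceOut F;
  compute_forces(s, p, F, false);

  int nrec = (rec_every > 0) ? nsteps / rec_every : 0;
  NumericMatrix rec(nrec, 7);
  NumericMatrix velrec(record_vel ? nrec : 0, record_vel ? 3 * s.Nc : 0);
  NumericMatrix dirrec(record_dir ? nrec : 0, record_dir ? 3 * s.Nc : 0);
  int irec = 0;

  for (int step = 0; step < nsteps; ++step) {
    // B: half kick
    for (int i = 0; i < 3 * nvert; ++i) s.vv[i] += half * F.fv[i];
    for (int i = 0; i < s.Nc; ++i)
      for (int k = 0; k < 3; ++k) {
        double f = F.fc[3 * i + k];
        if (active) f += p.f0 * s.cdir[3 * i + k];
        s.cv[3 * i + k] += half * f;
      }
    if (p.wall_mobile)
      s.vl += half * (F.wfl + p.P * s.Ly * s.Lz);
    // A: half drift
    for (int i = 0; i < 3 * nvert; ++i) s.vx[i] += half * s.vv[i];
    for (int i = 0; i < 3 * s.Nc; ++i) s.cx[i] += half * s.cv[i];
    if (p.wall_mobile) s.xl += half * s.vl;
    // O: damping / thermal noise
    for (int i = 0; i < 3 * nvert; ++i) s.vv[i] *= c;
    if (!active && p.T0 > 0.0) {
      for (int i = 0; i < 3 * s.Nc; ++i)
        s.cv[i] = c * s.cv[i] + nsd * R::norm_rand();
    } else {
      for (int i = 0; i < 3 * s.Nc; ++i) s.cv[i] *= c;
    }
    if (p.wall_mobile) s.vl *= c;
    if (active) rotate_dirs(s.cdir, s.Nc, h, p.taup);
    // A: half drift
    for (int i = 0; i < 3 * nvert; ++i) s.vx[i] += half * s.vv[i];
    for (int i = 0; i < 3 * s.Nc; ++i) s.cx[i] += half * s.cv[i];
    if (p.wall_mobile) s.xl += half * s.vl;
    // B: half kick with fresh forces
    compute_forces(s, p, F, false);
    for (int i = 0; i < 3 * nvert; ++i) s.vv[i] += half * F.fv[i];
    for (int i = 0; i < s.Nc; ++i)
      for (int k = 0; k < 3; ++k) {
        double f = F.fc[3 * i + k];
        if (active) f += p.f0 * s.cdir[3 * i + k];
        s.cv[3 * i + k] += half * f;
      }
    if (p.wall_mobile)
      s.vl += half * (F.wfl + p.P * s.Ly * s.Lz);
    wallA += -F.wfl / (s.Ly * s.Lz);

    if (rec_every > 0 && (step + 1) % rec_every == 0) {
      double kc = 0.0, ka = 0.0;
      for (int i = 0; i < 3 * s.Nc; ++i) kc += s.cv[i] * s.cv[i];
      for (int i = 0; i < 3 * nvert; ++i) ka += s.vv[i] * s.vv[i];
      rec(irec, 0) = (step + 1) * h;
      rec(irec, 1) = (s.Nc > 0) ? kc / (3.0 * s.Nc) : 0.0;
      rec(irec, 2) = (nvert > 0) ? ka / (3.0 * nvert) : 0.0;
      rec(irec, 3) = s.xl;
      rec(irec, 4) = s.vl;
      rec(irec, 5) = wallA / (step + 1);  // running mean wall pressure
      rec(irec, 6) = F.U;
      if (record_vel)
        for (int i = 0; i < 3 * s.Nc; ++i) velrec(irec, i) = s.cv[i];
      if (record_dir)
        for (int i = 0; i < 3 * s.Nc; ++i) dirrec(irec, i) = s.cdir[i];
      ++irec;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  colnames(rec) = CharacterVector::create("t", "kT_c", "kT_a", "xl", "vl",
                                          "P_wall", "U");
  List out = List::create(_["state"] = state_to_list(s), _["records"] = rec);
  if (record_vel) out["vel"] = velrec;
  if (record_dir) out["dir"] = dirrec;
  return out;
}

// FIRE energy minimization over adipocyte vertices and cancer cells
// (walls held fixed; only conservative forces enter).
// [[Rcpp::export(name = ".cpp_fire")]]
List cpp_fire(List state, List params, double tol = 1e-8,
              int max_iter = 200000, double dt0 = 0.01, double dtmax = 0.1) {
  SimState s = state_from_list(state);
  RunParams p = params_from_list(params);
  int nvert = s.Na * s.Nv;
  int n = 3 * (nvert + s.Nc);
  std::vector<double> v(n, 0.0), f(n, 0.0);
  double dt = dt0, alpha = 0.1;
  const double f_inc = 1.1, f_dec = 0.5, alpha0 = 0.1, f_alpha = 0.99;
  const int n_min = 5;
  int npos = 0, it = 0;
  double fmax = 0.0;
  ForceOut F;

  auto get_forces = [&]() {
    compute_forces(s, p, F, false);
    for (int i = 0; i < 3 * nvert; ++i) f[i] = F.fv[i];
    for (int i = 0; i < 3 * s.Nc; ++i) f[3 * nvert + i] = F.fc[i];
    fmax = 0.0;
    for (int i = 0; i < n; ++i) fmax = std::max(fmax, std::fabs(f[i]));
  };
  get_forces();

  for (it = 0; it < max_iter && fmax > tol; ++it) {
    double pw = 0.0;
    for (int i = 0; i < n; ++i) pw += f[i] * v[i];
    if (pw > 0.0) {
      if (++npos > n_min) {
        dt = std::min(dt * f_inc, dtmax);
        alpha *= f_alpha;
      }
    } else {
      npos = 0;
      dt *= f_dec;
      alpha = alpha0;
      std::fill(v.begin(), v.end(), 0.0);
    }
    for (int i = 0; i < n; ++i) v[i] += dt * f[i];
    double vn = 0.0, fn = 0.0;
    for (int i = 0; i < n; ++i) {
      vn += v[i] * v[i];
      fn += f[i] * f[i];
    }
    vn = std::sqrt(vn);
    fn = std::sqrt(fn);
    if (fn > 1e-300)
      for (int i = 0; i < n; ++i)
        v[i] = (1.0 - alpha) * v[i] + alpha * vn * f[i] / fn;
    for (int i = 0; i < 3 * nvert; ++i) s.vx[i] += dt * v[i];
    for (int i = 0; i < 3 * s.Nc; ++i) s.cx[i] += dt * v[3 * nvert + i];
    get_forces();
    if (it % 5000 == 0) Rcpp::checkUserInterrupt();
  }
  // exit with zero velocities
  std::fill(s.vv.begin(), s.vv.end(), 0.0);
  std::fill(s.cv.begin(), s.cv.end(), 0.0);
  s.vl = 0.0;
  return List::create(_["state"] = state_to_list(s), _["iterations"] = it,
                      _["residual"] = fmax, _["converged"] = (fmax <= tol),
                      _["potential"] = F.U);
}
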