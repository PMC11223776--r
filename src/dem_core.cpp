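#include "dem.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// state marshalling

SimState state_from_list(List st) {
  SimState s;
  NumericMatrix vx = st["vert_pos"];
  NumericMatrix vv = st["vert_vel"];
  IntegerMatrix fc = st["faces"];
  NumericVector v0 = st["v0"];
  NumericMatrix a0 = st["a0"];
  s.Na = v0.size();
  s.Nf = fc.nrow();
  s.Nv = (s.Na > 0) ? vx.nrow() / s.Na : 0;
  s.vx.resize(3 * vx.nrow());
  s.vv.resize(3 * vx.nrow());
  for (int i = 0; i < vx.nrow(); ++i)
    for (int k = 0; k < 3; ++k) {
      s.vx[3 * i + k] = vx(i, k);
      s.vv[3 * i + k] = vv(i, k);
    }
  s.faces.resize(3 * s.Nf);
  for (int i = 0; i < s.Nf; ++i)
    for (int k = 0; k < 3; ++k) s.faces[3 * i + k] = fc(i, k) - 1;
  s.v0.assign(v0.begin(), v0.end());
  s.a0.resize(s.Na * s.Nf);
  for (int i = 0; i < s.Na; ++i)
    for (int k = 0; k < s.Nf; ++k) s.a0[i * s.Nf + k] = a0(i, k);
  s.sigv = as<double>(st["sigma_vertex"]);
  s.eps_v = as<double>(st["eps_v"]);
  s.eps_a = as<double>(st["eps_a"]);

  NumericMatrix cx = st["cell_pos"], cv = st["cell_vel"], cn = st["cell_dir"];
  NumericVector cd = st["cell_diam"];
  s.Nc = cx.nrow();
  s.cx.resize(3 * s.Nc);
  s.cv.resize(3 * s.Nc);
  s.cdir.resize(3 * s.Nc);
  for (int i = 0; i < s.Nc; ++i)
    for (int k = 0; k < 3; ++k) {
      s.cx[3 * i + k] = cx(i, k);
      s.cv[3 * i + k] = cv(i, k);
      s.cdir[3 * i + k] = cn(i, k);
    }
  s.cd.assign(cd.begin(), cd.end());

  s.xl = as<double>(st["xl"]);
  s.xr = as<double>(st["xr"]);
  s.vl = as<double>(st["vl"]);
  s.Ly = as<double>(st["Ly"]);
  s.Lz = as<double>(st["Lz"]);

  List te = st["tethers"];
  IntegerMatrix tp = te["pairs"];
  IntegerMatrix to = te["offsets"];
  NumericVector tl = te["l0"];
  s.Kecm = as<double>(te["Kecm"]);
  s.tpair.resize(2 * tp.nrow());
  s.toff.resize(2 * tp.nrow());
  for (int e = 0; e < tp.nrow(); ++e) {
    s.tpair[2 * e] = tp(e, 0) - 1;
    s.tpair[2 * e + 1] = tp(e, 1) - 1;
    s.toff[2 * e] = to(e, 0);
    s.toff[2 * e + 1] = to(e, 1);
  }
  s.tl0.assign(tl.begin(), tl.end());
  return s;
}

List state_to_list(const SimState &s) {
  int nv = s.Na * s.Nv;
  NumericMatrix vx(nv, 3), vv(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) {
      vx(i, k) = s.vx[3 * i + k];
      vv(i, k) = s.vv[3 * i + k];
    }
  IntegerMatrix fc(s.Nf, 3);
  for (int i = 0; i < s.Nf; ++i)
    for (int k = 0; k < 3; ++k) fc(i, k) = s.faces[3 * i + k] + 1;
  NumericMatrix a0(s.Na, s.Nf);
  for (int i = 0; i < s.Na; ++i)
    for (int k = 0; k < s.Nf; ++k) a0(i, k) = s.a0[i * s.Nf + k];
  NumericMatrix cx(s.Nc, 3), cv(s.Nc, 3), cn(s.Nc, 3);
  for (int i = 0; i < s.Nc; ++i)
    for (int k = 0; k < 3; ++k) {
      cx(i, k) = s.cx[3 * i + k];
      cv(i, k) = s.cv[3 * i + k];
      cn(i, k) = s.cdir[3 * i + k];
    }
  IntegerMatrix tp(s.tl0.size(), 2), to(s.tl0.size(), 2);
  for (size_t e = 0; e < s.tl0.size(); ++e) {
    tp(e, 0) = s.tpair[2 * e] + 1;
    tp(e, 1) = s.tpair[2 * e + 1] + 1;
    to(e, 0) = s.toff[2 * e];
    to(e, 1) = s.toff[2 * e + 1];
  }
  return List::create(
      _["vert_pos"] = vx, _["vert_vel"] = vv, _["faces"] = fc,
      _["v0"] = NumericVector(s.v0.begin(), s.v0.end()), _["a0"] = a0,
      _["sigma_vertex"] = s.sigv, _["eps_v"] = s.eps_v, _["eps_a"] = s.eps_a,
      _["cell_pos"] = cx, _["cell_vel"] = cv, _["cell_dir"] = cn,
      _["cell_diam"] = NumericVector(s.cd.begin(), s.cd.end()),
      _["xl"] = s.xl, _["xr"] = s.xr, _["vl"] = s.vl, _["Ly"] = s.Ly,
      _["Lz"] = s.Lz,
      _["tethers"] = List::create(
          _["pairs"] = tp, _["offsets"] = to,
          _["l0"] = NumericVector(s.tl0.begin(), s.tl0.end()),
          _["Kecm"] = s.Kecm));
}

RunParams params_from_list(List pr) {
  RunParams p;
  p.dt = as<double>(pr["dt"]);
  p.gamma = as<double>(pr["gamma"]);
  p.alpha = as<double>(pr["alpha"]);
  p.beta = as<double>(pr["beta"]);
  p.model = as<int>(pr["model"]);
  p.f0 = as<double>(pr["f0"]);
  p.T0 = as<double>(pr["T0"]);
  p.taup = as<double>(pr["taup"]);
  p.P = as<double>(pr["P"]);
  p.wall_mobile = as<bool>(pr["wall_mobile"]);
  p.periodic_x = as<bool>(pr["periodic_x"]);
  p.pair_forces = as<bool>(pr["pair_forces"]);
  p.walls_on = as<bool>(pr["walls_on"]);
  return p;
}

// ---------------------------------------------------------------------------
// deformable-particle mesh quantities

static inline void cross3(const double *a, const double *b, double *c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

double mesh_volume_c(const std::vector<double> &x, const std::vector<int> &f,
                     int Nf) {
  double v = 0.0;
  double c[3];
  for (int k = 0; k < Nf; ++k) {
    const double *a = &x[3 * f[3 * k]];
    const double *b = &x[3 * f[3 * k + 1]];
    const double *cc = &x[3 * f[3 * k + 2]];
    cross3(b, cc, c);
    v += (a[0] * c[0] + a[1] * c[1] + a[2] * c[2]) / 6.0;
  }
  return v;
}

void face_areas_c(const std::vector<double> &x, const std::vector<int> &f,
                  int Nf, std::vector<double> &areas) {
  areas.resize(Nf);
  double u[3], w[3], n[3];
  for (int k = 0; k < Nf; ++k) {
    const double *a = &x[3 * f[3 * k]];
    const double *b = &x[3 * f[3 * k + 1]];
    const double *c = &x[3 * f[3 * k + 2]];
    for (int d = 0; d < 3; ++d) {
      u[d] = b[d] - a[d];
      w[d] = c[d] - a[d];
    }
    cross3(u, w, n);
    areas[k] = 0.5 * std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
  }
}

double shape_energy_c(const std::vector<double> &x, const std::vector<int> &f,
                      int Nf, double v0, const double *a0, double eps_v,
                      double eps_a) {
  double v = mesh_volume_c(x, f, Nf);
  std::vector<double> ar;
  face_areas_c(x, f, Nf, ar);
  double U = 0.5 * eps_v * (1.0 - v / v0) * (1.0 - v / v0);
  for (int k = 0; k < Nf; ++k) {
    double d = 1.0 - ar[k] / a0[k];
    U += 0.5 * eps_a * d * d;
  }
  return U;
}

void shape_forces_c(const std::vector<double> &x, const std::vector<int> &f,
                    int Nf, double v0, const double *a0, double eps_v,
                    double eps_a, std::vector<double> &force) {
  force.assign(x.size(), 0.0);
  double v = mesh_volume_c(x, f, Nf);
  double cv = eps_v * (1.0 - v / v0) / v0;  // coefficient on grad v
  double u[3], w[3], n[3], g[3];
  for (int k = 0; k < Nf; ++k) {
    int ia = f[3 * k], ib = f[3 * k + 1], ic = f[3 * k + 2];
    const double *a = &x[3 * ia];
    const double *b = &x[3 * ib];
    const double *c = &x[3 * ic];
    // volume term: grad_a v = (b x c)/6 etc.
    cross3(b, c, g);
    for (int d = 0; d < 3; ++d) force[3 * ia + d] += cv * g[d] / 6.0;
    cross3(c, a, g);
    for (int d = 0; d < 3; ++d) force[3 * ib + d] += cv * g[d] / 6.0;
    cross3(a, b, g);
    for (int d = 0; d < 3; ++d) force[3 * ic + d] += cv * g[d] / 6.0;
    // area term
    for (int d = 0; d < 3; ++d) {
      u[d] = b[d] - a[d];
      w[d] = c[d] - a[d];
    }
    cross3(u, w, n);
    double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    double ak = 0.5 * nn;
    double ca = eps_a * (1.0 - ak / a0[k]) / a0[k];  // coefficient on grad a
    // grad_a a = n x (c - b) / (2|n|), cyclic
    double e[3];
    for (int d = 0; d < 3; ++d) e[d] = c[d] - b[d];
    cross3(n, e, g);
    for (int d = 0; d < 3; ++d) force[3 * ia + d] += ca * g[d] / (2.0 * nn);
    for (int d = 0; d < 3; ++d) e[d] = a[d] - c[d];
    cross3(n, e, g);
    for (int d = 0; d < 3; ++d) force[3 * ib + d] += ca * g[d] / (2.0 * nn);
    for (int d = 0; d < 3; ++d) e[d] = b[d] - a[d];
    cross3(n, e, g);
    for (int d = 0; d < 3; ++d) force[3 * ic + d] += ca * g[d] / (2.0 * nn);
  }
}

// ---------------------------------------------------------------------------
// pair forces
//
// All pair interactions are linear springs in the overlap; cancer-cancer pairs
// add the short-range attractive well of depth beta and range alpha.
// g > 0 is repulsive along the unit separation vector.

static inline void pair_rep(double r, double st, double &g, double &U) {
  double u = 1.0 - r / st;
  g = u / st;
  U = 0.5 * u * u;
}

static inline bool pair_cc(double r, double st, double alpha, double beta,
                           double &g, double &U) {
  double rb = st * (1.0 + beta), ra = st * (1.0 + alpha);
  if (r > ra) return false;
  if (r <= rb) {
    double u = 1.0 - r / st;
    g = u / st;
    U = 0.5 * u * u - 0.5 * alpha * beta;
  } else {
    g = beta * (r - ra) / ((alpha - beta) * st * st);
    U = -0.5 * beta * (r - ra) * (r - ra) / ((alpha - beta) * st * st);
  }
  return true;
}

// group id: adipocyte index for vertices, -1 for cancer cells
struct PairCtx {
  const SimState *s;
  const RunParams *p;
  ForceOut *out;
  int nvert;
};

static inline void apply_pair(PairCtx &ctx, int i, int j, double dx, double dy,
                              double dz) {
  const SimState &s = *ctx.s;
  const RunParams &p = *ctx.p;
  int nvert = ctx.nvert;
  bool iv = i < nvert, jv = j < nvert;
  if (iv && jv && (i / s.Nv) == (j / s.Nv)) return;  // same adipocyte
  double st, g = 0.0, U = 0.0;
  double r2 = dx * dx + dy * dy + dz * dz;
  if (iv && jv) {
    st = s.sigv;
    if (r2 >= st * st) return;
  } else if (!iv && !jv) {
    st = 0.5 * (s.cd[i - nvert] + s.cd[j - nvert]);
    double ra = st * (1.0 + p.alpha);
    if (p.beta <= 0.0) {
      if (r2 >= st * st) return;
    } else if (r2 >= ra * ra) {
      return;
    }
  } else {
    int q = iv ? (j - nvert) : (i - nvert);
    st = 0.5 * (s.sigv + s.cd[q]);
    if (r2 >= st * st) return;
  }
  double r = std::sqrt(r2);
  if (r < 1e-14) return;  // coincident centres: no defined direction
  if (!iv && !jv && p.beta > 0.0) {
    if (!pair_cc(r, st, p.alpha, p.beta, g, U)) return;
  } else {
    if (r >= st) return;
    pair_rep(r, st, g, U);
  }
  double fx = g * dx / r, fy = g * dy / r, fz = g * dz / r;
  std::vector<double> &fi = iv ? ctx.out->fv : ctx.out->fc;
  std::vector<double> &fj = jv ? ctx.out->fv : ctx.out->fc;
  int ii = iv ? i : i - nvert, jj = jv ? j : j - nvert;
  fi[3 * ii] += fx;
  fi[3 * ii + 1] += fy;
  fi[3 * ii + 2] += fz;
  fj[3 * jj] -= fx;
  fj[3 * jj + 1] -= fy;
  fj[3 * jj + 2] -= fz;
  ctx.out->U += U;
}

void compute_forces(const SimState &s, const RunParams &p, ForceOut &out,
                    bool brute) {
  int nvert = s.Na * s.Nv;
  int N = nvert + s.Nc;
  out.fv.assign(3 * nvert, 0.0);
  out.fc.assign(3 * s.Nc, 0.0);
  out.U = 0.0;
  out.wfl = 0.0;
  out.wfr = 0.0;

  // gather all particle positions contiguously (vertices then cells)
  static thread_local std::vector<double> pos;
  pos.resize(3 * N);
  std::copy(s.vx.begin(), s.vx.end(), pos.begin());
  std::copy(s.cx.begin(), s.cx.end(), pos.begin() + 3 * nvert);
  auto px = [&](int i, int k) -> double { return pos[3 * i + k]; };

  double Lx = s.xr - s.xl;
  PairCtx ctx{&s, &p, &out, nvert};

  if (p.pair_forces) {
    double cut = std::max(s.sigv, 1.1 * (1.0 + p.alpha));
    cut = std::max(cut, 0.5 * (s.sigv + 1.1));
    int ncx = std::max(1, (int)std::floor(Lx / cut));
    int ncy = std::max(1, (int)std::floor(s.Ly / cut));
    int ncz = std::max(1, (int)std::floor(s.Lz / cut));
    bool can_grid = !brute && ncy >= 3 && ncz >= 3 && (!p.periodic_x || ncx >= 3) &&
                    (double)ncx * ncy * ncz < 8.0e6 && N > 32;
    if (!can_grid) {
      for (int i = 0; i < N; ++i)
        for (int j = i + 1; j < N; ++j) {
          double dx = px(i, 0) - px(j, 0);
          double dy = min_image(px(i, 1) - px(j, 1), s.Ly);
          double dz = min_image(px(i, 2) - px(j, 2), s.Lz);
          if (p.periodic_x) dx = min_image(dx, Lx);
          apply_pair(ctx, i, j, dx, dy, dz);
        }
    } else {
      // cell list
      std::vector<int> head(ncx * ncy * ncz, -1), nxt(N, -1), cix(N), ciy(N),
          ciz(N);
      for (int i = 0; i < N; ++i) {
        double X = px(i, 0) - s.xl, Y = px(i, 1), Z = px(i, 2);
        Y -= s.Ly * std::floor(Y / s.Ly);
        Z -= s.Lz * std::floor(Z / s.Lz);
        int cx0 = std::min(ncx - 1, std::max(0, (int)(X / Lx * ncx)));
        int cy0 = std::min(ncy - 1, std::max(0, (int)(Y / s.Ly * ncy)));
        int cz0 = std::min(ncz - 1, std::max(0, (int)(Z / s.Lz * ncz)));
        cix[i] = cx0;
        ciy[i] = cy0;
        ciz[i] = cz0;
        int c = (cx0 * ncy + cy0) * ncz + cz0;
        nxt[i] = head[c];
        head[c] = i;
      }
      for (int i = 0; i < N; ++i) {
        for (int ox = -1; ox <= 1; ++ox) {
          int ax = cix[i] + ox;
          if (p.periodic_x)
            ax = (ax + ncx) % ncx;
          else if (ax < 0 || ax >= ncx)
            continue;
          for (int oy = -1; oy <= 1; ++oy) {
            int ay = (ciy[i] + oy + ncy) % ncy;
            for (int oz = -1; oz <= 1; ++oz) {
              int az = (ciz[i] + oz + ncz) % ncz;
              int c = (ax * ncy + ay) * ncz + az;
              for (int j = head[c]; j >= 0; j = nxt[j]) {
                if (j <= i) continue;
                double dx = px(i, 0) - px(j, 0);
                double dy = min_image(px(i, 1) - px(j, 1), s.Ly);
                double dz = min_image(px(i, 2) - px(j, 2), s.Lz);
                if (p.periodic_x) dx = min_image(dx, Lx);
                apply_pair(ctx, i, j, dx, dy, dz);
              }
            }
          }
        }
      }
    }
  }

  // walls: repulsion active when the particle centre is within one diameter
  if (p.walls_on && !p.periodic_x) {
    for (int i = 0; i < N; ++i) {
      double sd = (i < nvert) ? s.sigv : s.cd[i - nvert];
      double X = px(i, 0);
      std::vector<double> &f = (i < nvert) ? out.fv : out.fc;
      int ii = (i < nvert) ? i : i - nvert;
      double dl = X - s.xl;
      if (dl <= sd) {
        double g = (1.0 - dl / sd) / sd;
        f[3 * ii] += g;
        out.wfl -= g;
        out.U += 0.5 * (1.0 - dl / sd) * (1.0 - dl / sd);
      }
      double dr = s.xr - X;
      if (dr <= sd) {
        double g = (1.0 - dr / sd) / sd;
        f[3 * ii] -= g;
        out.wfr += g;
        out.U += 0.5 * (1.0 - dr / sd) * (1.0 - dr / sd);
      }
    }
  }

  // tethers: centre-of-mass springs shared equally by all vertices
  if (s.Kecm > 0.0 && !s.tl0.empty()) {
    std::vector<double> R(3 * s.Na, 0.0);
    for (int i = 0; i < s.Na; ++i) {
      for (int m = 0; m < s.Nv; ++m)
        for (int k = 0; k < 3; ++k) R[3 * i + k] += s.vx[3 * (i * s.Nv + m) + k];
      for (int k = 0; k < 3; ++k) R[3 * i + k] /= s.Nv;
    }
    for (size_t e = 0; e < s.tl0.size(); ++e) {
      int i = s.tpair[2 * e], j = s.tpair[2 * e + 1];
      double dx = R[3 * i] - R[3 * j];
      double dy = R[3 * i + 1] - R[3 * j + 1] + s.toff[2 * e] * s.Ly;
      double dz = R[3 * i + 2] - R[3 * j + 2] + s.toff[2 * e + 1] * s.Lz;
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-14) continue;
      double fmag = -s.Kecm * (r - s.tl0[e]);  // >0 means push apart
      out.U += 0.5 * s.Kecm * (r - s.tl0[e]) * (r - s.tl0[e]);
      double fx = fmag * dx / r / s.Nv, fy = fmag * dy / r / s.Nv,
             fz = fmag * dz / r / s.Nv;
      for (int m = 0; m < s.Nv; ++m) {
        out.fv[3 * (i * s.Nv + m)] += fx;
        out.fv[3 * (i * s.Nv + m) + 1] += fy;
        out.fv[3 * (i * s.Nv + m) + 2] += fz;
        out.fv[3 * (j * s.Nv + m)] -= fx;
        out.fv[3 * (j * s.Nv + m) + 1] -= fy;
        out.fv[3 * (j * s.Nv + m) + 2] -= fz;
      }
    }
  }

  // shape energy of each adipocyte
  if (s.Na > 0) {
    std::vector<double> xi(3 * s.Nv), fi;
    for (int i = 0; i < s.Na; ++i) {
      for (int m = 0; m < s.Nv; ++m)
        for (int k = 0; k < 3; ++k) xi[3 * m + k] = s.vx[3 * (i * s.Nv + m) + k];
      out.U += shape_energy_c(xi, s.faces, s.Nf, s.v0[i], &s.a0[i * s.Nf],
                              s.eps_v, s.eps_a);
      shape_forces_c(xi, s.faces, s.Nf, s.v0[i], &s.a0[i * s.Nf], s.eps_v,
                     s.eps_a, fi);
      for (int m = 0; m < s.Nv; ++m)
        for (int k = 0; k < 3; ++k)
          out.fv[3 * (i * s.Nv + m) + k] += fi[3 * m + k];
    }
  }
}

// [[Rcpp::export(name = ".cpp_total_forces")]]
List cpp_total_forces(List state, List params, bool brute = false) {
  SimState s = state_from_list(state);
  RunParams p = params_from_list(params);
  ForceOut out;
  compute_forces(s, p, out, brute);
  int nvert = s.Na * s.Nv;
  NumericMatrix fv(nvert, 3), fc(s.Nc, 3);
  for (int i = 0; i < nvert; ++i)
    for (int k = 0; k < 3; ++k) fv(i, k) = out.fv[3 * i + k];
  for (int i = 0; i < s.Nc; ++i)
    for (int k = 0; k < 3; ++k) fc(i, k) = out.fc[3 * i + k];
  return List::create(_["vert_forces"] = fv, _["cell_forces"] = fc,
                      _["potential"] = out.U, _["wall_force_left"] = out.wfl,
                      _["wall_force_right"] = out.wfr);
}
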