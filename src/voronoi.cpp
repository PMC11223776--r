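#include "dem.h"
#include <array>
#include <algorithm>
using namespace Rcpp;

// Radical (Laguerre) tessellation by half-space clipping of each seed's cell,
// bounded by the wall planes in x and periodic images in y and z.

typedef std::array<double, 3> P3;

struct Face {
  int nb;  // >=0: seed index; -2 left wall; -3 right wall; -4 box leftover
  std::vector<P3> v;
};

static double poly_area(const std::vector<P3> &v, P3 *normal = nullptr) {
  // Newell's method
  double nx = 0, ny = 0, nz = 0;
  int n = v.size();
  for (int i = 0; i < n; ++i) {
    const P3 &a = v[i], &b = v[(i + 1) % n];
    nx += (a[1] - b[1]) * (a[2] + b[2]);
    ny += (a[2] - b[2]) * (a[0] + b[0]);
    nz += (a[0] - b[0]) * (a[1] + b[1]);
  }
  double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  if (normal && nn > 0) {
    (*normal)[0] = nx / nn;
    (*normal)[1] = ny / nn;
    (*normal)[2] = nz / nn;
  }
  return 0.5 * nn;
}

// clip convex polyhedron by half-space n.x <= d; returns false if empty
static bool clip_poly(std::vector<Face> &faces, const P3 &n, double d, int nb,
                      double eps) {
  std::vector<P3> cap;
  std::vector<Face> out;
  bool any_cut = false;
  for (Face &f : faces) {
    int m = f.v.size();
    std::vector<double> dist(m);
    int npos = 0, nneg = 0;
    for (int i = 0; i < m; ++i) {
      dist[i] = n[0] * f.v[i][0] + n[1] * f.v[i][1] + n[2] * f.v[i][2] - d;
      if (dist[i] > eps) ++npos;
      else if (dist[i] < -eps) ++nneg;
    }
    if (npos == 0) {  // fully kept
      out.push_back(std::move(f));
      continue;
    }
    any_cut = true;
    if (nneg == 0) continue;  // fully removed
    Face g;
    g.nb = f.nb;
    for (int i = 0; i < m; ++i) {
      int j = (i + 1) % m;
      bool ini = dist[i] <= eps, inj = dist[j] <= eps;
      if (ini) g.v.push_back(f.v[i]);
      if ((dist[i] > eps) != (dist[j] > eps)) {
        double t = dist[i] / (dist[i] - dist[j]);
        P3 p;
        for (int k = 0; k < 3; ++k)
          p[k] = f.v[i][k] + t * (f.v[j][k] - f.v[i][k]);
        g.v.push_back(p);
        cap.push_back(p);
      }
      (void)ini;
      (void)inj;
    }
    if (g.v.size() >= 3) out.push_back(std::move(g));
  }
  if (any_cut && cap.size() >= 3) {
    // build the cap as the convex hull of the intersection points in the
    // plane's 2D coordinates (robust against edge-chaining degeneracies)
    P3 e1, e2;
    double ax = std::fabs(n[0]), ay = std::fabs(n[1]), az = std::fabs(n[2]);
    P3 ref = (ax <= ay && ax <= az) ? P3{1, 0, 0}
             : (ay <= az)           ? P3{0, 1, 0}
                                    : P3{0, 0, 1};
    e1 = {n[1] * ref[2] - n[2] * ref[1], n[2] * ref[0] - n[0] * ref[2],
          n[0] * ref[1] - n[1] * ref[0]};
    double l1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
    for (int k = 0; k < 3; ++k) e1[k] /= l1;
    e2 = {n[1] * e1[2] - n[2] * e1[1], n[2] * e1[0] - n[0] * e1[2],
          n[0] * e1[1] - n[1] * e1[0]};
    double l2 = std::sqrt(e2[0] * e2[0] + e2[1] * e2[1] + e2[2] * e2[2]);
    for (int k = 0; k < 3; ++k) e2[k] /= l2;
    std::vector<std::array<double, 2>> pts2(cap.size());
    for (size_t i = 0; i < cap.size(); ++i) {
      pts2[i][0] = cap[i][0] * e1[0] + cap[i][1] * e1[1] + cap[i][2] * e1[2];
      pts2[i][1] = cap[i][0] * e2[0] + cap[i][1] * e2[1] + cap[i][2] * e2[2];
    }
    std::vector<int> idx(cap.size());
    for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      return pts2[a][0] < pts2[b][0] ||
             (pts2[a][0] == pts2[b][0] && pts2[a][1] < pts2[b][1]);
    });
    auto cross2 = [&](int o, int a, int b) {
      return (pts2[a][0] - pts2[o][0]) * (pts2[b][1] - pts2[o][1]) -
             (pts2[a][1] - pts2[o][1]) * (pts2[b][0] - pts2[o][0]);
    };
    std::vector<int> hull;
    for (int i : idx) {
      while (hull.size() >= 2 &&
             cross2(hull[hull.size() - 2], hull.back(), i) <= 0)
        hull.pop_back();
      hull.push_back(i);
    }
    size_t lower = hull.size() + 1;
    for (int t = idx.size() - 2; t >= 0; --t) {
      int i = idx[t];
      while (hull.size() >= lower &&
             cross2(hull[hull.size() - 2], hull.back(), i) <= 0)
        hull.pop_back();
      hull.push_back(i);
    }
    hull.pop_back();
    if (hull.size() >= 3) {
      Face g;
      g.nb = nb;
      for (int i : hull) g.v.push_back(cap[i]);
      out.push_back(std::move(g));
    }
  }
  faces.swap(out);
  return !faces.empty();
}

// [[Rcpp::export(name = ".cpp_power_cells")]]
List cpp_power_cells(NumericMatrix pts, NumericVector rad, IntegerVector group,
                     double xl, double xr, double Ly, double Lz,
                     bool radical = true) {
  int N = pts.nrow();
  double eps = 1e-9 * std::max(std::max(xr - xl, Ly), Lz);
  double rmax = 0.0;
  std::vector<double> w(N, 0.0);
  if (radical)
    for (int i = 0; i < N; ++i) {
      w[i] = rad[i] * rad[i];
      rmax = std::max(rmax, (double)rad[i]);
    }

  NumericMatrix areas(N, 7);
  NumericVector vol(N);
  colnames(areas) = CharacterVector::create("cancer", "same_adip",
                                            "other_adip", "wall_l", "wall_r",
                                            "box", "total");

  struct Cand {
    double d2;
    int j;
    double y, z;
  };
  std::vector<Cand> cand;
  cand.reserve(9 * N);

  for (int i = 0; i < N; ++i) {
    double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    // initial polyhedron: slab between walls, +/- L/2 in the periodic dirs
    double y0 = yi - Ly / 2, y1 = yi + Ly / 2, z0 = zi - Lz / 2,
           z1 = zi + Lz / 2;
    std::vector<Face> faces(6);
    faces[0] = {-2, {{xl, y0, z0}, {xl, y1, z0}, {xl, y1, z1}, {xl, y0, z1}}};
    faces[1] = {-3, {{xr, y0, z0}, {xr, y0, z1}, {xr, y1, z1}, {xr, y1, z0}}};
    faces[2] = {-4, {{xl, y0, z0}, {xl, y0, z1}, {xr, y0, z1}, {xr, y0, z0}}};
    faces[3] = {-4, {{xl, y1, z0}, {xr, y1, z0}, {xr, y1, z1}, {xl, y1, z1}}};
    faces[4] = {-4, {{xl, y0, z0}, {xr, y0, z0}, {xr, y1, z0}, {xl, y1, z0}}};
    faces[5] = {-4, {{xl, y0, z1}, {xl, y1, z1}, {xr, y1, z1}, {xr, y0, z1}}};

    cand.clear();
    for (int j = 0; j < N; ++j) {
      double dyb = min_image(pts(j, 1) - yi, Ly);
      double dzb = min_image(pts(j, 2) - zi, Lz);
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          if (j == i && std::fabs(dyb + oy * Ly) < eps &&
              std::fabs(dzb + oz * Lz) < eps)
            continue;
          double dy = dyb + oy * Ly, dz = dzb + oz * Lz;
          double dx = pts(j, 0) - xi;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < eps * eps) continue;  // coincident seed (jittered upstream)
          cand.push_back({d2, j, yi + dy, zi + dz});
        }
    }
    std::sort(cand.begin(), cand.end(),
              [](const Cand &a, const Cand &b) { return a.d2 < b.d2; });

    bool alive = true;
    for (const Cand &cc : cand) {
      // early stop: plane cannot cut the current cell
      double maxR2 = 0.0;
      for (const Face &f : faces)
        for (const P3 &v : f.v) {
          double dx = v[0] - xi, dy = v[1] - yi, dz = v[2] - zi;
          maxR2 = std::max(maxR2, dx * dx + dy * dy + dz * dz);
        }
      double dlim = 2.0 * std::sqrt(maxR2) + 2.0 * rmax;
      if (cc.d2 > dlim * dlim) break;
      double px = pts(cc.j, 0), py = cc.y, pz = cc.z;
      P3 n = {px - xi, py - yi, pz - zi};
      double d = 0.5 * (px * px + py * py + pz * pz -
                        (xi * xi + yi * yi + zi * zi) + w[i] - w[cc.j]);
      if (!clip_poly(faces, n, d, cc.j, eps)) {
        alive = false;
        break;
      }
    }
    if (!alive) {
      vol[i] = 0.0;
      continue;
    }

    // centroid-ish interior point
    P3 c = {0, 0, 0};
    int nv = 0;
    for (const Face &f : faces)
      for (const P3 &v : f.v) {
        for (int k = 0; k < 3; ++k) c[k] += v[k];
        ++nv;
      }
    for (int k = 0; k < 3; ++k) c[k] /= nv;

    double V = 0.0;
    for (const Face &f : faces) {
      P3 nrm;
      double A = poly_area(f.v, &nrm);
      if (A < eps * eps) continue;
      P3 fc = {0, 0, 0};
      for (const P3 &v : f.v)
        for (int k = 0; k < 3; ++k) fc[k] += v[k];
      for (int k = 0; k < 3; ++k) fc[k] /= f.v.size();
      double hgt = std::fabs((fc[0] - c[0]) * nrm[0] + (fc[1] - c[1]) * nrm[1] +
                             (fc[2] - c[2]) * nrm[2]);
      V += A * hgt / 3.0;
      int col;
      if (f.nb == -2) col = 3;
      else if (f.nb == -3) col = 4;
      else if (f.nb < 0) col = 5;
      else {
        int gj = group[f.nb], gi = group[i];
        if (gj < 0) col = 0;                 // neighbor is a cancer cell
        else if (gj == gi && gi >= 0) col = 1;  // same adipocyte
        else col = 2;                        // (other) adipocyte
      }
      areas(i, col) += A;
      areas(i, 6) += A;
    }
    vol[i] = V;
  }
  return List::create(_["areas"] = areas, _["volumes"] = vol);
}
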