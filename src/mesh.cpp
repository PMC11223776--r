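#include "dem.h"
using namespace Rcpp;

static std::vector<double> mat_to_vec(NumericMatrix V) {
  std::vector<double> x(3 * V.nrow());
  for (int i = 0; i < V.nrow(); ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = V(i, k);
  return x;
}

static std::vector<int> faces_to_vec(IntegerMatrix F) {
  std::vector<int> f(3 * F.nrow());
  for (int i = 0; i < F.nrow(); ++i)
    for (int k = 0; k < 3; ++k) f[3 * i + k] = F(i, k) - 1;
  return f;
}

// [[Rcpp::export(name = ".cpp_mesh_volume")]]
double cpp_mesh_volume(NumericMatrix V, IntegerMatrix F) {
  std::vector<double> x = mat_to_vec(V);
  std::vector<int> f = faces_to_vec(F);
  return mesh_volume_c(x, f, F.nrow());
}

// [[Rcpp::export(name = ".cpp_face_areas")]]
NumericVector cpp_face_areas(NumericMatrix V, IntegerMatrix F) {
  std::vector<double> x = mat_to_vec(V);
  std::vector<int> f = faces_to_vec(F);
  std::vector<double> a;
  face_areas_c(x, f, F.nrow(), a);
  return NumericVector(a.begin(), a.end());
}

// [[Rcpp::export(name = ".cpp_shape_energy")]]
double cpp_shape_energy(NumericMatrix V, IntegerMatrix F, double v0,
                        NumericVector a0, double eps_v, double eps_a) {
  std::vector<double> x = mat_to_vec(V);
  std::vector<int> f = faces_to_vec(F);
  return shape_energy_c(x, f, F.nrow(), v0, a0.begin(), eps_v, eps_a);
}

// [[Rcpp::export(name = ".cpp_shape_forces")]]
NumericMatrix cpp_shape_forces(NumericMatrix V, IntegerMatrix F, double v0,
                               NumericVector a0, double eps_v, double eps_a) {
  std::vector<double> x = mat_to_vec(V);
  std::vector<int> f = faces_to_vec(F);
  std::vector<double> fo;
  shape_forces_c(x, f, F.nrow(), v0, a0.begin(), eps_v, eps_a, fo);
  NumericMatrix out(V.nrow(), 3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = fo[3 * i + k];
  return out;
}

// skew(v) %*% a == v x a
static inline void skew(const double *v, double S[3][3]) {
  S[0][0] = 0;      S[0][1] = -v[2]; S[0][2] = v[1];
  S[1][0] = v[2];   S[1][1] = 0;     S[1][2] = -v[0];
  S[2][0] = -v[1];  S[2][1] = v[0];  S[2][2] = 0;
}

static void matmul3(const double A[3][3], const double B[3][3],
                    double C[3][3]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += A[i][k] * B[k][j];
      C[i][j] = s;
    }
}

// Analytic Hessian of the shape energy
//   U = eps_v/2 (1 - v/v0)^2 + eps_a/2 sum_k (1 - a_k/a0_k)^2
// with respect to the 3 Nv vertex coordinates.
// [[Rcpp::export(name = ".cpp_shape_hessian")]]
NumericMatrix cpp_shape_hessian(NumericMatrix V, IntegerMatrix F, double v0,
                                NumericVector a0, double eps_v, double eps_a) {
  int Nv = V.nrow(), Nf = F.nrow();
  std::vector<double> x = mat_to_vec(V);
  std::vector<int> f = faces_to_vec(F);
  int n = 3 * Nv;
  NumericMatrix H(n, n);
  double vol = mesh_volume_c(x, f, Nf);

  // grad v (for the rank-1 volume term)
  std::vector<double> gv(n, 0.0);
  for (int k = 0; k < Nf; ++k) {
    int id[3] = {f[3 * k], f[3 * k + 1], f[3 * k + 2]};
    const double *a = &x[3 * id[0]], *b = &x[3 * id[1]], *c = &x[3 * id[2]];
    double g[3];
    g[0] = (b[1] * c[2] - b[2] * c[1]) / 6.0;
    g[1] = (b[2] * c[0] - b[0] * c[2]) / 6.0;
    g[2] = (b[0] * c[1] - b[1] * c[0]) / 6.0;
    for (int d = 0; d < 3; ++d) gv[3 * id[0] + d] += g[d];
    g[0] = (c[1] * a[2] - c[2] * a[1]) / 6.0;
    g[1] = (c[2] * a[0] - c[0] * a[2]) / 6.0;
    g[2] = (c[0] * a[1] - c[1] * a[0]) / 6.0;
    for (int d = 0; d < 3; ++d) gv[3 * id[1] + d] += g[d];
    g[0] = (a[1] * b[2] - a[2] * b[1]) / 6.0;
    g[1] = (a[2] * b[0] - a[0] * b[2]) / 6.0;
    g[2] = (a[0] * b[1] - a[1] * b[0]) / 6.0;
    for (int d = 0; d < 3; ++d) gv[3 * id[2] + d] += g[d];
  }
  double cv1 = eps_v / (v0 * v0);               // on grad v grad v^T
  double cv2 = -eps_v * (1.0 - vol / v0) / v0;  // on hess v
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) H(i, j) += cv1 * gv[i] * gv[j];

  for (int k = 0; k < Nf; ++k) {
    int id[3] = {f[3 * k], f[3 * k + 1], f[3 * k + 2]};
    const double *a = &x[3 * id[0]], *b = &x[3 * id[1]], *c = &x[3 * id[2]];
    // volume Hessian blocks: d2v/(dra drb) = -skew(c)/6, etc.
    double S[3][3];
    const double *third[3][3] = {{nullptr, c, b}, {c, nullptr, a},
                                 {b, a, nullptr}};
    double sgn[3][3] = {{0, -1, 1}, {1, 0, -1}, {-1, 1, 0}};
    for (int p = 0; p < 3; ++p)
      for (int q = 0; q < 3; ++q) {
        if (p == q) continue;
        skew(third[p][q], S);
        for (int d1 = 0; d1 < 3; ++d1)
          for (int d2 = 0; d2 < 3; ++d2)
            H(3 * id[p] + d1, 3 * id[q] + d2) +=
                cv2 * sgn[p][q] * S[d1][d2] / 6.0;
      }

    // area term, in edge coordinates u = rb - ra, w = rc - ra
    double u[3], w[3], nrm[3];
    for (int d = 0; d < 3; ++d) {
      u[d] = b[d] - a[d];
      w[d] = c[d] - a[d];
    }
    nrm[0] = u[1] * w[2] - u[2] * w[1];
    nrm[1] = u[2] * w[0] - u[0] * w[2];
    nrm[2] = u[0] * w[1] - u[1] * w[0];
    double nn = std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] + nrm[2] * nrm[2]);
    double ak = 0.5 * nn;
    double nh[3] = {nrm[0] / nn, nrm[1] / nn, nrm[2] / nn};
    double P[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        P[i][j] = ((i == j) ? 1.0 : 0.0) - nh[i] * nh[j];
    double Su[3][3], Sw[3][3], Sn[3][3], T1[3][3];
    skew(u, Su);
    skew(w, Sw);
    skew(nh, Sn);
    double Huu[3][3], Hww[3][3], Huw[3][3];
    // Huu = -(1/(2|n|)) Sw P Sw ; Hww = -(1/(2|n|)) Su P Su
    matmul3(Sw, P, T1);
    matmul3(T1, Sw, Huu);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) Huu[i][j] *= -0.5 / nn;
    matmul3(Su, P, T1);
    matmul3(T1, Su, Hww);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) Hww[i][j] *= -0.5 / nn;
    // Huw = (1/(2|n|)) Sw P Su - (1/2) skew(nh)
    matmul3(Sw, P, T1);
    matmul3(T1, Su, Huw);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        Huw[i][j] = 0.5 * Huw[i][j] / nn - 0.5 * Sn[i][j];

    // grad a in vertex coordinates (rank-1 term)
    double ga[3][3];  // per vertex
    double e[3];
    for (int d = 0; d < 3; ++d) e[d] = c[d] - b[d];
    ga[0][0] = (nrm[1] * e[2] - nrm[2] * e[1]) / (2 * nn);
    ga[0][1] = (nrm[2] * e[0] - nrm[0] * e[2]) / (2 * nn);
    ga[0][2] = (nrm[0] * e[1] - nrm[1] * e[0]) / (2 * nn);
    for (int d = 0; d < 3; ++d) e[d] = a[d] - c[d];
    ga[1][0] = (nrm[1] * e[2] - nrm[2] * e[1]) / (2 * nn);
    ga[1][1] = (nrm[2] * e[0] - nrm[0] * e[2]) / (2 * nn);
    ga[1][2] = (nrm[0] * e[1] - nrm[1] * e[0]) / (2 * nn);
    for (int d = 0; d < 3; ++d) e[d] = b[d] - a[d];
    ga[2][0] = (nrm[1] * e[2] - nrm[2] * e[1]) / (2 * nn);
    ga[2][1] = (nrm[2] * e[0] - nrm[0] * e[2]) / (2 * nn);
    ga[2][2] = (nrm[0] * e[1] - nrm[1] * e[0]) / (2 * nn);

    double ca1 = eps_a / (a0[k] * a0[k]);
    double ca2 = -eps_a * (1.0 - ak / a0[k]) / a0[k];
    for (int p = 0; p < 3; ++p)
      for (int q = 0; q < 3; ++q)
        for (int d1 = 0; d1 < 3; ++d1)
          for (int d2 = 0; d2 < 3; ++d2)
            H(3 * id[p] + d1, 3 * id[q] + d2) +=
                ca1 * ga[p][d1] * ga[q][d2];

    // map (u,w) Hessian to vertices: du = -dra + drb, dw = -dra + drc
    double cu[3] = {-1, 1, 0}, cw[3] = {-1, 0, 1};
    for (int p = 0; p < 3; ++p)
      for (int q = 0; q < 3; ++q)
        for (int d1 = 0; d1 < 3; ++d1)
          for (int d2 = 0; d2 < 3; ++d2) {
            double h = cu[p] * cu[q] * Huu[d1][d2] +
                       cu[p] * cw[q] * Huw[d1][d2] +
                       cw[p] * cu[q] * Huw[d2][d1] +
                       cw[p] * cw[q] * Hww[d1][d2];
            H(3 * id[p] + d1, 3 * id[q] + d2) += ca2 * h;
          }
  }
  return H;
}
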