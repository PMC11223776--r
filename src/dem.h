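#ifndef ADIPOINVADE_DEM_H
#define ADIPOINVADE_DEM_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

// Reduced units throughout: eps_c = sigma = m = 1.

struct SimState {
  // adipocytes: Na meshes sharing one face topology (Nv vertices, Nf faces)
  int Na = 0, Nv = 0, Nf = 0;
  std::vector<double> vx;   // 3 * Na * Nv vertex positions (x,y,z interleaved)
  std::vector<double> vv;   // vertex velocities
  std::vector<int>    faces; // 3 * Nf, 0-based vertex indices (outward oriented)
  std::vector<double> v0;   // Na preferred volumes
  std::vector<double> a0;   // Na * Nf preferred face areas (adipocyte-major)
  double sigv = 2.0;        // vertex diameter sigma_imu
  double eps_v = 1e3, eps_a = 10.0;

  // cancer cells
  int Nc = 0;
  std::vector<double> cx, cv, cdir; // 3*Nc each
  std::vector<double> cd;           // Nc diameters

  // box / walls; x in [xl, xr], periodic y,z with lengths Ly, Lz
  double xl = 0.0, xr = 1.0, vl = 0.0, Ly = 1.0, Lz = 1.0;

  // tethers between adipocyte centres of mass; image offsets are fixed at
  // build time so springs longer than half the box stay well defined
  std::vector<int> tpair;    // 2 * Ne (0-based adipocyte indices)
  std::vector<int> toff;     // 2 * Ne integer (oy, oz) image offsets
  std::vector<double> tl0;   // Ne rest lengths
  double Kecm = 0.0;
};

struct RunParams {
  double dt = 0.05;
  double gamma = 0.2;
  double alpha = 0.2, beta = 0.0;  // cancer-cancer attraction range/depth
  int model = 0;                   // 0 passive, 1 active
  double f0 = 0.0, T0 = 0.0, taup = 0.0;
  double P = 1.3e-3;               // imposed pressure on the left wall
  bool wall_mobile = false;
  bool periodic_x = false;         // fully periodic (no walls), for dilute studies
  bool pair_forces = true;         // false => ideal (interaction-free) cells
  bool walls_on = true;            // wall-particle repulsion
};

struct ForceOut {
  std::vector<double> fv; // on vertices
  std::vector<double> fc; // on cancer cells
  double U = 0.0;         // potential energy (pairs + walls + tethers + shape)
  double wfl = 0.0;       // x-force exerted by particles on the left wall
  double wfr = 0.0;       // ... right wall
};

// force engine; brute=true uses the all-pairs double loop (oracle path)
void compute_forces(const SimState &s, const RunParams &p, ForceOut &out,
                    bool brute);

// single-mesh deformable-particle quantities
double mesh_volume_c(const std::vector<double> &x, const std::vector<int> &f,
                     int Nf);
void face_areas_c(const std::vector<double> &x, const std::vector<int> &f,
                  int Nf, std::vector<double> &areas);
double shape_energy_c(const std::vector<double> &x, const std::vector<int> &f,
                      int Nf, double v0, const double *a0, double eps_v,
                      double eps_a);
void shape_forces_c(const std::vector<double> &x, const std::vector<int> &f,
                    int Nf, double v0, const double *a0, double eps_v,
                    double eps_a, std::vector<double> &force);

SimState state_from_list(Rcpp::List st);
Rcpp::List state_to_list(const SimState &s);
RunParams params_from_list(Rcpp::List pr);

inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

#endif
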