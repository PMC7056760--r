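// Monte Carlo photon transport core.
//
// Phase 1 (mc_transport): Woodcock (delta) tracking of photon histories
// through a voxelized material map with analog Klein-Nishina scattering and
// photoelectric survival biasing; emits a list of interaction events.
//
// Phase 2 (mc_score_angle): forced-detection scoring of emission and
// interaction events toward one detector angle, splatting attenuated,
// direction-weighted contributions into per-(distance-knot, energy-bin,
// window) accumulator images that are convolved with the PSF kernels in R.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double ME_KEV = 510.999;
static const double FOUR_PI = 4.0 * M_PI;

// ---- small helpers ---------------------------------------------------------

// log-log interpolation of mu tables; clamps outside the grid.
static double loglog_interp(const std::vector<double>& logx,
                            const std::vector<double>& logy, double x) {
  double lx = std::log(x);
  int n = (int)logx.size();
  if (lx <= logx[0]) return std::exp(logy[0]);
  if (lx >= logx[n - 1]) return std::exp(logy[n - 1]);
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (logx[mid] <= lx) lo = mid; else hi = mid;
  }
  double t = (lx - logx[lo]) / (logx[hi] - logx[lo]);
  return std::exp(logy[lo] + t * (logy[hi] - logy[lo]));
}

static double kn_sigma_total(double E) {
  double k = E / ME_KEV;
  const double r_e2 = 7.940787e-26;
  double t1 = (1 + k) / (k * k * k) *
              (2 * k * (1 + k) / (1 + 2 * k) - std::log(1 + 2 * k));
  double t2 = std::log(1 + 2 * k) / (2 * k);
  double t3 = (1 + 3 * k) / ((1 + 2 * k) * (1 + 2 * k));
  return 2.0 * M_PI * r_e2 * (t1 + t2 - t3);
}

static double kn_diff(double E, double cost) {
  double k = E / ME_KEV;
  double eps = 1.0 / (1.0 + k * (1.0 - cost));
  const double r_e2 = 7.940787e-26;
  double sin2 = 1.0 - cost * cost;
  return r_e2 / 2.0 * eps * eps * (eps + 1.0 / eps - sin2);
}

// Kahn-style composition-rejection sampling of the Klein-Nishina distribution.
// Returns eps = E'/E and fills cost with the scattering cosine.
static double kn_sample_eps(double E, double& cost) {
  double k = E / ME_KEV;
  double eps0 = 1.0 / (1.0 + 2.0 * k);
  double a1 = -std::log(eps0);
  double a2 = 0.5 * (1.0 - eps0 * eps0);
  double eps, t, g;
  do {
    if (unif_rand() * (a1 + a2) < a1) {
      eps = std::exp(-a1 * unif_rand());
    } else {
      double e2 = eps0 * eps0 + (1.0 - eps0 * eps0) * unif_rand();
      eps = std::sqrt(e2);
    }
    t = (1.0 - eps) / (k * eps);
    double sin2 = t * (2.0 - t);
    g = 1.0 - eps * sin2 / (1.0 + eps * eps);
  } while (unif_rand() > g);
  cost = 1.0 - t;
  return eps;
}

// [[Rcpp::export]]
List mc_sample_compton(double energy, int n) {
  NumericVector e_out(n), ang(n);
  for (int i = 0; i < n; ++i) {
    double cost;
    double eps = kn_sample_eps(energy, cost);
    e_out[i] = energy * eps;
    ang[i] = std::acos(std::max(-1.0, std::min(1.0, cost)));
  }
  return List::create(_["energy"] = e_out, _["angle"] = ang);
}

// Rotate direction (ux,uy,uz) by polar angle theta (cost given) and uniform
// azimuth; standard scattering frame rotation.
static void rotate_direction(double& ux, double& uy, double& uz, double cost) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double phi = 2.0 * M_PI * unif_rand();
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double nx, ny, nz;
  if (std::fabs(uz) < 0.99999) {
    double denom = std::sqrt(ux * ux + uy * uy);
    nx = sint * (ux * uz * cphi - uy * sphi) / denom + ux * cost;
    ny = sint * (uy * uz * cphi + ux * sphi) / denom + uy * cost;
    nz = -sint * cphi * denom + uz * cost;
  } else {
    nx = sint * cphi;
    ny = sint * sphi;
    nz = cost * (uz > 0 ? 1.0 : -1.0);
  }
  double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx / norm; uy = ny / norm; uz = nz / norm;
}

struct MuTables {
  std::vector<double> loge;
  std::vector<std::vector<double> > logmu_tot;  // per material
  std::vector<std::vector<double> > logmu_com;
  int nmat;
  MuTables(NumericVector e_grid, NumericMatrix mu_tot, NumericMatrix mu_com) {
    int ne = e_grid.size();
    nmat = mu_tot.nrow();
    loge.resize(ne);
    for (int i = 0; i < ne; ++i) loge[i] = std::log(e_grid[i]);
    logmu_tot.resize(nmat); logmu_com.resize(nmat);
    for (int m = 0; m < nmat; ++m) {
      logmu_tot[m].resize(ne); logmu_com[m].resize(ne);
      for (int i = 0; i < ne; ++i) {
        logmu_tot[m][i] = std::log(std::max(mu_tot(m, i), 1e-12));
        logmu_com[m][i] = std::log(std::max(mu_com(m, i), 1e-12));
      }
    }
  }
  double mu_tot(int m, double E) const {
    return loglog_interp(loge, logmu_tot[m], E);
  }
  double mu_com(int m, double E) const {
    return loglog_interp(loge, logmu_com[m], E);
  }
  double mu_max(double E) const {
    double mx = 0.0;
    for (int m = 0; m < nmat; ++m) mx = std::max(mx, mu_tot(m, E));
    return mx;
  }
};

// Voxel lookup. Positions are in mm relative to the volume center; voxel
// centers follow the 0-based, voxel-center convention.
struct Grid {
  int nx, ny, nz;
  double vx, vy, vz;    // voxel size, mm
  double ox, oy, oz;    // position of voxel (0,0,0) center, mm
  const int* mat;
  Grid(IntegerVector materials, IntegerVector dim, NumericVector voxel_mm)
      : nx(dim[0]), ny(dim[1]), nz(dim[2]),
        vx(voxel_mm[0]), vy(voxel_mm[1]), vz(voxel_mm[2]),
        mat(INTEGER(materials)) {
    ox = -0.5 * (nx - 1) * vx;
    oy = -0.5 * (ny - 1) * vy;
    oz = -0.5 * (nz - 1) * vz;
  }
  // returns material label (0-based) or -1 outside
  int material_at(double x, double y, double z) const {
    int ix = (int)std::floor((x - ox) / vx + 0.5);
    int iy = (int)std::floor((y - oy) / vy + 0.5);
    int iz = (int)std::floor((z - oz) / vz + 0.5);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
      return -1;
    return mat[ix + (size_t)nx * (iy + (size_t)ny * iz)];
  }
};

// [[Rcpp::export]]
List mc_transport(NumericMatrix pos0, NumericVector e0,
                  IntegerVector materials, IntegerVector dim,
                  NumericVector voxel_mm, NumericVector e_grid,
                  NumericMatrix mu_tot, NumericMatrix mu_com,
                  double e_cutoff, int max_scatters, double w_min) {
  RNGScope scope;
  MuTables mu(e_grid, mu_tot, mu_com);
  Grid grid(materials, dim, voxel_mm);
  int n = pos0.nrow();
  std::vector<double> ev_x, ev_y, ev_z, ev_e, ev_w, ev_ux, ev_uy, ev_uz;

  for (int i = 0; i < n; ++i) {
    double x = pos0(i, 0), y = pos0(i, 1), z = pos0(i, 2);
    double E = e0[i], w = 1.0;
    // isotropic initial direction
    double cost = 2.0 * unif_rand() - 1.0;
    double sint = std::sqrt(1.0 - cost * cost);
    double phi = 2.0 * M_PI * unif_rand();
    double ux = sint * std::cos(phi), uy = sint * std::sin(phi), uz = cost;

    for (int s = 0; s < max_scatters; ++s) {
      double mumax = mu.mu_max(E);          // 1/cm
      bool interacted = false;
      // Woodcock tracking until a real interaction or escape
      for (int it = 0; it < 10000; ++it) {
        double l_mm = -std::log(unif_rand()) / mumax * 10.0;
        x += ux * l_mm; y += uy * l_mm; z += uz * l_mm;
        int m = grid.material_at(x, y, z);
        if (m < 0) break;                    // escaped the volume
        double mut = mu.mu_tot(m, E);
        if (unif_rand() * mumax <= mut) {    // real interaction
          double pc = mu.mu_com(m, E) / mut;
          double we = w * pc;
          if (we > w_min) {
            ev_x.push_back(x); ev_y.push_back(y); ev_z.push_back(z);
            ev_e.push_back(E); ev_w.push_back(we);
            ev_ux.push_back(ux); ev_uy.push_back(uy); ev_uz.push_back(uz);
          }
          w = we;
          interacted = true;
          break;
        }
      }
      if (!interacted || w <= w_min) break;
      double c;
      double eps = kn_sample_eps(E, c);
      E *= eps;
      if (E < e_cutoff) break;
      rotate_direction(ux, uy, uz, c);
    }
  }
  int ne = (int)ev_x.size();
  NumericMatrix pos(ne, 3), dir(ne, 3);
  NumericVector ee(ne), ww(ne);
  for (int i = 0; i < ne; ++i) {
    pos(i, 0) = ev_x[i]; pos(i, 1) = ev_y[i]; pos(i, 2) = ev_z[i];
    dir(i, 0) = ev_ux[i]; dir(i, 1) = ev_uy[i]; dir(i, 2) = ev_uz[i];
    ee[i] = ev_e[i]; ww[i] = ev_w[i];
  }
  return List::create(_["pos"] = pos, _["dir"] = dir,
                      _["energy"] = ee, _["weight"] = ww);
}

// [[Rcpp::export]]
NumericVector mc_score_angle(NumericMatrix pos, NumericVector energy,
                             NumericVector weight, NumericMatrix dir,
                             IntegerVector type, double angle,
                             IntegerVector materials, IntegerVector dim,
                             NumericVector voxel_mm, NumericVector e_grid,
                             NumericMatrix mu_tot, NumericMatrix mu_com,
                             NumericMatrix windows, double fwhm_ref,
                             double e_ref, double res_exp,
                             NumericVector bin_edges,
                             NumericVector dist_knots_mm, double radius_mm,
                             int nu, int nv, double pitch_u, double pitch_v,
                             double step_mm, bool skip_unscattered_direct) {
  MuTables mu(e_grid, mu_tot, mu_com);
  Grid grid(materials, dim, voxel_mm);
  int n = pos.nrow();
  int nw = windows.nrow();
  int nknot = dist_knots_mm.size();
  int nbin = bin_edges.size() - 1;   // indirect PSF energy bins
  int nslot = nbin + 1;              // + direct slot
  NumericVector acc((R_xlen_t)nu * nv * nknot * nslot * nw);
  acc.attr("dim") = IntegerVector::create(nu, nv, nknot, nslot, nw);
  double* pacc = REAL(acc);
  size_t s_uv = (size_t)nu * nv;
  size_t s_k = s_uv * nknot;
  size_t s_b = s_k * nslot;

  double ca = std::cos(angle), sa = std::sin(angle);
  // detector direction (photon travel direction toward the camera)
  double dxn = ca, dyn = sa, dzn = 0.0;
  const double inv_sqrt2 = 0.7071067811865475;
  double step_cm = step_mm / 10.0;
  double half_u = 0.5 * (nu - 1), half_v = 0.5 * (nv - 1);

  for (int i = 0; i < n; ++i) {
    double w0 = weight[i];
    if (w0 <= 0) continue;
    double E = energy[i];
    double edet, angw;
    if (type[i] == 0) {
      edet = E;
      angw = 1.0;  // 4*pi * isotropic pdf
    } else {
      double cost = dir(i, 0) * dxn + dir(i, 1) * dyn + dir(i, 2) * dzn;
      double k = E / ME_KEV;
      edet = E / (1.0 + k * (1.0 - cost));
      angw = FOUR_PI * kn_diff(E, cost) / kn_sigma_total(E);
    }
    if (edet < 40.0) continue;
    // detector coordinates
    double x = pos(i, 0), y = pos(i, 1), z = pos(i, 2);
    double u = -x * sa + y * ca;
    double v = z;
    int ub = (int)std::floor(u / pitch_u + half_u + 0.5);
    int vb = (int)std::floor(v / pitch_v + half_v + 0.5);
    if (ub < 0 || ub >= nu || vb < 0 || vb >= nv) continue;
    double distmm = radius_mm - (x * ca + y * sa);
    if (distmm < 0) continue;

    // attenuation along the exit ray at the detected energy
    std::vector<double> muv(mu.nmat);
    for (int m = 0; m < mu.nmat; ++m) muv[m] = mu.mu_tot(m, edet);
    double att = 0.0;
    double px = x, py = y, pz = z;
    for (int it = 0; it < 100000; ++it) {
      px += dxn * step_mm; py += dyn * step_mm; pz += dzn * step_mm;
      int m = grid.material_at(px, py, pz);
      if (m < 0) break;
      att += muv[m] * step_cm;
    }
    double contrib = w0 * angw * std::exp(-att);
    if (contrib < 1e-14) continue;

    // distance knot split (linear interpolation weights)
    int k0 = 0;
    while (k0 < nknot - 2 && dist_knots_mm[k0 + 1] < distmm) ++k0;
    double d0 = dist_knots_mm[k0], d1 = dist_knots_mm[k0 + 1];
    double t = (distmm - d0) / (d1 - d0);
    if (t < 0) t = 0; if (t > 1) t = 1;

    size_t base = (size_t)ub + (size_t)nu * vb;

    // indirect slot by PSF source-energy bin (half-open [lo, hi))
    int eb = -1;
    if (edet >= bin_edges[0] && edet < bin_edges[nbin]) {
      eb = 0;
      while (eb < nbin - 1 && bin_edges[eb + 1] <= edet) ++eb;
    } else if (edet == bin_edges[nbin]) {
      eb = nbin - 1;
    }
    for (int iw = 0; iw < nw; ++iw) {
      // direct detection probability: Gaussian mass inside the window
      double fwhm = fwhm_ref * std::pow(e_ref / edet, res_exp) * edet;
      double sig = fwhm / 2.3548200450309493;
      double detp = 0.5 * (std::erf((windows(iw, 1) - edet) / sig * inv_sqrt2) -
                           std::erf((windows(iw, 0) - edet) / sig * inv_sqrt2));
      if (detp > 1e-9 && !(skip_unscattered_direct && type[i] == 0)) {
        double c = contrib * detp;
        pacc[base + s_k * nbin + s_b * iw + s_uv * k0] += c * (1.0 - t);
        pacc[base + s_k * nbin + s_b * iw + s_uv * (k0 + 1)] += c * t;
      }
      if (eb >= 0) {
        pacc[base + s_k * eb + s_b * iw + s_uv * k0] += contrib * (1.0 - t);
        pacc[base + s_k * eb + s_b * iw + s_uv * (k0 + 1)] += contrib * t;
      }
    }
  }
  return acc;
}
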