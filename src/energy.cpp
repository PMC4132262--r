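#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// CHARMM-style energy switching between r_on and r_off
static inline double sw(double r2, double ron2, double roff2) {
  if (r2 <= ron2) return 1.0;
  if (r2 >= roff2) return 0.0;
  double a = roff2 - r2;
  double d = roff2 - ron2;
  return a * a * (roff2 + 2.0 * r2 - 3.0 * ron2) / (d * d * d);
}

// non-bonded pair exclusions: all pairs within one residue, and
// backbone/CB pairs of sequence-adjacent residues in the same chain
static inline bool excluded(int ri, int rj, int ci, int cj, int bi, int bj) {
  if (ri == rj) return true;
  if (ci == cj && std::abs(ri - rj) == 1 && bi && bj) return true;
  return false;
}

// Lennard-Jones 6-12 + Coulomb with distance-dependent dielectric eps(r)=kd*r,
// both switched off between r_on and r_off.  rmin is the per-atom rmin/2.
// [[Rcpp::export(name = ".nonbonded_cpp")]]
List nonbonded_cpp(NumericMatrix xyz, NumericVector eps, NumericVector rmin,
                   NumericVector q, IntegerVector res, IntegerVector chain,
                   IntegerVector bbcb, double r_on, double r_off, double kdiel) {
  const int n = xyz.nrow();
  const double ron2 = r_on * r_on, roff2 = r_off * r_off;
  const double kq = 332.0637 / kdiel;
  double evdw = 0.0, eelec = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - xyz(j, 0), dy = yi - xyz(j, 1), dz = zi - xyz(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= roff2) continue;
      if (excluded(res[i], res[j], chain[i], chain[j], bbcb[i], bbcb[j]))
        continue;
      double s = sw(r2, ron2, roff2);
      double rm = rmin[i] + rmin[j];
      double sr2 = rm * rm / r2;
      double sr6 = sr2 * sr2 * sr2;
      evdw += s * std::sqrt(eps[i] * eps[j]) * (sr6 * sr6 - 2.0 * sr6);
      // eps(r) = kdiel * r  =>  E = 332 q q / (kdiel r^2)
      eelec += s * kq * q[i] * q[j] / r2;
    }
  }
  return List::create(_["vdw"] = evdw, _["elec"] = eelec);
}

// Still-style pairwise Generalized-Born polar solvation.
// Effective Born radii from intrinsic radii rho with an optional coarse
// pairwise volume descreening term; off-diagonal pair terms share the
// non-bonded switching cutoff so the energy stays strictly local.
// [[Rcpp::export(name = ".gb_cpp")]]
double gb_cpp(NumericMatrix xyz, NumericVector q, NumericVector rho,
              double r_on, double r_off, bool descreen,
              double descreen_scale, double alpha_max, double eps_w) {
  const int n = xyz.nrow();
  const double ron2 = r_on * r_on, roff2 = r_off * r_off;
  std::vector<double> alpha(n);
  if (descreen) {
    for (int i = 0; i < n; ++i) {
      double inv = 1.0 / rho[i];
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
               dz = xyz(i, 2) - xyz(j, 2);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= roff2) continue;
        double rj3 = rho[j] * rho[j] * rho[j];
        inv -= descreen_scale * rj3 / (3.0 * r2 * r2);
      }
      if (inv < 1.0 / alpha_max) inv = 1.0 / alpha_max;
      alpha[i] = 1.0 / inv;
    }
  } else {
    for (int i = 0; i < n; ++i) alpha[i] = rho[i];
  }
  const double tau = 332.0637 * (1.0 - 1.0 / eps_w);
  double e = 0.0;
  for (int i = 0; i < n; ++i) e += 0.5 * q[i] * q[i] / alpha[i];
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
             dz = xyz(i, 2) - xyz(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= roff2) continue;
      double aa = alpha[i] * alpha[j];
      double f = std::sqrt(r2 + aa * std::exp(-r2 / (4.0 * aa)));
      e += sw(r2, ron2, roff2) * q[i] * q[j] / f;
    }
  }
  return -tau * e;
}

// Shrake-Rupley solvent-accessible surface area with a deterministic
// golden-spiral point set.
// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radius,
                       double probe, int n_points) {
  const int n = xyz.nrow();
  NumericVector out(n);
  // fixed unit sphere points (golden spiral)
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = z;
  }
  std::vector<double> ri(n);
  for (int i = 0; i < n; ++i) ri[i] = radius[i] + probe;
  for (int i = 0; i < n; ++i) {
    // neighbor list, nearest first so occluded points terminate early
    std::vector<std::pair<double, int> > nbd;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
             dz = xyz(i, 2) - xyz(j, 2);
      double lim = ri[i] + ri[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < lim * lim) nbd.push_back(std::make_pair(d2, j));
    }
    std::sort(nbd.begin(), nbd.end());
    std::vector<int> nb(nbd.size());
    for (size_t m = 0; m < nbd.size(); ++m) nb[m] = nbd[m].second;
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double x = xyz(i, 0) + ri[i] * px[k];
      double y = xyz(i, 1) + ri[i] * py[k];
      double z = xyz(i, 2) + ri[i] * pz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = x - xyz(j, 0), dy = y - xyz(j, 1), dz = z - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < ri[j] * ri[j]) {
          free_pt = false;
          break;
        }
      }
      if (free_pt) ++acc;
    }
    out[i] = 4.0 * M_PI * ri[i] * ri[i] * acc / n_points;
  }
  return out;
}
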