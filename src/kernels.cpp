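#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Inter-molecular heavy-atom pair list. A and B are n x 3 / m x 3 coordinate
// matrices (Angstrom); returns a two-column matrix of 1-based (i, j) indices
// of pairs with d(A_i, B_j) <= cutoff.
// [[Rcpp::export]]
IntegerMatrix cpp_close_pairs(NumericMatrix A, NumericMatrix B, double cutoff) {
  const int n = A.nrow(), m = B.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= c2) { ii.push_back(i + 1); jj.push_back(j + 1); }
    }
  }
  IntegerMatrix out((int) ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) { out(k, 0) = ii[k]; out(k, 1) = jj[k]; }
  return out;
}

// [[Rcpp::export]]
int cpp_count_close_pairs(NumericMatrix A, NumericMatrix B, double cutoff) {
  const int n = A.nrow(), m = B.nrow();
  const double c2 = cutoff * cutoff;
  int count = 0;
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      if (dx * dx + dy * dy + dz * dz <= c2) ++count;
    }
  }
  return count;
}

// Inter-molecular 12-6 Lennard-Jones sum with geometric-mean combination of
// per-atom well depths (eps, kcal/mol) and minimum-energy distances (xm, A):
//   E_ij = eps_ij * ((xm_ij / r)^12 - 2 * (xm_ij / r)^6),  r <= cutoff.
// A cutoff <= 0 disables the distance cutoff.
// [[Rcpp::export]]
double cpp_lj_energy(NumericMatrix A, NumericMatrix B,
                     NumericVector epsA, NumericVector epsB,
                     NumericVector xmA, NumericVector xmB,
                     double cutoff) {
  const int n = A.nrow(), m = B.nrow();
  const bool use_cut = cutoff > 0;
  const double c2 = cutoff * cutoff;
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (use_cut && d2 > c2) continue;
      const double eps = std::sqrt(epsA[i] * epsB[j]);
      const double xm = std::sqrt(xmA[i] * xmB[j]);
      const double s2 = xm * xm / d2;
      const double s6 = s2 * s2 * s2;
      e += eps * (s6 * s6 - 2.0 * s6);
    }
  }
  return e;
}

// Shrake-Rupley solvent-accessible surface area. X is n x 3 coordinates,
// radius the per-atom van der Waals radii. Test points are placed on a
// deterministic golden-spiral lattice (n_points per atom) on each solvent
// sphere of radius r_i + probe; a point is accessible if outside every other
// atom's solvent sphere. Returns the per-atom accessible area (A^2).
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix X, NumericVector radius,
                       double probe, int n_points) {
  const int n = X.nrow();
  NumericVector area(n);
  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    const double z = 1.0 - (2.0 * k + 1.0) / n_points;
    const double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    const double th = golden * k;
    px[k] = r * std::cos(th); py[k] = r * std::sin(th); pz[k] = z;
  }
  std::vector<double> sr(n);  // solvent-expanded radii
  for (int i = 0; i < n; ++i) sr[i] = radius[i] + probe;

  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2), ri = sr[i];
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xi - X(j, 0), dy = yi - X(j, 1), dz = zi - X(j, 2);
      const double lim = ri + sr[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nbr.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      const double qx = xi + ri * px[k], qy = yi + ri * py[k], qz = zi + ri * pz[k];
      bool buried = false;
      for (size_t t = 0; t < nbr.size(); ++t) {
        const int j = nbr[t];
        const double dx = qx - X(j, 0), dy = qy - X(j, 1), dz = qz - X(j, 2);
        if (dx * dx + dy * dy + dz * dz < sr[j] * sr[j]) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * ((double) acc / n_points);
  }
  return area;
}
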