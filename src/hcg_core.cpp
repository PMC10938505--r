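#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>

using namespace Rcpp;

// Count inter-set heavy-atom pairs with distance strictly below cutoff.
// Cell-list neighbor search; equivalent to the all-pairs O(N*M) count.
// [[Rcpp::export(name = ".clash_count_cpp")]]
int clash_count_cpp(NumericMatrix a, NumericMatrix b, double cutoff) {
  const int na = a.nrow(), nb = b.nrow();
  if (na == 0 || nb == 0) return 0;
  const double c2 = cutoff * cutoff;
  // hash grid over set b with cell edge = cutoff
  const double inv = 1.0 / cutoff;
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(nb * 2);
  auto key = [](long long ix, long long iy, long long iz) {
    // coordinates in Angstrom; offsets keep indices positive for typical systems
    return ((ix + 100000LL) * 4000003LL + (iy + 100000LL)) * 4000037LL +
           (iz + 100000LL);
  };
  for (int j = 0; j < nb; ++j) {
    long long ix = (long long)std::floor(b(j, 0) * inv);
    long long iy = (long long)std::floor(b(j, 1) * inv);
    long long iz = (long long)std::floor(b(j, 2) * inv);
    grid[key(ix, iy, iz)].push_back(j);
  }
  int count = 0;
  for (int i = 0; i < na; ++i) {
    const double x = a(i, 0), y = a(i, 1), z = a(i, 2);
    long long ix = (long long)std::floor(x * inv);
    long long iy = (long long)std::floor(y * inv);
    long long iz = (long long)std::floor(z * inv);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            const double ddx = x - b(j, 0), ddy = y - b(j, 1),
                         ddz = z - b(j, 2);
            const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 < c2) ++count;
          }
        }
  }
  return count;
}

// Debye formula: I(q_k) = sum_a sum_b f_a(q_k) f_b(q_k) sinc(q_k r_ab).
// F is n_atoms x n_q (per-atom form factor evaluated on the q grid).
// q and coords share a length unit (q in 1/unit). Exact double loop.
// [[Rcpp::export(name = ".debye_sum_cpp")]]
NumericVector debye_sum_cpp(NumericMatrix coords, NumericMatrix F,
                            NumericVector q) {
  const int n = coords.nrow(), nq = q.size();
  NumericVector I(nq);
  // self terms
  for (int k = 0; k < nq; ++k) {
    double s = 0.0;
    for (int a = 0; a < n; ++a) s += F(a, k) * F(a, k);
    I[k] = s;
  }
  // pair terms
  for (int a = 0; a < n; ++a) {
    const double xa = coords(a, 0), ya = coords(a, 1), za = coords(a, 2);
    for (int b = a + 1; b < n; ++b) {
      const double dx = xa - coords(b, 0), dy = ya - coords(b, 1),
                   dz = za - coords(b, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int k = 0; k < nq; ++k) {
        const double x = q[k] * r;
        const double sinc = (x < 1e-12) ? 1.0 : std::sin(x) / x;
        I[k] += 2.0 * F(a, k) * F(b, k) * sinc;
      }
    }
  }
  return I;
}

// Minimum inter-set distance (diagnostics for merge rejections).
// [[Rcpp::export(name = ".min_pair_dist_cpp")]]
double min_pair_dist_cpp(NumericMatrix a, NumericMatrix b) {
  double best = R_PosInf;
  for (int i = 0; i < a.nrow(); ++i)
    for (int j = 0; j < b.nrow(); ++j) {
      const double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1),
                   dz = a(i, 2) - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}

// Whole-chain clash scan for post-hoc ensemble validation: counts heavy-atom
// pairs in *different* residues closer than cutoff, exempting the covalent
// O3'(i)-P(i+1) linkage and the adjacent phosphate-group contacts
// O3'(i)-{OP1,OP2,O5'}(i+1) that the growth step excludes at junctions.
// [[Rcpp::export(name = ".chain_clash_count_cpp")]]
int chain_clash_count_cpp(NumericMatrix x, IntegerVector resi,
                          LogicalVector is_o3, LogicalVector is_pgrp,
                          double cutoff) {
  const int n = x.nrow();
  const double c2 = cutoff * cutoff;
  const double *xp = REAL(x);
  const double *yp = xp + n, *zp = xp + 2 * n;
  const int *rp = INTEGER(resi);
  const int *o3 = LOGICAL(is_o3), *pg = LOGICAL(is_pgrp);
  int count = 0;
  for (int i = 0; i < n; ++i) {
    const double xi = xp[i], yi = yp[i], zi = zp[i];
    const int ri = rp[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - xp[j], dy = yi - yp[j], dz = zi - zp[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= c2) continue;
      const int rj = rp[j];
      if (ri == rj) continue;
      const bool adj_ij = (rj == ri + 1) && o3[i] && pg[j];
      const bool adj_ji = (ri == rj + 1) && o3[j] && pg[i];
      if (adj_ij || adj_ji) continue;
      ++count;
    }
  }
  return count;
}
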