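#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter, in place. a[0] must be 1.
static void filt_inplace(const std::vector<double>& b,
                         const std::vector<double>& a,
                         std::vector<double>& x) {
  const int nb = (int)b.size(), na = (int)a.size();
  const int nz = std::max(na, nb) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  const size_t n = x.size();
  double* xs = x.data();
  if (nz == 4) {  // the common order-4 case: keep state in registers
    double z0 = 0, z1 = 0, z2 = 0, z3 = 0;
    const double b0 = bb[0], b1 = bb[1], b2 = bb[2], b3 = bb[3], b4 = bb[4];
    const double a1 = aa[1], a2 = aa[2], a3 = aa[3], a4 = aa[4];
    for (size_t t = 0; t < n; ++t) {
      const double xn = xs[t];
      const double yn = b0 * xn + z0;
      z0 = b1 * xn - a1 * yn + z1;
      z1 = b2 * xn - a2 * yn + z2;
      z2 = b3 * xn - a3 * yn + z3;
      z3 = b4 * xn - a4 * yn;
      xs[t] = yn;
    }
    return;
  }
  std::vector<double> z(nz, 0.0);
  for (size_t t = 0; t < n; ++t) {
    const double xn = xs[t];
    const double yn = bb[0] * xn + z[0];
    for (int i = 1; i < nz; ++i) z[i - 1] = bb[i] * xn - aa[i] * yn + z[i];
    z[nz - 1] = bb[nz] * xn - aa[nz] * yn;
    xs[t] = yn;
  }
}

// Zero-phase (forward-backward) filtering with odd-reflection padding at the
// ends; pad is trimmed from the output so length is preserved.
// [[Rcpp::export]]
NumericVector filtfilt_cpp(NumericVector x, NumericVector b, NumericVector a,
                           int pad) {
  const int n = x.size();
  if (n < 2) stop("trace too short to filter");
  if (pad >= n) pad = n - 1;
  if (pad < 0) pad = 0;
  std::vector<double> xp(n + 2 * pad);
  for (int i = 0; i < pad; ++i) xp[i] = 2.0 * x[0] - x[pad - i];
  for (int i = 0; i < n; ++i) xp[pad + i] = x[i];
  for (int i = 0; i < pad; ++i) xp[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  filt_inplace(bb, aa, xp);
  std::reverse(xp.begin(), xp.end());
  filt_inplace(bb, aa, xp);
  std::reverse(xp.begin(), xp.end());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = xp[pad + i];
  return out;
}

struct UnionFind {
  std::vector<int> parent;
  UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  }
  void unite(int i, int j) {
    int ri = find(i), rj = find(j);
    if (ri != rj) parent[ri] = rj;
  }
};

// Superparamagnetic clustering scan (Potts model + Swendsen-Wang dynamics).
// Points are mapped to q-state Potts spins on a symmetrized k-nearest-
// neighbour graph with distance-decaying couplings
//   J_ij = (1/Khat) exp(-d_ij^2 / (2 a^2)),
// a = mean neighbour distance, Khat = mean degree. At each temperature the
// spin-spin correlation G_ij is estimated over `meas` sweeps (after `burn`
// burn-in sweeps); neighbour pairs with G_ij > 0.5 are linked and connected
// components of the linked graph are the clusters at that temperature.
// Returns an n x n_temps matrix of 1-based component ids. Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix spc_scan_cpp(NumericMatrix feats, int k, int q,
                           NumericVector temps, int burn, int meas) {
  const int n = feats.nrow(), d = feats.ncol(), nt = temps.size();
  if (n < 2) stop("need at least 2 points");
  if (k < 1) stop("k_neighbors must be >= 1");
  if (k > n - 1) k = n - 1;

  // pairwise squared distances
  std::vector<double> d2((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double dv = feats(i, c) - feats(j, c);
        s += dv * dv;
      }
      d2[(size_t)i * n + j] = s;
      d2[(size_t)j * n + i] = s;
    }
  }

  // symmetrized kNN edge set
  std::vector<std::pair<int, int> > edges;
  {
    std::vector<std::pair<double, int> > nb(n - 1);
    std::vector<char> adj((size_t)n * n, 0);
    for (int i = 0; i < n; ++i) {
      int m = 0;
      for (int j = 0; j < n; ++j)
        if (j != i) nb[m++] = std::make_pair(d2[(size_t)i * n + j], j);
      std::partial_sort(nb.begin(), nb.begin() + k, nb.end());
      for (int t = 0; t < k; ++t) {
        const int j = nb[t].second;
        const int u = std::min(i, j), v = std::max(i, j);
        if (!adj[(size_t)u * n + v]) {
          adj[(size_t)u * n + v] = 1;
          edges.push_back(std::make_pair(u, v));
        }
      }
    }
  }
  const int ne = (int)edges.size();

  double a_mean = 0.0;
  for (int e = 0; e < ne; ++e)
    a_mean += std::sqrt(d2[(size_t)edges[e].first * n + edges[e].second]);
  a_mean /= ne;
  if (a_mean <= 0.0) a_mean = 1.0;  // all points identical
  const double khat = 2.0 * ne / n;

  std::vector<double> J(ne);
  for (int e = 0; e < ne; ++e) {
    const double dd2 = d2[(size_t)edges[e].first * n + edges[e].second];
    J[e] = std::exp(-dd2 / (2.0 * a_mean * a_mean)) / khat;
  }

  IntegerMatrix labels(n, nt);
  std::vector<int> spin(n), same(ne), newspin(n), comp(n);

  for (int ti = 0; ti < nt; ++ti) {
    const double T = temps[ti];
    std::vector<double> pe(ne);
    for (int e = 0; e < ne; ++e)
      pe[e] = (T <= 0.0) ? 1.0 : 1.0 - std::exp(-J[e] / T);
    for (int i = 0; i < n; ++i) spin[i] = (int)(unif_rand() * q);
    std::fill(same.begin(), same.end(), 0);

    for (int s = 0; s < burn + meas; ++s) {
      UnionFind uf(n);
      for (int e = 0; e < ne; ++e) {
        if (spin[edges[e].first] == spin[edges[e].second] &&
            unif_rand() < pe[e])
          uf.unite(edges[e].first, edges[e].second);
      }
      std::fill(newspin.begin(), newspin.end(), -1);
      for (int i = 0; i < n; ++i) {
        const int r = uf.find(i);
        if (newspin[r] < 0) newspin[r] = (int)(unif_rand() * q);
        spin[i] = newspin[r];
      }
      if (s >= burn) {
        for (int e = 0; e < ne; ++e)
          if (spin[edges[e].first] == spin[edges[e].second]) same[e]++;
      }
    }

    UnionFind uf2(n);
    for (int e = 0; e < ne; ++e)
      if ((double)same[e] / meas > 0.5)
        uf2.unite(edges[e].first, edges[e].second);
    std::fill(comp.begin(), comp.end(), 0);
    int next_id = 0;
    for (int i = 0; i < n; ++i) {
      const int r = uf2.find(i);
      if (comp[r] == 0) comp[r] = ++next_id;
      labels(i, ti) = comp[r];
    }
  }
  return labels;
}
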