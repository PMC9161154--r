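#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// n*log2(n) lookup table builder (L[0] = 0)
static std::vector<double> nlog2n_table(int n) {
  std::vector<double> L(n + 1, 0.0);
  for (int k = 1; k <= n; ++k) L[k] = k * std::log2((double)k);
  return L;
}

// Information gain (bits) of each discretized gene with a binary label.
// disc: samples x genes, values in 0..c-1; y: 0/1.
// [[Rcpp::export]]
NumericVector cpp_ig1d(IntegerMatrix disc, IntegerVector y, int c) {
  const int n = disc.nrow(), p = disc.ncol();
  if (y.size() != n) stop("label length mismatch");
  std::vector<double> L = nlog2n_table(n);
  int n1 = 0;
  for (int i = 0; i < n; ++i) n1 += y[i];
  const double hy = (L[n] - L[n1] - L[n - n1]) / n;
  NumericVector out(p);
  std::vector<int> cnt(2 * c);
  for (int g = 0; g < p; ++g) {
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) cnt[2 * disc(i, g) + y[i]]++;
    // n*H(Y|X) = sum_x L[n_x] - sum_xy L[n_xy]
    double s = 0.0;
    for (int b = 0; b < c; ++b) {
      const int nx = cnt[2 * b] + cnt[2 * b + 1];
      s += L[nx] - L[cnt[2 * b]] - L[cnt[2 * b + 1]];
    }
    double ig = hy - s / n;
    out[g] = ig > 0 ? ig : 0.0;
  }
  return out;
}

// Mutual information (bits) between gene columns a and b of a discretized
// matrix, for each index pair. Used for MRMR redundancy and test oracles.
// [[Rcpp::export]]
NumericVector cpp_pair_ig(IntegerMatrix disc, int c,
                          IntegerVector idx_a, IntegerVector idx_b) {
  const int n = disc.nrow();
  const int m = idx_a.size();
  if (idx_b.size() != m) stop("index length mismatch");
  std::vector<double> L = nlog2n_table(n);
  NumericVector out(m);
  std::vector<int> joint(c * c), ma(c), mb(c);
  for (int q = 0; q < m; ++q) {
    const int a = idx_a[q], b = idx_b[q];
    std::fill(joint.begin(), joint.end(), 0);
    std::fill(ma.begin(), ma.end(), 0);
    std::fill(mb.begin(), mb.end(), 0);
    for (int i = 0; i < n; ++i) {
      const int xa = disc(i, a), xb = disc(i, b);
      joint[xa * c + xb]++; ma[xa]++; mb[xb]++;
    }
    double ha = 0, hb = 0, hab = 0;
    for (int k = 0; k < c; ++k) { ha += L[ma[k]]; hb += L[mb[k]]; }
    for (int k = 0; k < c * c; ++k) hab += L[joint[k]];
    // IG = H(A)+H(B)-H(A,B); n*H(A) = L[n]-sum L[n_a]
    double ig = ((L[n] - ha) + (L[n] - hb) - (L[n] - hab)) / n;
    out[q] = ig > 0 ? ig : 0.0;
  }
  return out;
}

// ---- bit-packed 2D scan ----------------------------------------------

struct PackedDraw {
  int n_words;
  std::vector<uint64_t> bits;   // gene-major: gene g at [g*n_words ...]
  std::vector<int> n1;          // popcount(x_g)
  std::vector<int> n1y1;        // popcount(x_g & y)
};

static inline int popcnt(uint64_t v) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(v);
#else
  int c = 0; while (v) { v &= v - 1; ++c; } return c;
#endif
}

// Max over draws and partner pairs of the conditional information gain
// CG(i | j) = H(Y|Xj) - H(Y|Xi,Xj), binary bins only.
// draws: list of samples x genes 0/1 integer matrices;
// pairs: m x 2 matrix of 0-based gene indices (i, j); each pair updates
// both genes' maxima with their respective conditional gains.
// [[Rcpp::export]]
NumericVector cpp_mdfs2d_max(List draws, IntegerVector y, IntegerMatrix pairs) {
  const int D = draws.size();
  if (D < 1) stop("no draws");
  IntegerMatrix first = draws[0];
  const int n = first.nrow(), p = first.ncol();
  if (y.size() != n) stop("label length mismatch");
  const int W = (n + 63) / 64;
  std::vector<double> L = nlog2n_table(n);

  std::vector<uint64_t> ybits(W, 0);
  int Ny1 = 0;
  for (int i = 0; i < n; ++i) if (y[i]) { ybits[i / 64] |= (uint64_t)1 << (i % 64); ++Ny1; }

  std::vector<PackedDraw> pk(D);
  for (int d = 0; d < D; ++d) {
    IntegerMatrix disc = draws[d];
    if (disc.nrow() != n || disc.ncol() != p) stop("draw dimension mismatch");
    PackedDraw &pd = pk[d];
    pd.n_words = W;
    pd.bits.assign((size_t)p * W, 0);
    pd.n1.assign(p, 0); pd.n1y1.assign(p, 0);
    for (int g = 0; g < p; ++g) {
      uint64_t *bg = &pd.bits[(size_t)g * W];
      for (int i = 0; i < n; ++i) {
        if (disc(i, g)) bg[i / 64] |= (uint64_t)1 << (i % 64);
      }
      int c1 = 0, c11 = 0;
      for (int w = 0; w < W; ++w) { c1 += popcnt(bg[w]); c11 += popcnt(bg[w] & ybits[w]); }
      pd.n1[g] = c1; pd.n1y1[g] = c11;
    }
  }

  // n * H(Y | X_g) per gene per draw
  std::vector<std::vector<double>> hyx(D, std::vector<double>(p));
  for (int d = 0; d < D; ++d) {
    for (int g = 0; g < p; ++g) {
      const int a1 = pk[d].n1[g], a1y1 = pk[d].n1y1[g];
      const int a0 = n - a1, a0y1 = Ny1 - a1y1;
      hyx[d][g] = (L[a1] - L[a1y1] - L[a1 - a1y1]) +
                  (L[a0] - L[a0y1] - L[a0 - a0y1]);
    }
  }

  const int m = pairs.nrow();
  NumericVector out(p, 0.0);
  for (int d = 0; d < D; ++d) {
    const PackedDraw &pd = pk[d];
    for (int q = 0; q < m; ++q) {
      const int gi = pairs(q, 0), gj = pairs(q, 1);
      const uint64_t *bi = &pd.bits[(size_t)gi * W];
      const uint64_t *bj = &pd.bits[(size_t)gj * W];
      int n11 = 0, n11y1 = 0;
      for (int w = 0; w < W; ++w) {
        const uint64_t both = bi[w] & bj[w];
        n11 += popcnt(both);
        n11y1 += popcnt(both & ybits[w]);
      }
      const int i1 = pd.n1[gi], j1 = pd.n1[gj];
      const int i1y1 = pd.n1y1[gi], j1y1 = pd.n1y1[gj];
      const int n10 = i1 - n11, n01 = j1 - n11;
      const int n00 = n - i1 - j1 + n11;
      const int n10y1 = i1y1 - n11y1, n01y1 = j1y1 - n11y1;
      const int n00y1 = Ny1 - i1y1 - j1y1 + n11y1;
      // n * H(Y | Xi, Xj)
      const double hyij =
        (L[n11] - L[n11y1] - L[n11 - n11y1]) +
        (L[n10] - L[n10y1] - L[n10 - n10y1]) +
        (L[n01] - L[n01y1] - L[n01 - n01y1]) +
        (L[n00] - L[n00y1] - L[n00 - n00y1]);
      const double cg_i = (hyx[d][gj] - hyij) / n;  // gain of i given j
      const double cg_j = (hyx[d][gi] - hyij) / n;  // gain of j given i
      if (cg_i > out[gi]) out[gi] = cg_i;
      if (cg_j > out[gj]) out[gj] = cg_j;
    }
  }
  return out;
}

// ---- FCBF --------------------------------------------------------------

// SU values are rounded to 1e-10 before ordering and predominance
// comparisons so that ties between mathematically equal quantities are
// broken by gene index, not floating-point summation order.
static inline double round10(double x) {
  return std::nearbyint(x * 1e10) / 1e10;
}

static double su_from_counts(const std::vector<int> &joint,
                             const std::vector<int> &ma,
                             const std::vector<int> &mb,
                             int ca, int cb, int n,
                             const std::vector<double> &L) {
  double ha = L[n], hb = L[n], hab = L[n];
  for (int k = 0; k < ca; ++k) ha -= L[ma[k]];
  for (int k = 0; k < cb; ++k) hb -= L[mb[k]];
  for (int k = 0; k < ca * cb; ++k) hab -= L[joint[k]];
  if (ha + hb <= 0) return 0.0;
  double ig = (ha + hb - hab) / n;
  if (ig < 0) ig = 0;
  return 2.0 * ig * n / (ha + hb);
}

// Full fast correlation-based filter. Returns the SU-with-label per gene,
// the gene order (decreasing SU, 0-based), and the selected flag after the
// predominance scan over genes with SU > delta.
// [[Rcpp::export]]
List cpp_fcbf(IntegerMatrix disc, IntegerVector y, int c, double delta) {
  const int n = disc.nrow(), p = disc.ncol();
  if (y.size() != n) stop("label length mismatch");
  std::vector<double> L = nlog2n_table(n);

  NumericVector su_y(p);
  {
    std::vector<int> joint(c * 2), ma(c), mb(2);
    for (int g = 0; g < p; ++g) {
      std::fill(joint.begin(), joint.end(), 0);
      std::fill(ma.begin(), ma.end(), 0);
      std::fill(mb.begin(), mb.end(), 0);
      for (int i = 0; i < n; ++i) {
        const int xa = disc(i, g), xb = y[i];
        joint[xa * 2 + xb]++; ma[xa]++; mb[xb]++;
      }
      su_y[g] = round10(su_from_counts(joint, ma, mb, c, 2, n, L));
    }
  }

  std::vector<int> ord(p);
  for (int g = 0; g < p; ++g) ord[g] = g;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (su_y[a] != su_y[b]) return su_y[a] > su_y[b];
    return a < b;
  });

  LogicalVector selected(p, false);
  std::vector<int> kept;
  std::vector<int> joint(c * c), ma(c), mb(c);
  for (int r = 0; r < p; ++r) {
    const int j = ord[r];
    if (!(su_y[j] > delta)) break;  // ordered, so the rest fail too
    bool dominated = false;
    for (size_t t = 0; t < kept.size() && !dominated; ++t) {
      const int i = kept[t];
      std::fill(joint.begin(), joint.end(), 0);
      std::fill(ma.begin(), ma.end(), 0);
      std::fill(mb.begin(), mb.end(), 0);
      for (int s = 0; s < n; ++s) {
        const int xa = disc(s, i), xb = disc(s, j);
        joint[xa * c + xb]++; ma[xa]++; mb[xb]++;
      }
      const double su_ij = round10(su_from_counts(joint, ma, mb, c, c, n, L));
      if (su_ij >= su_y[j]) dominated = true;
    }
    if (!dominated) { kept.push_back(j); selected[j] = true; }
  }

  return List::create(_["su_y"] = su_y,
                      _["order"] = IntegerVector(ord.begin(), ord.end()),
                      _["selected"] = selected);
}

// ---- ReliefF ------------------------------------------------------------

// ReliefF weights on range-normalized features (Manhattan distance).
// xnorm: samples x genes, already normalized to [0,1] per gene;
// y: integer class labels 0..K-1; sample_idx: 0-based instances to visit.
// For each instance, the k nearest same-class hits and, per other class,
// the k nearest misses update the weights with the prior ratio
// P(C)/(1 - P(class(i))).
// [[Rcpp::export]]
NumericVector cpp_relieff(NumericMatrix xnorm, IntegerVector y, int k,
                          IntegerVector sample_idx) {
  const int n = xnorm.nrow(), p = xnorm.ncol();
  if (y.size() != n) stop("label length mismatch");
  int K = 0;
  for (int i = 0; i < n; ++i) if (y[i] + 1 > K) K = y[i] + 1;
  std::vector<double> prior(K, 0.0);
  for (int i = 0; i < n; ++i) prior[y[i]] += 1.0 / n;

  const int m = sample_idx.size();
  NumericVector W(p, 0.0);
  std::vector<double> dist(n);
  std::vector<std::vector<std::pair<double, int>>> byclass(K);

  for (int s = 0; s < m; ++s) {
    const int i = sample_idx[s];
    for (int j = 0; j < n; ++j) {
      if (j == i) { dist[j] = R_PosInf; continue; }
      double d = 0.0;
      for (int g = 0; g < p; ++g) d += std::fabs(xnorm(i, g) - xnorm(j, g));
      dist[j] = d;
    }
    for (int cls = 0; cls < K; ++cls) byclass[cls].clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      byclass[y[j]].push_back(std::make_pair(dist[j], j));
    }
    for (int cls = 0; cls < K; ++cls) {
      std::vector<std::pair<double, int>> &v = byclass[cls];
      const int kk = std::min((size_t)k, v.size());
      if ((int)v.size() < k && cls == y[i])
        stop("k_neighbors must be smaller than the class size");
      std::partial_sort(v.begin(), v.begin() + kk, v.end());
      const double factor = (cls == y[i])
        ? -1.0
        : prior[cls] / (1.0 - prior[y[i]]);
      for (int t = 0; t < kk; ++t) {
        const int j = v[t].second;
        for (int g = 0; g < p; ++g)
          W[g] += factor * std::fabs(xnorm(i, g) - xnorm(j, g)) / ((double)m * k);
      }
    }
  }
  return W;
}
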