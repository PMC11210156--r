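// Compiled kernels for the clustering hot paths: average-linkage
// agglomeration (NN-chain), PAM (BUILD + FastPAM1-style steepest SWAP) and
// the internal validity indices. Each is cross-checked in the test suite
// against stats::hclust, cluster::pam and brute-force pair enumeration.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Average-linkage (UPGMA) hierarchical clustering via the NN-chain algorithm.
// Returns merge (n-1 x 2, hclust convention), non-decreasing heights and a
// plotting order; cutree() consumes the result directly.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_average_linkage(NumericMatrix D0) {
  const int n = D0.nrow();
  if (n < 2) stop("need at least 2 observations");
  std::vector<double> D(D0.begin(), D0.end());
  std::vector<int> sz(n, 1);
  std::vector<bool> alive(n, true);
  std::vector<int> label(n);            // current node label per slot
  for (int i = 0; i < n; ++i) label[i] = -(i + 1);

  struct MergeRec { int la, lb; double h; };
  std::vector<MergeRec> rec;
  rec.reserve(n - 1);
  std::vector<int> chain;
  chain.reserve(n + 1);

  while ((int)rec.size() < n - 1) {
    if (chain.empty()) {
      for (int i = 0; i < n; ++i) if (alive[i]) { chain.push_back(i); break; }
    }
    while (true) {
      int top = chain.back();
      int prev = (chain.size() >= 2) ? chain[chain.size() - 2] : -1;
      int nn = -1;
      double best = std::numeric_limits<double>::infinity();
      const double *col = &D[(size_t)top * n];   // symmetric: contiguous read
      for (int j = 0; j < n; ++j) {
        if (!alive[j] || j == top) continue;
        double d = col[j];
        if (d < best || (d == best && j == prev)) { best = d; nn = j; }
      }
      if (nn == prev) {                  // reciprocal nearest neighbours
        chain.pop_back(); chain.pop_back();
        int a = prev, b = top;           // result kept in slot a
        rec.push_back({label[a], label[b], best});
        label[a] = (int)rec.size();      // generation index (1-based)
        double na = sz[a], nb = sz[b];
        double *colA = &D[(size_t)a * n];
        const double *colB = &D[(size_t)b * n];
        for (int j = 0; j < n; ++j) {
          if (!alive[j] || j == a || j == b) continue;
          double d = (na * colA[j] + nb * colB[j]) / (na + nb);
          colA[j] = d;
          D[(size_t)j * n + a] = d;
        }
        sz[a] += sz[b];
        alive[b] = false;
        break;
      }
      chain.push_back(nn);
    }
  }

  // Stable sort by height: generation order is preserved on ties, which
  // keeps every child merge before its parent (average linkage is monotone).
  std::vector<int> ord(n - 1);
  for (int i = 0; i < n - 1; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return rec[a].h < rec[b].h; });
  std::vector<int> new_row(n - 1);
  for (int r = 0; r < n - 1; ++r) new_row[ord[r]] = r + 1;

  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1);
  for (int r = 0; r < n - 1; ++r) {
    const MergeRec &m = rec[ord[r]];
    int la = m.la > 0 ? new_row[m.la - 1] : m.la;
    int lb = m.lb > 0 ? new_row[m.lb - 1] : m.lb;
    // canonical within-row layout: singletons first, then by ascending label
    bool swap = (la > 0 && lb < 0) ||
                (la < 0 && lb < 0 && la < lb) ||
                (la > 0 && lb > 0 && la > lb);
    if (swap) std::swap(la, lb);
    merge(r, 0) = la;
    merge(r, 1) = lb;
    height[r] = m.h;
  }

  // leaf order by depth-first traversal of the final merge
  IntegerVector order_out(n);
  {
    std::vector<int> work;
    work.push_back(n - 1);               // rows are 1-based; last row = n-1
    int pos = 0;
    while (!work.empty()) {
      int nd = work.back(); work.pop_back();
      if (nd > 0) {
        work.push_back(merge(nd - 1, 1));
        work.push_back(merge(nd - 1, 0));
      } else {
        order_out[pos++] = -nd;
      }
    }
  }

  return List::create(_["merge"] = merge, _["height"] = height,
                      _["order"] = order_out);
}

// ---------------------------------------------------------------------------
// PAM: deterministic BUILD initialisation plus steepest-descent SWAP with the
// FastPAM1 delta computation (explores the same swap neighbourhood as the
// classical SWAP phase). Returns 1-based cluster labels.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_pam(NumericMatrix Dm, int k) {
  const int n = Dm.nrow();
  if (k < 1 || k > n) stop("invalid k");
  const double *D = Dm.begin();
  std::vector<int> med;
  med.reserve(k);
  std::vector<bool> is_med(n, false);
  std::vector<double> dnear(n);

  // BUILD
  {
    int best = -1;
    double bestTD = std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; ++i) {
      double td = 0;
      for (int j = 0; j < n; ++j) td += D[(size_t)i * n + j];
      if (td < bestTD) { bestTD = td; best = i; }
    }
    med.push_back(best);
    is_med[best] = true;
    for (int j = 0; j < n; ++j) dnear[j] = D[(size_t)best * n + j];
  }
  while ((int)med.size() < k) {
    int best = -1;
    double bestGain = -std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; ++i) {
      if (is_med[i]) continue;
      double gain = 0;
      for (int j = 0; j < n; ++j) {
        double d = D[(size_t)i * n + j];
        if (d < dnear[j]) gain += dnear[j] - d;
      }
      if (gain > bestGain) { bestGain = gain; best = i; }
    }
    med.push_back(best);
    is_med[best] = true;
    for (int j = 0; j < n; ++j) {
      double d = D[(size_t)best * n + j];
      if (d < dnear[j]) dnear[j] = d;
    }
  }

  // SWAP
  std::vector<int> nearest(n);
  std::vector<double> dsec(n);
  auto recompute = [&]() {
    for (int j = 0; j < n; ++j) {
      double d1 = std::numeric_limits<double>::infinity(), d2 = d1;
      int m1 = -1;
      for (int c = 0; c < k; ++c) {
        double d = D[(size_t)med[c] * n + j];
        if (d < d1) { d2 = d1; d1 = d; m1 = c; }
        else if (d < d2) { d2 = d; }
      }
      nearest[j] = m1; dnear[j] = d1; dsec[j] = d2;
    }
  };
  recompute();

  std::vector<double> dTD(k);
  const int max_iter = 300;
  for (int iter = 0; iter < max_iter; ++iter) {
    double bestDelta = -1e-12;
    int best_h = -1, best_c = -1;
    for (int h = 0; h < n; ++h) {
      if (is_med[h]) continue;
      std::fill(dTD.begin(), dTD.end(), 0.0);
      double acc = 0.0;
      for (int j = 0; j < n; ++j) {
        double dh = D[(size_t)h * n + j];
        double d1 = dnear[j];
        if (dh < d1) {
          acc += dh - d1;                 // j moves to h under any swap
        } else {
          // j is affected only if its nearest medoid is the one removed
          double alt = std::min(dh, dsec[j]);
          dTD[nearest[j]] += alt - d1;
        }
      }
      for (int c = 0; c < k; ++c) {
        double delta = acc + dTD[c];
        if (delta < bestDelta) { bestDelta = delta; best_h = h; best_c = c; }
      }
    }
    if (best_h < 0) break;
    is_med[med[best_c]] = false;
    med[best_c] = best_h;
    is_med[best_h] = true;
    recompute();
  }

  IntegerVector labels(n);
  for (int j = 0; j < n; ++j) labels[j] = nearest[j] + 1;
  return labels;
}

// ---------------------------------------------------------------------------
// Validity indices in one pass: WB-ratio, Dunn, average silhouette.
// labels must be 1..k with every cluster non-empty and k >= 2.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_validity(NumericMatrix Dm, IntegerVector labels, int k) {
  const int n = Dm.nrow();
  const double *D = Dm.begin();
  std::vector<int> cnt(k, 0);
  for (int i = 0; i < n; ++i) cnt[labels[i] - 1]++;

  std::vector<double> S((size_t)n * k, 0.0);  // per point: dist sum to cluster
  double within_sum = 0, between_sum = 0;
  double min_sep = std::numeric_limits<double>::infinity(), max_diam = 0;
  long long within_pairs = 0, between_pairs = 0;
  for (int i = 0; i < n; ++i) {
    int li = labels[i] - 1;
    const double *col = D + (size_t)i * n;   // column i (symmetric matrix)
    for (int j = i + 1; j < n; ++j) {
      double d = col[j];
      int lj = labels[j] - 1;
      S[(size_t)i * k + lj] += d;
      S[(size_t)j * k + li] += d;
      if (li == lj) {
        within_sum += d; ++within_pairs;
        if (d > max_diam) max_diam = d;
      } else {
        between_sum += d; ++between_pairs;
        if (d < min_sep) min_sep = d;
      }
    }
  }
  double mean_within = within_pairs > 0 ? within_sum / within_pairs : 0.0;
  double mean_between = between_sum / between_pairs;
  double wb = mean_within / mean_between;
  double dunn = max_diam > 0 ? min_sep / max_diam : R_PosInf;

  double sil_sum = 0;
  for (int i = 0; i < n; ++i) {
    int li = labels[i] - 1;
    if (cnt[li] <= 1) continue;                // silhouette 0 for singletons
    double a = S[(size_t)i * k + li] / (cnt[li] - 1);
    double b = std::numeric_limits<double>::infinity();
    for (int c = 0; c < k; ++c) {
      if (c == li) continue;
      double m = S[(size_t)i * k + c] / cnt[c];
      if (m < b) b = m;
    }
    double mx = std::max(a, b);
    sil_sum += mx > 0 ? (b - a) / mx : 0.0;
  }
  return NumericVector::create(_["wb_ratio"] = wb, _["dunn"] = dunn,
                               _["avg_silhouette"] = sil_sum / n);
}
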