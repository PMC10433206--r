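// Weighted-candidate CART regression forest with per-split audit records.
//
// Trees minimise weighted SSE (variance reduction). Split search runs over
// per-feature bins built once per fit: when a feature has at most max_bins
// distinct values the cut points are exactly the midpoints between
// consecutive distinct values (classic CART thresholds); otherwise cuts are
// placed at weighted-quantile boundaries of the observed distribution.
// Candidate features at each node are drawn without replacement with
// probability proportional to the supplied feature weights, which is what
// makes the iterative reweighting of iRF possible.
//
// Samples are addressed through `row_of`: sample i carries the feature
// vector X[row_of[i], ]. Samples mapping to the same row (e.g. patients
// sharing a ZIP code, hence identical areal covariates) always travel
// through the tree together, so the fit is carried out on distinct rows
// holding aggregated (count, sum y, sum y^2) statistics — numerically
// identical to growing the tree on the expanded sample matrix, at a fraction
// of the cost. Bootstrap resampling draws samples (not rows) and aggregates
// the draws per row, again matching the expanded-sample semantics.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>
#include <random>

using namespace Rcpp;

namespace {

struct FeatureBins {
  // thr[b] separates bin b (x <= thr[b]) from bin b+1; nbins = thr.size()+1
  std::vector<double> thr;
};

class Rng {
 public:
  explicit Rng(uint32_t seed) : gen_(seed) {}
  double unif() {
    // in (0, 1); never returns 0 so log(u) is finite
    return (static_cast<double>(gen_()) + 0.5) * (1.0 / 4294967296.0);
  }
  int below(int n) {  // integer in [0, n)
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
 private:
  std::mt19937 gen_;
};

// Distinct values with aggregated sample weights, ascending. Rows carrying
// no samples (weight 0) contribute no values, so candidate thresholds come
// from the represented samples only.
FeatureBins make_bins(const double* x, const double* wrow, int n_rows,
                      double total_w, int max_bins) {
  std::vector<std::pair<double, double> > vw;
  vw.reserve(n_rows);
  for (int r = 0; r < n_rows; ++r)
    if (wrow[r] > 0.0) vw.push_back(std::make_pair(x[r], wrow[r]));
  std::sort(vw.begin(), vw.end());
  // merge duplicates
  std::vector<double> v;
  std::vector<double> w;
  v.reserve(vw.size());
  w.reserve(vw.size());
  for (size_t r = 0; r < vw.size(); ++r) {
    if (!v.empty() && vw[r].first == v.back()) {
      w.back() += vw[r].second;
    } else {
      v.push_back(vw[r].first);
      w.push_back(vw[r].second);
    }
  }
  FeatureBins fb;
  const int nu = static_cast<int>(v.size());
  if (nu <= 1) return fb;  // constant feature: no cuts
  if (nu <= max_bins) {
    fb.thr.reserve(nu - 1);
    for (int i = 0; i + 1 < nu; ++i)
      fb.thr.push_back(v[i] + (v[i + 1] - v[i]) / 2.0);
  } else {
    fb.thr.reserve(max_bins - 1);
    double cum = 0.0;
    int k = 1;
    for (int i = 0; i + 1 < nu && k < max_bins; ++i) {
      cum += w[i];
      const double target = static_cast<double>(k) * total_w / max_bins;
      if (cum >= target) {
        fb.thr.push_back(v[i] + (v[i + 1] - v[i]) / 2.0);
        while (k < max_bins &&
               static_cast<double>(k) * total_w / max_bins <= cum)
          ++k;
      }
    }
  }
  return fb;
}

inline int bin_of(const std::vector<double>& thr, double x) {
  // first index with thr[idx] >= x; x goes left of cut c iff x <= thr[c]
  return static_cast<int>(
      std::lower_bound(thr.begin(), thr.end(), x) - thr.begin());
}

struct Node {
  int feat = -1;          // 0-based feature, -1 for leaf
  double thr = 0.0;
  int left = -1, right = -1;
  double pred = 0.0;
  double n = 0.0;         // weighted sample count
};

struct Task {
  int node_id;
  int start, end;         // range in idx (distinct rows)
};

struct SplitRow {
  int tree, node, feat;
  double thr;
  double n, nl, nr;
  double yl, yr, xl, xr, gain;
};

// Precomputed, weight-independent state shared across iRF iterations.
struct FitContext {
  const NumericMatrix& X;
  const NumericVector& y;
  const IntegerVector& row_of;
  int R, F, n, min_leaf, max_bins;
  bool bootstrap;
  std::vector<FeatureBins> bins;
  std::vector<uint16_t> bidx;
  std::vector<double> base_w, base_sy, base_syy;

  FitContext(const NumericMatrix& X_, const NumericVector& y_,
             const IntegerVector& row_of_, int min_leaf_, bool bootstrap_,
             int max_bins_)
      : X(X_), y(y_), row_of(row_of_), R(X_.nrow()), F(X_.ncol()),
        n(y_.size()), min_leaf(min_leaf_), max_bins(max_bins_),
        bootstrap(bootstrap_), base_w(R, 0.0), base_sy(R, 0.0),
        base_syy(R, 0.0) {
    if (R < 1 || n < 1) stop("X has no rows");
    if (row_of.size() != n) stop("row_of must have one entry per sample");
    if (min_leaf < 1) stop("min_leaf must be >= 1");
    if (max_bins < 2) stop("max_bins must be >= 2");
    for (int i = 0; i < n; ++i) {
      const int r = row_of[i];
      if (r < 0 || r >= R) stop("row_of out of range");
      base_w[r] += 1.0;
      base_sy[r] += y[i];
      base_syy[r] += y[i] * y[i];
    }
    bins.resize(F);
    bidx.resize(static_cast<size_t>(R) * F);
    for (int f = 0; f < F; ++f) {
      bins[f] = make_bins(&X(0, f), base_w.data(), R,
                          static_cast<double>(n), max_bins);
      const std::vector<double>& thr = bins[f].thr;
      for (int r = 0; r < R; ++r)
        bidx[static_cast<size_t>(f) * R + r] =
            static_cast<uint16_t>(bin_of(thr, X(r, f)));
    }
  }
};

List fit_one_forest(const FitContext& ctx, const NumericVector& w,
                    int n_trees, int mtry, const IntegerVector& tree_seeds) {
  const int R = ctx.R, F = ctx.F, n = ctx.n;
  const int min_leaf = ctx.min_leaf, max_bins = ctx.max_bins;
  const bool bootstrap = ctx.bootstrap;
  const NumericMatrix& X = ctx.X;
  const NumericVector& y = ctx.y;
  const IntegerVector& row_of = ctx.row_of;
  const std::vector<FeatureBins>& bins = ctx.bins;
  const std::vector<uint16_t>& bidx = ctx.bidx;
  const std::vector<double>& base_w = ctx.base_w;
  const std::vector<double>& base_sy = ctx.base_sy;
  const std::vector<double>& base_syy = ctx.base_syy;

  std::vector<int> usable;  // features with >1 distinct value and weight > 0
  usable.reserve(F);
  for (int f = 0; f < F; ++f)
    if (!bins[f].thr.empty() && w[f] > 0) usable.push_back(f);
  const int n_usable = static_cast<int>(usable.size());
  const int mtry_eff = std::min(std::max(1, mtry), std::max(n_usable, 1));

  std::vector<double> cnt(max_bins, 0.0), sybin(max_bins, 0.0);
  std::vector<double> tw(R), tsy(R), tsyy(R);
  NumericVector imp(F);
  List trees(n_trees);
  std::vector<SplitRow> all_splits;

  for (int t = 0; t < n_trees; ++t) {
    Rng rng(static_cast<uint32_t>(tree_seeds[t]));
    if (bootstrap) {
      std::fill(tw.begin(), tw.end(), 0.0);
      std::fill(tsy.begin(), tsy.end(), 0.0);
      std::fill(tsyy.begin(), tsyy.end(), 0.0);
      for (int d = 0; d < n; ++d) {
        const int i = rng.below(n);
        const int r = row_of[i];
        tw[r] += 1.0;
        tsy[r] += y[i];
        tsyy[r] += y[i] * y[i];
      }
    } else {
      tw = base_w;
      tsy = base_sy;
      tsyy = base_syy;
    }

    std::vector<int> idx;
    idx.reserve(R);
    for (int r = 0; r < R; ++r)
      if (tw[r] > 0.0) idx.push_back(r);

    std::vector<Node> nodes;
    nodes.reserve(64);
    nodes.push_back(Node());
    std::vector<Task> stack;
    stack.push_back({0, 0, static_cast<int>(idx.size())});

    std::vector<std::pair<double, int> > keys;
    keys.reserve(usable.size());

    while (!stack.empty()) {
      Task tk = stack.back();
      stack.pop_back();
      // node aggregates are recomputed from the rows rather than propagated
      // by subtraction, so mathematically equal split gains are computed
      // from identical operands and tie-breaking is exact
      double nn = 0.0, nsy = 0.0, nsyy = 0.0;
      for (int j = tk.start; j < tk.end; ++j) {
        const int r = idx[j];
        nn += tw[r];
        nsy += tsy[r];
        nsyy += tsyy[r];
      }
      Node& nd0 = nodes[tk.node_id];
      nd0.n = nn;
      nd0.pred = nsy / nn;
      const double sse = nsyy - nsy * nsy / nn;
      if (nn < 2.0 * min_leaf ||
          sse <= 1e-12 * (std::fabs(nsyy) + 1.0) || usable.empty())
        continue;  // leaf

      // candidate features: weighted sampling without replacement
      keys.clear();
      if (n_usable <= mtry_eff) {
        for (int f : usable) keys.push_back(std::make_pair(0.0, f));
      } else {
        for (int f : usable)
          keys.push_back(std::make_pair(std::log(rng.unif()) / w[f], f));
        std::nth_element(
            keys.begin(), keys.begin() + mtry_eff - 1, keys.end(),
            [](const std::pair<double, int>& a,
               const std::pair<double, int>& b) { return a.first > b.first; });
        keys.resize(mtry_eff);
      }

      double best_gain = 0.0, best_thr = 0.0;
      int best_f = -1, best_cut = -1;
      double best_nl = 0.0, best_syl = 0.0;

      const double parent_term = nsy * nsy / nn;
      for (size_t c = 0; c < keys.size(); ++c) {
        const int f = keys[c].second;
        const std::vector<double>& thr = bins[f].thr;
        const int nb = static_cast<int>(thr.size()) + 1;
        // histogram arrays are zero on entry; only touched bins are reset
        // on exit, so the cost scales with node rows, not with max_bins
        const uint16_t* bf = &bidx[static_cast<size_t>(f) * R];
        for (int j = tk.start; j < tk.end; ++j) {
          const int r = idx[j];
          const int b = bf[r];
          cnt[b] += tw[r];
          sybin[b] += tsy[r];
        }
        double cl = 0.0, syl = 0.0;
        for (int b = 0; b + 1 < nb; ++b) {
          if (cnt[b] == 0.0) continue;  // same partition as previous cut
          cl += cnt[b];
          syl += sybin[b];
          if (cl < min_leaf) continue;
          const double cr = nn - cl;
          if (cr < min_leaf) break;
          const double syr = nsy - syl;
          const double gain = syl * syl / cl + syr * syr / cr - parent_term;
          const bool better =
              gain > best_gain ||
              (best_f >= 0 && gain == best_gain &&
               (f < best_f || (f == best_f && thr[b] < best_thr)));
          if (better && gain > 0.0) {
            best_gain = gain;
            best_f = f;
            best_thr = thr[b];
            best_cut = b;
            best_nl = cl;
            best_syl = syl;
          }
        }
        if (tk.end - tk.start > nb) {
          std::fill(cnt.begin(), cnt.begin() + nb, 0.0);
          std::fill(sybin.begin(), sybin.begin() + nb, 0.0);
        } else {
          for (int j = tk.start; j < tk.end; ++j) {
            const int b = bf[idx[j]];
            cnt[b] = 0.0;
            sybin[b] = 0.0;
          }
        }
      }

      if (best_f < 0) continue;  // no admissible split: leaf

      // partition idx[start,end) by bin <= best_cut (stable)
      const uint16_t* bf = &bidx[static_cast<size_t>(best_f) * R];
      auto mid_it = std::stable_partition(
          idx.begin() + tk.start, idx.begin() + tk.end,
          [&](int r) { return bf[r] <= best_cut; });
      const int mid = static_cast<int>(mid_it - idx.begin());
      double sxl = 0.0, sxr = 0.0;
      for (int j = tk.start; j < mid; ++j) sxl += X(idx[j], best_f) * tw[idx[j]];
      for (int j = mid; j < tk.end; ++j) sxr += X(idx[j], best_f) * tw[idx[j]];

      const int li = static_cast<int>(nodes.size());
      nodes.push_back(Node());
      const int ri = static_cast<int>(nodes.size());
      nodes.push_back(Node());
      Node& nd = nodes[tk.node_id];
      nd.feat = best_f;
      nd.thr = best_thr;
      nd.left = li;
      nd.right = ri;

      const double nr = nn - best_nl;
      SplitRow sr;
      sr.tree = t + 1;
      sr.node = tk.node_id + 1;
      sr.feat = best_f + 1;
      sr.thr = best_thr;
      sr.n = nn;
      sr.nl = best_nl;
      sr.nr = nr;
      sr.yl = best_syl / best_nl;
      sr.yr = (nsy - best_syl) / nr;
      sr.xl = sxl / best_nl;
      sr.xr = sxr / nr;
      sr.gain = best_gain;
      all_splits.push_back(sr);
      imp[best_f] += best_gain;

      stack.push_back({ri, mid, tk.end});
      stack.push_back({li, tk.start, mid});
    }

    NumericMatrix tm(static_cast<int>(nodes.size()), 6);
    for (size_t k = 0; k < nodes.size(); ++k) {
      const Node& nd = nodes[k];
      tm(k, 0) = nd.feat + 1;  // 0 means leaf
      tm(k, 1) = nd.thr;
      tm(k, 2) = nd.left + 1;
      tm(k, 3) = nd.right + 1;
      tm(k, 4) = nd.pred;
      tm(k, 5) = nd.n;
    }
    colnames(tm) = CharacterVector::create("feature", "threshold", "left",
                                           "right", "pred", "n");
    trees[t] = tm;
  }

  NumericMatrix sm(static_cast<int>(all_splits.size()), 12);
  for (size_t k = 0; k < all_splits.size(); ++k) {
    const SplitRow& s = all_splits[k];
    sm(k, 0) = s.tree;
    sm(k, 1) = s.node;
    sm(k, 2) = s.feat;
    sm(k, 3) = s.thr;
    sm(k, 4) = s.n;
    sm(k, 5) = s.nl;
    sm(k, 6) = s.nr;
    sm(k, 7) = s.yl;
    sm(k, 8) = s.yr;
    sm(k, 9) = s.xl;
    sm(k, 10) = s.xr;
    sm(k, 11) = s.gain;
  }
  colnames(sm) = CharacterVector::create(
      "tree", "node", "feature", "threshold", "n_node", "n_left", "n_right",
      "y_mean_left", "y_mean_right", "x_mean_left", "x_mean_right",
      "sse_decrease");

  return List::create(_["trees"] = trees, _["splits"] = sm,
                      _["raw_importance"] = imp);
}

}  // namespace

// [[Rcpp::export]]
List cpp_fit_forest(NumericMatrix X, NumericVector y, IntegerVector row_of,
                    NumericVector w, int n_trees, int min_leaf, int mtry,
                    bool bootstrap, IntegerVector tree_seeds, int max_bins) {
  FitContext ctx(X, y, row_of, min_leaf, bootstrap, max_bins);
  return fit_one_forest(ctx, w, n_trees, mtry, tree_seeds);
}

// Full iRF driver: iteration 1 uses uniform weights 1/F; iteration t+1
// samples candidates with probability proportional to iteration t's
// normalized importance plus the smoothing floor eps, renormalized. Bins
// are computed once and shared across iterations.
// [[Rcpp::export]]
List cpp_fit_irf(NumericMatrix X, NumericVector y, IntegerVector row_of,
                 int n_trees, int min_leaf, int mtry, bool bootstrap,
                 IntegerMatrix tree_seeds, int max_bins, int n_iterations,
                 double eps) {
  FitContext ctx(X, y, row_of, min_leaf, bootstrap, max_bins);
  const int F = X.ncol();
  NumericVector w(F, 1.0 / F);
  List iterations(n_iterations);
  List weight_hist(n_iterations);
  for (int it = 0; it < n_iterations; ++it) {
    IntegerVector seeds_it = tree_seeds(_, it);
    List fit = fit_one_forest(ctx, w, n_trees, mtry, seeds_it);
    iterations[it] = fit;
    weight_hist[it] = clone(w);
    NumericVector raw = fit["raw_importance"];
    double tot = 0.0;
    for (int f = 0; f < F; ++f) tot += raw[f];
    NumericVector wn(F);
    double s = 0.0;
    for (int f = 0; f < F; ++f) {
      wn[f] = (tot > 0.0 ? raw[f] / tot : 0.0) + eps;
      s += wn[f];
    }
    for (int f = 0; f < F; ++f) w[f] = wn[f] / s;
  }
  return List::create(_["iterations"] = iterations,
                      _["weights"] = weight_hist);
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List trees, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  const int T = trees.size();
  for (int t = 0; t < T; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while (tm(k, 0) > 0) {
        const int f = static_cast<int>(tm(k, 0)) - 1;
        k = (X(i, f) <= tm(k, 1)) ? static_cast<int>(tm(k, 2)) - 1
                                  : static_cast<int>(tm(k, 3)) - 1;
      }
      out[i] += tm(k, 4);
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
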