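#include <Rcpp.h>
using namespace Rcpp;

// Paired-sample t statistic per map point for sign-flipped differences.
// D: n x p matrix of per-participant condition differences (already A - B).
// signs: length-n vector of +-1.
static void t_map(const NumericMatrix& D, const std::vector<double>& signs,
                  std::vector<double>& t) {
  const int n = D.nrow(), p = D.ncol();
  for (int j = 0; j < p; ++j) {
    double s = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) {
      const double v = signs[i] * D(i, j);
      s += v;
      ss += v * v;
    }
    const double m = s / n;
    double var = (ss - n * m * m) / (n - 1);
    if (var < 1e-300) var = 1e-300;
    t[j] = m / std::sqrt(var / n);
  }
}

// 4-connected component labelling on an nf x nt grid (points flattened
// column-major: idx = f + nf*t). Points cluster when supra-threshold AND of
// equal sign. Returns number of clusters; labels are 1..k (0 = unlabelled).
static int label_clusters(const std::vector<double>& t, double tcrit,
                          int nf, int nt, std::vector<int>& labels,
                          std::vector<double>& sums) {
  const int p = nf * nt;
  std::fill(labels.begin(), labels.end(), 0);
  sums.clear();
  int k = 0;
  std::vector<int> stack;
  for (int start = 0; start < p; ++start) {
    if (labels[start] != 0 || std::fabs(t[start]) <= tcrit) continue;
    const int sgn = t[start] > 0 ? 1 : -1;
    ++k;
    double sum = 0.0;
    stack.push_back(start);
    labels[start] = k;
    while (!stack.empty()) {
      const int idx = stack.back();
      stack.pop_back();
      sum += t[idx];
      const int f = idx % nf, tt = idx / nf;
      const int nb[4] = {f > 0 ? idx - 1 : -1, f < nf - 1 ? idx + 1 : -1,
                         tt > 0 ? idx - nf : -1, tt < nt - 1 ? idx + nf : -1};
      for (int q = 0; q < 4; ++q) {
        const int j = nb[q];
        if (j < 0 || labels[j] != 0) continue;
        if (std::fabs(t[j]) > tcrit && ((t[j] > 0 ? 1 : -1) == sgn)) {
          labels[j] = k;
          stack.push_back(j);
        }
      }
    }
    sums.push_back(sum);
  }
  return k;
}

// Cluster-based permutation test for a paired design via within-participant
// sign flips of the difference maps. Returns the observed t map, cluster
// labels and sums, and the null distribution of the maximum |t_sum|.
// [[Rcpp::export]]
List cluster_perm_paired_cpp(NumericMatrix D, int nf, int nt, int nperm,
                             double tcrit) {
  const int n = D.nrow(), p = D.ncol();
  if (p != nf * nt) stop("map dimensions do not match the data");
  std::vector<double> t(p), sums;
  std::vector<int> labels(p);
  std::vector<double> signs(n, 1.0);

  t_map(D, signs, t);
  label_clusters(t, tcrit, nf, nt, labels, sums);
  NumericVector obs_sums(sums.begin(), sums.end());
  IntegerVector obs_labels(labels.begin(), labels.end());
  NumericVector tvec(t.begin(), t.end());

  NumericVector null_max(nperm);
  std::vector<double> psums;
  std::vector<int> plabels(p);
  std::vector<double> pt(p);
  for (int b = 0; b < nperm; ++b) {
    for (int i = 0; i < n; ++i) signs[i] = unif_rand() < 0.5 ? -1.0 : 1.0;
    t_map(D, signs, pt);
    label_clusters(pt, tcrit, nf, nt, plabels, psums);
    double mx = 0.0;
    for (size_t c = 0; c < psums.size(); ++c) {
      mx = std::max(mx, std::fabs(psums[c]));
    }
    null_max[b] = mx;
  }
  return List::create(_["t"] = tvec, _["labels"] = obs_labels,
                      _["cluster_sums"] = obs_sums, _["null_max"] = null_max);
}
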