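#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Refine a haplotype partition by the alleles at SNP column j.
// cls holds a class id per haplotype; ids are compacted to 0..(n_class-1).
// Returns the new number of classes.
static int refine_classes(const IntegerMatrix& hap, int j,
                          std::vector<int>& cls, int n_class) {
  const int n = cls.size();
  // candidate id = 2*cls + allele, then compact
  std::vector<int> remap(2 * n_class, -1);
  int next_id = 0;
  for (int i = 0; i < n; ++i) {
    int cand = 2 * cls[i] + (hap(i, j) != 0 ? 1 : 0);
    if (remap[cand] < 0) remap[cand] = next_id++;
    cls[i] = remap[cand];
  }
  return next_id;
}

// Pairwise-identity homozygosity of the current partition:
// sum_c n_c (n_c - 1) / (n (n - 1)).
static double partition_homozygosity(const std::vector<int>& cls, int n_class) {
  const int n = cls.size();
  std::vector<int> cnt(n_class, 0);
  for (int i = 0; i < n; ++i) cnt[cls[i]]++;
  double num = 0.0;
  for (int c = 0; c < n_class; ++c) num += (double)cnt[c] * (cnt[c] - 1);
  return num / ((double)n * (n - 1));
}

// Walk outward from `focal` (0-based) in direction dir (+1/-1), recording the
// site-EHH curve. Identity is over all SNPs from the focal out to each point
// (the focal allele included in the partition); EHH at the focal itself is 1
// by convention. Stops at the first point with ehh < cutoff (excluded), an
// inter-SNP gap > max_gap, or the end of the SNP table.
static void ehh_walk(const IntegerMatrix& hap, const NumericVector& pos,
                     int focal, int dir, double cutoff, double max_gap,
                     std::vector<double>& out_pos, std::vector<double>& out_ehh) {
  const int n = hap.nrow();
  const int m = hap.ncol();
  out_pos.push_back(pos[focal]);
  out_ehh.push_back(1.0);
  std::vector<int> cls(n, 0);
  int n_class = refine_classes(hap, focal, cls, 1);
  double prev_pos = pos[focal];
  for (int j = focal + dir; j >= 0 && j < m; j += dir) {
    if (std::abs(pos[j] - prev_pos) > max_gap) break;
    n_class = refine_classes(hap, j, cls, n_class);
    double e = partition_homozygosity(cls, n_class);
    if (e < cutoff) break;
    out_pos.push_back(pos[j]);
    out_ehh.push_back(e);
    prev_pos = pos[j];
    if (e == 0.0) break;
  }
}

static double trapezoid(const std::vector<double>& x, const std::vector<double>& y) {
  double a = 0.0;
  for (size_t k = 1; k < x.size(); ++k)
    a += 0.5 * (y[k] + y[k - 1]) * std::abs(x[k] - x[k - 1]);
  return a;
}

// [[Rcpp::export(name = ".ehh_side_cpp")]]
DataFrame ehh_side_cpp(IntegerMatrix hap, NumericVector pos, int focal,
                       int dir, double cutoff, double max_gap) {
  if (hap.nrow() < 2) stop("EHH needs at least 2 haplotypes");
  std::vector<double> px, ex;
  ehh_walk(hap, pos, focal - 1, dir, cutoff, max_gap, px, ex);
  return DataFrame::create(_["pos"] = px, _["ehh"] = ex);
}

// [[Rcpp::export(name = ".ies_batch_cpp")]]
NumericVector ies_batch_cpp(IntegerMatrix hap, NumericVector pos,
                            double cutoff, double max_gap) {
  if (hap.nrow() < 2) stop("iES needs at least 2 haplotypes");
  const int m = hap.ncol();
  NumericVector out(m);
  std::vector<double> px, ex;
  for (int f = 0; f < m; ++f) {
    double a = 0.0;
    for (int dir = -1; dir <= 1; dir += 2) {
      px.clear(); ex.clear();
      ehh_walk(hap, pos, f, dir, cutoff, max_gap, px, ex);
      a += trapezoid(px, ex);
    }
    out[f] = a;
  }
  return out;
}

// Li-Stephens-style founder mosaic: each output haplotype copies one founder
// at a time, switching to a uniformly redrawn founder with the per-gap
// probability in switch_prob (switch_prob[0] is ignored). Uses the R RNG.
// [[Rcpp::export(name = ".mosaic_cpp")]]
IntegerMatrix mosaic_cpp(IntegerMatrix founders, int n_hap,
                         NumericVector switch_prob) {
  const int K = founders.nrow();
  const int m = founders.ncol();
  if (switch_prob.size() != m) stop("switch_prob length must equal n_snps");
  IntegerMatrix out(n_hap, m);
  for (int h = 0; h < n_hap; ++h) {
    int f = (int)std::floor(unif_rand() * K);
    if (f == K) f = K - 1;
    for (int j = 0; j < m; ++j) {
      if (j > 0 && unif_rand() < switch_prob[j]) {
        f = (int)std::floor(unif_rand() * K);
        if (f == K) f = K - 1;
      }
      out(h, j) = founders(f, j);
    }
  }
  return out;
}
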