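#include <Rcpp.h>
#include <vector>
#include <map>
using namespace Rcpp;

// Per-locus microsatellite statistics computed from a haplotype matrix
// (rows = allele copies, cols = loci, NA_INTEGER = missing copy).
// Five within-group statistics per (group, locus):
//   het  - Nei's unbiased expected heterozygosity, (n/(n-1)) (1 - sum p^2)
//   varr - sample variance of repeat counts (n-1 denominator)
//   nall - number of distinct alleles
//   maxf - frequency of the most frequent allele
//   sing - number of singleton alleles (count exactly 1)
// plus pairwise multi-allelic Weir-Cockerham theta between groups
// (haploid/allele-frequency form; no within-individual component).

struct LocusCounts {
  std::map<int, int> cnt;
  int n = 0;
  double sum = 0.0, sumsq = 0.0;
};

static void gather(const IntegerMatrix& hap, const std::vector<int>& rows,
                   int locus, LocusCounts& lc) {
  lc.cnt.clear(); lc.n = 0; lc.sum = 0.0; lc.sumsq = 0.0;
  for (int r : rows) {
    int a = hap(r, locus);
    if (a == NA_INTEGER) continue;
    lc.cnt[a]++; lc.n++;
    lc.sum += a; lc.sumsq += (double)a * a;
  }
}

static void five_stats(const LocusCounts& lc, double* out) {
  int n = lc.n;
  if (n < 2) {
    out[0] = NA_REAL; out[1] = NA_REAL;
    out[2] = (n >= 1) ? (double)lc.cnt.size() : NA_REAL;
    out[3] = (n >= 1) ? 1.0 : NA_REAL;
    out[4] = (n >= 1) ? (double)(lc.cnt.begin()->second == 1) : NA_REAL;
    return;
  }
  double sp2 = 0.0; int maxc = 0, sing = 0;
  for (auto& kv : lc.cnt) {
    double p = (double)kv.second / n;
    sp2 += p * p;
    if (kv.second > maxc) maxc = kv.second;
    if (kv.second == 1) ++sing;
  }
  out[0] = ((double)n / (n - 1.0)) * (1.0 - sp2);
  out[1] = (lc.sumsq - lc.sum * lc.sum / n) / (n - 1.0);
  out[2] = (double)lc.cnt.size();
  out[3] = (double)maxc / n;
  out[4] = (double)sing;
}

// Multi-allelic Weir-Cockerham theta for two groups at one locus, from
// allele counts (ratio-of-sums over alleles). NA when undefined (both
// groups fixed for the same allele, or a group with n < 2).
static double wc_theta(const LocusCounts& A, const LocusCounts& B) {
  int n1 = A.n, n2 = B.n;
  if (n1 < 2 || n2 < 2) return NA_REAL;
  double nt = n1 + n2;
  double nc = nt - ((double)n1 * n1 + (double)n2 * n2) / nt;
  std::map<int, std::pair<int, int>> joint;
  for (auto& kv : A.cnt) joint[kv.first].first = kv.second;
  for (auto& kv : B.cnt) joint[kv.first].second = kv.second;
  double num = 0.0, den = 0.0;
  const int r = 2;
  for (auto& kv : joint) {
    double p1 = (double)kv.second.first / n1;
    double p2 = (double)kv.second.second / n2;
    double pbar = (n1 * p1 + n2 * p2) / nt;
    double ssg = n1 * p1 * (1.0 - p1) + n2 * p2 * (1.0 - p2);
    double ssp = n1 * (p1 - pbar) * (p1 - pbar) + n2 * (p2 - pbar) * (p2 - pbar);
    double msg = ssg / (nt - r);
    double msp = ssp / (r - 1.0);
    num += msp - msg;
    den += msp + (nc - 1.0) * msg;
  }
  if (den == 0.0) return NA_REAL;
  return num / den;
}

// Returns a list:
//   within: n_loci x (5 * n_groups) matrix, group-major column blocks
//           (het, varr, nall, maxf, sing per group)
//   fst:    n_loci x n_pairs matrix, pairs (0,1),(0,2),...,(1,2),... in order
// group_of: 0-based group index per haplotype row.
// [[Rcpp::export]]
List cpp_locus_stats(IntegerMatrix hap, IntegerVector group_of, int n_groups) {
  int n_loci = hap.ncol();
  std::vector<std::vector<int>> rows(n_groups);
  for (int r = 0; r < group_of.size(); ++r) rows[group_of[r]].push_back(r);
  int n_pairs = n_groups * (n_groups - 1) / 2;
  NumericMatrix within(n_loci, 5 * n_groups);
  NumericMatrix fst(n_loci, std::max(n_pairs, 0));
  std::vector<LocusCounts> lc(n_groups);
  double s5[5];
  for (int l = 0; l < n_loci; ++l) {
    for (int g = 0; g < n_groups; ++g) {
      gather(hap, rows[g], l, lc[g]);
      five_stats(lc[g], s5);
      for (int s = 0; s < 5; ++s) within(l, 5 * g + s) = s5[s];
    }
    int p = 0;
    for (int g1 = 0; g1 < n_groups; ++g1)
      for (int g2 = g1 + 1; g2 < n_groups; ++g2)
        fst(l, p++) = wc_theta(lc[g1], lc[g2]);
  }
  return List::create(_["within"] = within, _["fst"] = fst);
}
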