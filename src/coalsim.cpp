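#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Structured-coalescent machinery.
//
// Time runs backwards from the present (t = 0) in units of generations.
// Deme i has present/reference diploid size size[i] and exponential growth
// rate alpha[i] (forward in time), i.e. looking backwards
//   N_i(t) = size[i] * exp(-alpha[i] * t)        for t <  t_growth_end[i]
//   N_i(t) = size[i] * exp(-alpha[i] * t_end)    for t >= t_growth_end[i]
// Pairwise coalescence rate within a deme is 1 / (2 N_i(t)) per generation.
// Event times are sampled exactly by inverting the integrated hazard; there
// is no time discretization. Migration is a constant per-lineage backward
// rate mig(i, j) from deme i to deme j, active only while both demes exist.
// merges rows (time, from, to) move every lineage of `from` into `to` and
// retire `from`. All randomness comes from R's RNG.

struct DemoPars {
  int n_demes;
  std::vector<double> size, alpha, t_end, alive_start;
  NumericMatrix merges;  // k x 3: time, from, to (0-based demes)
  NumericMatrix mig;     // n x n per-lineage rates
  bool has_mig;
};

// waiting time to the next coalescence in deme i with k lineages starting
// at time t; valid within a window free of regime changes (the caller caps
// the result at the next demographic boundary)
static inline double coal_wait(const DemoPars& d, int i, int k, double t) {
  if (k < 2) return R_PosInf;
  double c2 = 0.5 * k * (k - 1.0);
  double E = exp_rand();
  if (t >= d.t_end[i] || d.alpha[i] == 0.0) {
    double Nc = (t >= d.t_end[i] && R_finite(d.t_end[i]))
                  ? d.size[i] * std::exp(-d.alpha[i] * d.t_end[i])
                  : d.size[i];
    return E * 2.0 * Nc / c2;
  }
  double a = d.alpha[i];
  // integral of c2 / (2 N0 e^{-a u}) over (t, t+s] equated to E
  double arg = 1.0 + a * E * 2.0 * d.size[i] * std::exp(-a * t) / c2;
  if (arg <= 0.0) return R_PosInf;  // declining deme: hazard may never reach E
  return std::log(arg) / a;
}

// One genealogy. sample_sizes: haplotypes per deme at t = 0. Fills
// parent (0-based, -1 at root), node times, and the deme of each leaf.
// Leaves are nodes 0..n-1 in deme-block order; internal nodes are appended
// in coalescence-time order, so parent index > child index always.
static void simulate_tree(const DemoPars& d, const IntegerVector& sample_sizes,
                          std::vector<int>& parent, std::vector<double>& ntime,
                          std::vector<int>& leaf_deme) {
  int nd = d.n_demes;
  int n = 0;
  for (int i = 0; i < nd; ++i) n += sample_sizes[i];
  int n_nodes = (n >= 2) ? 2 * n - 1 : 1;
  parent.assign(n_nodes, -1);
  ntime.assign(n_nodes, 0.0);
  leaf_deme.clear();
  std::vector<std::vector<int>> by_deme(nd);  // active lineage node ids
  int id = 0;
  for (int i = 0; i < nd; ++i)
    for (int j = 0; j < sample_sizes[i]; ++j) {
      by_deme[i].push_back(id++);
      leaf_deme.push_back(i);
    }
  if (n < 2) return;

  std::vector<bool> dead(nd, false);
  std::vector<double> bounds;
  for (int r = 0; r < d.merges.nrow(); ++r) bounds.push_back(d.merges(r, 0));
  for (int i = 0; i < nd; ++i)
    if (R_finite(d.t_end[i])) bounds.push_back(d.t_end[i]);
  std::sort(bounds.begin(), bounds.end());
  bounds.erase(std::unique(bounds.begin(), bounds.end()), bounds.end());
  size_t bi = 0;

  // per-deme outward migration rate per lineage; changes only at boundaries
  std::vector<double> out(nd, 0.0);
  auto refresh_out = [&](double t) {
    for (int i = 0; i < nd; ++i) {
      out[i] = 0.0;
      if (dead[i]) continue;
      for (int j = 0; j < nd; ++j)
        if (j != i && !dead[j] && d.alive_start[j] <= t) out[i] += d.mig(i, j);
    }
  };
  if (d.has_mig) refresh_out(0.0);

  double t = 0.0;
  int next_node = n;
  int n_active = n;

  while (n_active > 1) {
    double tb = (bi < bounds.size()) ? bounds[bi] : R_PosInf;

    double s_min = R_PosInf; int ev_deme = -1;
    for (int i = 0; i < nd; ++i) {
      int k = (int)by_deme[i].size();
      if (k >= 2) {
        double s = coal_wait(d, i, k, t);
        if (s < s_min) { s_min = s; ev_deme = i; }
      }
    }
    double rate_mig = 0.0;
    if (d.has_mig)
      for (int i = 0; i < nd; ++i) rate_mig += by_deme[i].size() * out[i];
    bool mig_event = false;
    if (rate_mig > 0.0) {
      double s = exp_rand() / rate_mig;
      if (s < s_min) { s_min = s; mig_event = true; ev_deme = -1; }
    }

    if (t + s_min < tb) {
      t += s_min;
      if (mig_event) {
        double u = unif_rand() * rate_mig, acc = 0.0;
        int src_deme = nd - 1;
        for (int i = 0; i < nd; ++i) {
          acc += by_deme[i].size() * out[i];
          if (u <= acc) { src_deme = i; break; }
        }
        int li = (int)std::floor(unif_rand() * by_deme[src_deme].size());
        double v = unif_rand() * out[src_deme], acc2 = 0.0;
        int tgt = -1;
        for (int j = 0; j < nd; ++j) {
          if (j == src_deme || dead[j] || d.alive_start[j] > t) continue;
          if (d.mig(src_deme, j) <= 0.0) continue;
          tgt = j;  // last eligible target guards against fp rounding
          acc2 += d.mig(src_deme, j);
          if (v <= acc2) break;
        }
        if (tgt >= 0) {
          int node = by_deme[src_deme][li];
          by_deme[src_deme][li] = by_deme[src_deme].back();
          by_deme[src_deme].pop_back();
          by_deme[tgt].push_back(node);
        }
      } else {
        std::vector<int>& L = by_deme[ev_deme];
        int k = (int)L.size();
        int a = (int)std::floor(unif_rand() * k);
        int b = (int)std::floor(unif_rand() * (k - 1));
        if (b >= a) ++b;
        int node = next_node++;
        ntime[node] = t;
        parent[L[a]] = node;
        parent[L[b]] = node;
        L[a] = node;
        L[b] = L.back();
        L.pop_back();
        --n_active;
      }
    } else {
      t = tb;
      for (int r = 0; r < d.merges.nrow(); ++r) {
        if (d.merges(r, 0) == tb) {
          int from = (int)d.merges(r, 1), to = (int)d.merges(r, 2);
          for (int node : by_deme[from]) by_deme[to].push_back(node);
          by_deme[from].clear();
          dead[from] = true;
        }
      }
      ++bi;
      if (d.has_mig) refresh_out(t);
    }
  }
}

static DemoPars unpack(NumericVector size, NumericVector alpha,
                       NumericVector t_growth_end, NumericVector alive_start,
                       NumericMatrix merges, NumericMatrix mig) {
  DemoPars d;
  d.n_demes = size.size();
  d.size = as<std::vector<double>>(size);
  d.alpha = as<std::vector<double>>(alpha);
  d.t_end = as<std::vector<double>>(t_growth_end);
  d.alive_start = as<std::vector<double>>(alive_start);
  d.merges = merges;
  d.mig = mig;
  d.has_mig = false;
  for (int i = 0; i < mig.nrow() * mig.ncol(); ++i)
    if (mig[i] > 0.0) { d.has_mig = true; break; }
  return d;
}

// [[Rcpp::export]]
List cpp_simulate_genealogy(NumericVector size, NumericVector alpha,
                            NumericVector t_growth_end, NumericVector alive_start,
                            NumericMatrix merges, NumericMatrix mig,
                            IntegerVector sample_sizes) {
  DemoPars d = unpack(size, alpha, t_growth_end, alive_start, merges, mig);
  std::vector<int> parent, leaf_deme;
  std::vector<double> ntime;
  simulate_tree(d, sample_sizes, parent, ntime, leaf_deme);
  int n = (int)leaf_deme.size();
  return List::create(_["parent"] = wrap(parent), _["time"] = wrap(ntime),
                      _["n_leaves"] = n, _["leaf_deme"] = wrap(leaf_deme));
}

// Generalized stepwise mutation overlay. The total mutation count is
// Poisson(mu * total tree length); each mutation lands on a branch with
// probability proportional to its length (equivalent to independent
// Poisson counts per branch) and adds s * k to every descendant,
// s = +/-1 equiprobable, k = 1 + geometric(p_step) repeats,
// P(k) = p_step (1-p_step)^(k-1).
static void mutate_tree(const std::vector<int>& parent,
                        const std::vector<double>& ntime, int n_leaves,
                        double mu, double p_step, int ancestral,
                        std::vector<int>& leaf_state,
                        std::vector<double>& cumlen, std::vector<int>& delta) {
  int n_nodes = (int)parent.size();
  cumlen.resize(n_nodes);
  delta.assign(n_nodes, 0);
  double total = 0.0;
  for (int node = 0; node < n_nodes; ++node) {
    if (parent[node] >= 0) total += ntime[parent[node]] - ntime[node];
    cumlen[node] = total;
  }
  if (mu > 0.0 && total > 0.0) {
    int nmut = (int)R::rpois(mu * total);
    for (int m = 0; m < nmut; ++m) {
      double u = unif_rand() * total;
      int node = (int)(std::lower_bound(cumlen.begin(), cumlen.end(), u) -
                       cumlen.begin());
      if (node >= n_nodes) node = n_nodes - 1;
      int step = 1 + (int)R::rgeom(p_step);
      delta[node] += (unif_rand() < 0.5) ? step : -step;
    }
  }
  // parent index > child index, so a reverse sweep accumulates path sums
  std::vector<int>& state = delta;  // reuse: state[node] = delta + state[parent]
  for (int node = n_nodes - 2; node >= 0; --node)
    state[node] += state[parent[node]];
  leaf_state.resize(n_leaves);
  for (int i = 0; i < n_leaves; ++i) leaf_state[i] = ancestral + state[i];
}

// [[Rcpp::export]]
IntegerVector cpp_mutate_genealogy(IntegerVector parent, NumericVector ntime,
                                   int n_leaves, double mu, double p_step,
                                   int ancestral_state) {
  if (n_leaves < 2) return IntegerVector(n_leaves, ancestral_state);
  std::vector<int> pa = as<std::vector<int>>(parent);
  std::vector<double> tt = as<std::vector<double>>(ntime);
  std::vector<int> leaf, delta;
  std::vector<double> cumlen;
  mutate_tree(pa, tt, n_leaves, mu, p_step, ancestral_state, leaf,
              cumlen, delta);
  return wrap(leaf);
}

// Whole multi-locus dataset: per locus draw mu ~ U(mu_lo, mu_hi), simulate
// an independent genealogy, overlay mutations. Returns haplotype matrix
// (rows = haplotypes in deme-block order, cols = loci).
// [[Rcpp::export]]
IntegerMatrix cpp_simulate_dataset(NumericVector size, NumericVector alpha,
                                   NumericVector t_growth_end, NumericVector alive_start,
                                   NumericMatrix merges, NumericMatrix mig,
                                   IntegerVector sample_sizes, int n_loci,
                                   double mu_lo, double mu_hi, double p_step,
                                   int ancestral_state) {
  DemoPars d = unpack(size, alpha, t_growth_end, alive_start, merges, mig);
  int n = 0;
  for (int i = 0; i < d.n_demes; ++i) n += sample_sizes[i];
  IntegerMatrix out(n, n_loci);
  std::vector<int> parent, leaf_deme, leaf, delta;
  std::vector<double> ntime, cumlen;
  for (int l = 0; l < n_loci; ++l) {
    double mu = (mu_lo == mu_hi) ? mu_lo : R::runif(mu_lo, mu_hi);
    simulate_tree(d, sample_sizes, parent, ntime, leaf_deme);
    if (n < 2) {
      for (int i = 0; i < n; ++i) out(i, l) = ancestral_state;
      continue;
    }
    mutate_tree(parent, ntime, n, mu, p_step, ancestral_state, leaf,
                cumlen, delta);
    for (int i = 0; i < n; ++i) out(i, l) = leaf[i];
  }
  return out;
}
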