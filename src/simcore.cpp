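// Forward-time Wright-Fisher core for a recombining gene region under the
// gene-based (geometric-mean) liability model with Gaussian stabilizing
// selection.  Mutation follows the infinitely-many-sites model on [0,1);
// positions are continuous and uniqueness is enforced against all currently
// tracked (segregating + fixed) positions.
//
// All randomness comes from R's RNG so that runs are reproducible from
// set.seed() at the R level.

#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <cmath>
#include <cfloat>

using namespace Rcpp;

namespace {

struct MutationTable {
  std::vector<double> pos;
  std::vector<double> eff;
  std::vector<int> origin;
  std::unordered_set<double> pos_set;

  size_t size() const { return pos.size(); }

  // returns 0-based index of the new mutation
  int add(double p, double e, int gen) {
    pos.push_back(p);
    eff.push_back(e);
    origin.push_back(gen);
    pos_set.insert(p);
    return static_cast<int>(pos.size()) - 1;
  }

  double fresh_position() {
    double p;
    do {
      p = unif_rand();
    } while (p >= 1.0 || pos_set.count(p) > 0);
    return p;
  }
};

typedef std::vector<int> Hap;

// Poisson sampling by inversion for the small per-gamete rates used here
// (one uniform in the common zero-event case); exp(-lambda) is
// precomputed by the caller.  Falls back to R::rpois for large means.
inline int rpois_small(double lambda, double exp_neg) {
  if (lambda > 10.0) return static_cast<int>(R::rpois(lambda));
  double u = unif_rand();
  double p = exp_neg, cum = p;
  int k = 0;
  while (u > cum && k < 1000) {
    ++k;
    p *= lambda / k;
    cum += p;
  }
  return k;
}

// Gamete formation: Poisson(r) crossover breakpoints uniform on [0,1),
// alternating segments between the parental haplotypes starting from a
// randomly chosen strand, then Poisson(mu_n + mu_c) new mutations at fresh
// positions (causative w.p. mu_c/(mu_n+mu_c), effect ~ Exponential(lambda)).
// Writes into `out` (cleared first) so gamete buffers can be reused.
void make_gamete_internal(const Hap& hapA, const Hap& hapB,
                          MutationTable& tab,
                          double mu_n, double mu_c, double r, double lambda,
                          int gen, double exp_neg_r, double exp_neg_mu,
                          Hap& out) {
  out.clear();

  int nx = (r > 0.0) ? rpois_small(r, exp_neg_r) : 0;
  bool startA = (unif_rand() < 0.5);

  if (nx == 0) {
    out = startA ? hapA : hapB;
  } else {
    std::vector<double> bp(nx);
    for (int i = 0; i < nx; ++i) bp[i] = unif_rand();
    std::sort(bp.begin(), bp.end());
    // merge the two sorted haplotypes in position order, keeping an element
    // when the strand it sits on matches the current segment's strand
    size_t i = 0, j = 0, bi = 0;
    const size_t na = hapA.size(), nb = hapB.size();
    while (i < na || j < nb) {
      bool fromA;
      if (i >= na) fromA = false;
      else if (j >= nb) fromA = true;
      else fromA = tab.pos[hapA[i]] <= tab.pos[hapB[j]];
      int idx = fromA ? hapA[i] : hapB[j];
      double p = tab.pos[idx];
      while (bi < bp.size() && bp[bi] <= p) ++bi;
      bool segA = ((bi % 2 == 0) == startA);  // even segment -> start strand
      if (fromA == segA) out.push_back(idx);
      if (fromA) ++i; else ++j;
    }
  }

  double mu_tot = mu_n + mu_c;
  if (mu_tot > 0.0) {
    int nmut = rpois_small(mu_tot, exp_neg_mu);
    for (int k = 0; k < nmut; ++k) {
      double p = tab.fresh_position();
      double e = 0.0;
      if (mu_c > 0.0 && unif_rand() < mu_c / mu_tot) {
        e = (lambda > 0.0) ? R::rexp(lambda) : 0.0;  // R::rexp takes the mean
      }
      int idx = tab.add(p, e, gen);
      // insert keeping the haplotype sorted by position
      Hap::iterator it = std::lower_bound(
          out.begin(), out.end(), idx,
          [&](int a, int b) { return tab.pos[a] < tab.pos[b]; });
      out.insert(it, idx);
    }
  }
}

double hap_effect_sum(const Hap& h, const MutationTable& tab) {
  double s = 0.0;
  for (int idx : h) s += tab.eff[idx];
  return s;
}

// Remove extinct mutations from the table and move fixed mutations out of
// the haplotypes: neutral fixations are dropped entirely, causative
// fixations accumulate into the fixed-burden constant (and a log).
void compact(std::vector<Hap>& haps, MutationTable& tab, int twoN,
             double& fixed_burden,
             std::vector<double>& fixed_pos, std::vector<double>& fixed_eff,
             std::vector<int>& fixed_origin, std::vector<int>& fixed_gen,
             int gen, std::vector<int>& counts_out) {
  const size_t m = tab.size();
  std::vector<int> counts(m, 0);
  for (const Hap& h : haps)
    for (int idx : h) ++counts[idx];

  std::vector<int> remap(m, -1);
  MutationTable newtab;
  newtab.pos.reserve(m);
  std::vector<int> newcounts;
  for (size_t k = 0; k < m; ++k) {
    if (counts[k] == 0) continue;
    if (counts[k] == twoN) {
      if (tab.eff[k] > 0.0) {
        fixed_burden += tab.eff[k];
        fixed_pos.push_back(tab.pos[k]);
        fixed_eff.push_back(tab.eff[k]);
        fixed_origin.push_back(tab.origin[k]);
        fixed_gen.push_back(gen);
        newtab.pos_set.insert(tab.pos[k]);  // keep position reserved
      }
      continue;
    }
    remap[k] = newtab.add(tab.pos[k], tab.eff[k], tab.origin[k]);
    newcounts.push_back(counts[k]);
  }
  for (Hap& h : haps) {
    size_t w = 0;
    for (size_t z = 0; z < h.size(); ++z) {
      int nk = remap[h[z]];
      if (nk >= 0) h[w++] = nk;
    }
    h.resize(w);
  }
  tab = std::move(newtab);
  counts_out = std::move(newcounts);
}

List population_to_list(const std::vector<Hap>& haps, const MutationTable& tab,
                        const std::vector<int>& counts, double fixed_burden,
                        const std::vector<double>& fixed_pos,
                        const std::vector<double>& fixed_eff,
                        const std::vector<int>& fixed_origin,
                        const std::vector<int>& fixed_gen,
                        int generation, double optimum) {
  List hl(haps.size());
  for (size_t i = 0; i < haps.size(); ++i) {
    IntegerVector v(haps[i].size());
    for (size_t z = 0; z < haps[i].size(); ++z) v[z] = haps[i][z] + 1;
    hl[i] = v;
  }
  DataFrame mut = DataFrame::create(
      _["position"] = NumericVector(tab.pos.begin(), tab.pos.end()),
      _["effect"] = NumericVector(tab.eff.begin(), tab.eff.end()),
      _["origin_generation"] = IntegerVector(tab.origin.begin(), tab.origin.end()),
      _["count"] = IntegerVector(counts.begin(), counts.end()));
  DataFrame fix = DataFrame::create(
      _["position"] = NumericVector(fixed_pos.begin(), fixed_pos.end()),
      _["effect"] = NumericVector(fixed_eff.begin(), fixed_eff.end()),
      _["origin_generation"] = IntegerVector(fixed_origin.begin(), fixed_origin.end()),
      _["generation_fixed"] = IntegerVector(fixed_gen.begin(), fixed_gen.end()));
  return List::create(_["haplotypes"] = hl, _["mutations"] = mut,
                      _["fixed"] = fix, _["fixed_burden"] = fixed_burden,
                      _["generation"] = generation, _["optimum"] = optimum);
}

}  // namespace

// [[Rcpp::export(name = ".wf_evolve_cpp")]]
List wf_evolve_cpp(List haplotypes, NumericVector mut_position,
                   NumericVector mut_effect, IntegerVector mut_origin,
                   DataFrame fixed, double fixed_burden, int generation,
                   int N, double mu_neutral, double mu_causative, double r,
                   double lambda_effect, double sigma_e, double sigma_s,
                   int n_generations, bool recenter_optimum,
                   int compact_interval) {
  const int twoN = 2 * N;
  if (haplotypes.size() != twoN)
    stop("expected 2N haplotypes");

  std::vector<Hap> haps(twoN);
  for (int i = 0; i < twoN; ++i) {
    IntegerVector v = haplotypes[i];
    haps[i].assign(v.begin(), v.end());
    for (int& idx : haps[i]) --idx;  // to 0-based
  }
  MutationTable tab;
  tab.pos.assign(mut_position.begin(), mut_position.end());
  tab.eff.assign(mut_effect.begin(), mut_effect.end());
  tab.origin.assign(mut_origin.begin(), mut_origin.end());
  for (double p : tab.pos) tab.pos_set.insert(p);

  std::vector<double> fixed_pos, fixed_eff;
  std::vector<int> fixed_origin, fixed_gen;
  {
    NumericVector fp = fixed["position"], fe = fixed["effect"];
    IntegerVector fo = fixed["origin_generation"], fg = fixed["generation_fixed"];
    fixed_pos.assign(fp.begin(), fp.end());
    fixed_eff.assign(fe.begin(), fe.end());
    fixed_origin.assign(fo.begin(), fo.end());
    fixed_gen.assign(fg.begin(), fg.end());
    for (double p : fixed_pos) tab.pos_set.insert(p);
  }

  double optimum = recenter_optimum ? fixed_burden : 0.0;
  const double inv2ss = 1.0 / (2.0 * sigma_s * sigma_s);
  const double exp_neg_r = std::exp(-r);
  const double exp_neg_mu = std::exp(-(mu_neutral + mu_causative));

  std::vector<double> hap_eff(twoN), fitness(N), cumw(N);
  std::vector<Hap> offspring(twoN);
  std::vector<double> off_eff(twoN);

  bool any_causative = (mu_causative > 0.0 && lambda_effect > 0.0);
  if (!any_causative)
    for (double e : tab.eff)
      if (e > 0.0) { any_causative = true; break; }
  if (fixed_burden > 0.0) any_causative = true;

  for (int i = 0; i < twoN; ++i)
    hap_eff[i] = any_causative ? hap_effect_sum(haps[i], tab) : 0.0;

  std::vector<int> counts;  // valid only right after compaction

  for (int g = 0; g < n_generations; ++g) {
    // fitness of current diploids
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      double E1 = fixed_burden + hap_eff[2 * i];
      double E2 = fixed_burden + hap_eff[2 * i + 1];
      double G = std::sqrt(E1 * E2);
      double P = G + ((sigma_e > 0.0) ? norm_rand() * sigma_e : 0.0);
      double d = P - optimum;
      double w = std::exp(-d * d * inv2ss);
      fitness[i] = w;
      tot += w;
      cumw[i] = tot;
    }
    if (!(tot > 0.0)) stop("all fitnesses are zero; cannot sample parents");

    int cur_gen = generation + g + 1;
    for (int i = 0; i < twoN; ++i) {
      double u = unif_rand() * tot;
      int parent = static_cast<int>(
          std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
      if (parent >= N) parent = N - 1;
      make_gamete_internal(haps[2 * parent], haps[2 * parent + 1], tab,
                           mu_neutral, mu_causative, r, lambda_effect,
                           cur_gen, exp_neg_r, exp_neg_mu, offspring[i]);
      off_eff[i] = any_causative ? hap_effect_sum(offspring[i], tab) : 0.0;
    }
    haps.swap(offspring);
    hap_eff.swap(off_eff);

    bool last = (g == n_generations - 1);
    if (last || ((g + 1) % compact_interval == 0)) {
      double old_burden = fixed_burden;
      compact(haps, tab, twoN, fixed_burden, fixed_pos, fixed_eff,
              fixed_origin, fixed_gen, cur_gen, counts);
      if (fixed_burden != old_burden) {
        any_causative = true;
        if (recenter_optimum) optimum = fixed_burden;
      }
      if (any_causative)
        for (int i = 0; i < twoN; ++i)
          hap_eff[i] = hap_effect_sum(haps[i], tab);
    }
  }

  if (n_generations == 0) {
    compact(haps, tab, twoN, fixed_burden, fixed_pos, fixed_eff, fixed_origin,
            fixed_gen, generation, counts);
  }

  return population_to_list(haps, tab, counts, fixed_burden, fixed_pos,
                            fixed_eff, fixed_origin, fixed_gen,
                            generation + n_generations, optimum);
}

// [[Rcpp::export(name = ".make_gamete_cpp")]]
List make_gamete_cpp(IntegerVector hapA, IntegerVector hapB,
                     NumericVector mut_position, NumericVector mut_effect,
                     double mu_neutral, double mu_causative, double r,
                     double lambda_effect, int origin_generation) {
  MutationTable tab;
  tab.pos.assign(mut_position.begin(), mut_position.end());
  tab.eff.assign(mut_effect.begin(), mut_effect.end());
  tab.origin.assign(mut_position.size(), 0);
  for (double p : tab.pos) tab.pos_set.insert(p);
  size_t m0 = tab.size();

  Hap A(hapA.begin(), hapA.end()), B(hapB.begin(), hapB.end());
  for (int& x : A) --x;
  for (int& x : B) --x;

  Hap g;
  make_gamete_internal(A, B, tab, mu_neutral, mu_causative, r,
                       lambda_effect, origin_generation,
                       std::exp(-r), std::exp(-(mu_neutral + mu_causative)),
                       g);

  IntegerVector out(g.size());
  for (size_t i = 0; i < g.size(); ++i) out[i] = g[i] + 1;
  size_t n_new = tab.size() - m0;
  NumericVector np(n_new), ne(n_new);
  for (size_t i = 0; i < n_new; ++i) {
    np[i] = tab.pos[m0 + i];
    ne[i] = tab.eff[m0 + i];
  }
  return List::create(_["haplotype"] = out, _["new_position"] = np,
                      _["new_effect"] = ne);
}

// Two-sided Fisher exact p-values for 2x2 tables given as parallel vectors:
// a = minor alleles in cases, b = major in cases, c = minor in controls,
// d = major in controls.  Two-sided by the usual likelihood-ordering rule
// (sum of all hypergeometric point probabilities <= P(observed)*(1+1e-7)).
// [[Rcpp::export(name = ".fisher2x2_cpp")]]
NumericVector fisher2x2_cpp(IntegerVector a, IntegerVector b, IntegerVector c,
                            IntegerVector d) {
  const int n = a.size();
  NumericVector out(n);
  const double relerr = 1.0 + 1e-7;
  for (int i = 0; i < n; ++i) {
    int m = a[i] + c[i];       // total minor alleles
    int nn = b[i] + d[i];      // total major alleles
    int k = a[i] + b[i];       // alleles in cases
    int lo = std::max(0, k - nn), hi = std::min(k, m);
    double pobs = R::dhyper(a[i], m, nn, k, 0);
    // walk the support outward from the mode with the ratio recurrence;
    // the mode probability is always representable, and terms that
    // underflow far in the tails contribute nothing to the sum
    int mode = (int)std::floor((double)(k + 1) * (double)(m + 1) /
                               (double)(m + nn + 2));
    if (mode < lo) mode = lo;
    if (mode > hi) mode = hi;
    double pmode = R::dhyper(mode, m, nn, k, 0);
    double p = (pmode <= pobs * relerr) ? pmode : 0.0;
    double px = pmode;
    for (int x = mode; x < hi; ++x) {  // uphill in x, downhill in prob
      px *= (double)(m - x) * (double)(k - x) /
            ((double)(x + 1) * (double)(nn - k + x + 1));
      if (px <= pobs * relerr) p += px;
    }
    px = pmode;
    for (int x = mode; x > lo; --x) {
      px *= (double)x * (double)(nn - k + x) /
            ((double)(m - x + 1) * (double)(k - x + 1));
      if (px <= pobs * relerr) p += px;
    }
    out[i] = std::max(std::min(p, 1.0), DBL_MIN);
  }
  return out;
}
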