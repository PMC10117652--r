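// Metropolis-Hastings core for the two-locus TRD models.
//
// Likelihoods operate on aggregated counts: one row per observed ordered
// mating configuration, nine offspring-class columns in the package's
// canonical order. The sampler consumes R's RNG (norm_rand / unif_rand) in
// exactly the same order as the reference R implementation, so chains are
// reproducible and bit-identical across the two code paths.

#include <Rcpp.h>
using namespace Rcpp;

// coefficient rows, parameter order:
// alpha_A, alpha_B, delta_A, delta_B, aa_e, ad_e, da_e, dd_e
static const int GENO_COEF[9][8] = {
    {+1, +1, -1, -1, +1, +1, +1, -1}, // AABB
    {0, +1, +1, -1, 0, 0, -1, +1},    // AaBB
    {-1, +1, -1, -1, -1, -1, +1, -1}, // aaBB
    {+1, 0, -1, +1, 0, -1, 0, +1},    // AABb
    {0, 0, +1, +1, 0, 0, 0, -1},      // AaBb
    {-1, 0, -1, +1, 0, +1, 0, +1},    // aaBb
    {+1, -1, -1, -1, -1, +1, -1, -1}, // AAbb
    {0, -1, +1, -1, 0, 0, +1, +1},    // Aabb
    {-1, -1, -1, -1, +1, -1, -1, -1}  // aabb
};

static const int DOSE_A[9] = {2, 1, 0, 2, 1, 0, 2, 1, 0};
static const int DOSE_B[9] = {2, 2, 2, 1, 1, 1, 0, 0, 0};
// gametes in canonical order AB, Ab, aB, ab (capital-allele indicators)
static const int GAM_A[4] = {1, 1, 0, 0};
static const int GAM_B[4] = {1, 0, 1, 0};
// slot of beta_{gi/gj} (i<j) within params[2..7]
static const int PAIR_SLOT[4][4] = {
    {-1, 0, 1, 2}, {0, -1, 3, 4}, {1, 3, -1, 5}, {2, 4, 5, -1}};

static double geno_loglik(const NumericMatrix &cnt, const NumericMatrix &mend,
                          const double *p) {
  double ll = 0.0;
  const int nm = cnt.nrow();
  for (int m = 0; m < nm; ++m) {
    double w[9], S = 0.0;
    for (int g = 0; g < 9; ++g) {
      double base = 16.0 * mend(m, g);
      double v = 0.0;
      if (base > 0.0) {
        v = base;
        for (int k = 0; k < 8; ++k) v += GENO_COEF[g][k] * p[k];
        if (v < 0.0) v = 0.0;
      }
      w[g] = v;
      S += v;
    }
    if (S <= 0.0) return R_NegInf;
    const double logS = std::log(S);
    for (int g = 0; g < 9; ++g) {
      double c = cnt(m, g);
      if (c > 0.0) {
        if (w[g] <= 0.0) return R_NegInf;
        ll += c * (std::log(w[g]) - logS);
      }
    }
  }
  return ll;
}

// normalized gamete distribution of one parent; returns false if degenerate
static bool gamete_dist(int dose_a, int dose_b, const double *p,
                        double out[4]) {
  bool hetA = dose_a == 1, hetB = dose_b == 1;
  int feas[4], nf = 0;
  for (int g = 0; g < 4; ++g) {
    bool okA = hetA || GAM_A[g] == (dose_a == 2 ? 1 : 0);
    bool okB = hetB || GAM_B[g] == (dose_b == 2 ? 1 : 0);
    out[g] = 0.0;
    if (okA && okB) feas[nf++] = g;
  }
  if (nf == 1) {
    out[feas[0]] = 1.0;
    return true;
  }
  double S = 0.0;
  for (int i = 0; i < nf; ++i) {
    int g = feas[i];
    double f = 1.0;
    if (hetA) f *= GAM_A[g] ? 0.5 + p[0] : 0.5 - p[0];
    if (hetB) f *= GAM_B[g] ? 0.5 + p[1] : 0.5 - p[1];
    int comp = (nf == 4) ? 3 - g : feas[1 - i];
    double pf = (g < comp) ? 1.0 + p[2 + PAIR_SLOT[g][comp]]
                           : 1.0 - p[2 + PAIR_SLOT[comp][g]];
    out[g] = f * pf;
    S += out[g];
  }
  if (S <= 0.0) return false;
  for (int g = 0; g < 4; ++g) out[g] /= S;
  return true;
}

static double allelic_loglik(const NumericMatrix &cnt,
                             const IntegerVector &sire_a,
                             const IntegerVector &sire_b,
                             const IntegerVector &dam_a,
                             const IntegerVector &dam_b, const double *p) {
  double ll = 0.0;
  const int nm = cnt.nrow();
  for (int m = 0; m < nm; ++m) {
    double ps[4], pd[4], cls[9];
    if (!gamete_dist(sire_a[m], sire_b[m], p, ps)) return R_NegInf;
    if (!gamete_dist(dam_a[m], dam_b[m], p, pd)) return R_NegInf;
    for (int g = 0; g < 9; ++g) cls[g] = 0.0;
    for (int gs = 0; gs < 4; ++gs) {
      if (ps[gs] == 0.0) continue;
      for (int gd = 0; gd < 4; ++gd) {
        if (pd[gd] == 0.0) continue;
        int da = GAM_A[gs] + GAM_A[gd], db = GAM_B[gs] + GAM_B[gd];
        int k = 3 * (2 - db) + (2 - da);
        cls[k] += ps[gs] * pd[gd];
      }
    }
    for (int g = 0; g < 9; ++g) {
      double c = cnt(m, g);
      if (c > 0.0) {
        if (cls[g] <= 0.0) return R_NegInf;
        ll += c * std::log(cls[g]);
      }
    }
  }
  return ll;
}

// [[Rcpp::export(name = ".geno_loglik_cpp")]]
double geno_loglik_cpp(NumericMatrix cnt, NumericMatrix mend,
                       NumericVector params) {
  return geno_loglik(cnt, mend, params.begin());
}

// [[Rcpp::export(name = ".allelic_loglik_cpp")]]
double allelic_loglik_cpp(NumericMatrix cnt, IntegerVector sire_a,
                          IntegerVector sire_b, IntegerVector dam_a,
                          IntegerVector dam_b, NumericVector params) {
  return allelic_loglik(cnt, sire_a, sire_b, dam_a, dam_b, params.begin());
}

static double reflect(double x, double lo, double hi) {
  while (x < lo || x > hi) {
    if (x > hi)
      x = 2.0 * hi - x;
    else
      x = 2.0 * lo - x;
  }
  return x;
}

// model: 1 = genotypic, 2 = allelic
// [[Rcpp::export(name = ".mh_core_cpp")]]
List mh_core_cpp(int model, NumericMatrix cnt, NumericMatrix mend,
                 IntegerVector sire_a, IntegerVector sire_b,
                 IntegerVector dam_a, IntegerVector dam_b,
                 NumericVector lower, NumericVector upper,
                 NumericVector prop_sd, int n_iter, int burn_in, int thin,
                 bool tune, int tune_interval) {
  const int np = lower.size();
  std::vector<double> cur(np, 0.0), sd(prop_sd.begin(), prop_sd.end());
  std::vector<int> n_acc(np, 0), n_try(np, 0);

  auto loglik = [&](const double *p) -> double {
    if (model == 1) return geno_loglik(cnt, mend, p);
    return allelic_loglik(cnt, sire_a, sire_b, dam_a, dam_b, p);
  };

  double cur_ll = loglik(cur.data());
  if (!R_finite(cur_ll))
    stop("log-likelihood is not finite at the all-zero (Mendelian) start; "
         "check the pair data for impossible counts");

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix draws(n_keep, np);
  NumericVector ll_out(n_keep);
  long long accepted = 0, proposed = 0;
  int kept = 0;

  std::vector<double> prop(np);
  for (int it = 1; it <= n_iter; ++it) {
    for (int k = 0; k < np; ++k) {
      std::copy(cur.begin(), cur.end(), prop.begin());
      double x = cur[k] + sd[k] * norm_rand();
      prop[k] = reflect(x, lower[k], upper[k]);
      double new_ll = loglik(prop.data());
      double u = unif_rand();
      ++proposed;
      ++n_try[k];
      if (R_finite(new_ll) && std::log(u) < new_ll - cur_ll) {
        cur[k] = prop[k];
        cur_ll = new_ll;
        ++accepted;
        ++n_acc[k];
      }
    }
    if (tune && it <= burn_in && it % tune_interval == 0) {
      for (int k = 0; k < np; ++k) {
        double rate = n_try[k] ? (double)n_acc[k] / n_try[k] : 0.0;
        if (rate < 0.2)
          sd[k] *= 0.8;
        else if (rate > 0.4)
          sd[k] *= 1.25;
        double cap = (upper[k] - lower[k]) / 2.0;
        if (sd[k] > cap) sd[k] = cap;
        if (sd[k] < 1e-4) sd[k] = 1e-4;
        n_acc[k] = 0;
        n_try[k] = 0;
      }
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int k = 0; k < np; ++k) draws(kept, k) = cur[k];
      ll_out[kept] = cur_ll;
      ++kept;
    }
  }

  return List::create(
      _["draws"] = draws, _["ll"] = ll_out,
      _["acceptance_rate"] = (double)accepted / (double)proposed,
      _["proposal_sd"] = NumericVector(sd.begin(), sd.end()));
}
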