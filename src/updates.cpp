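#include <Rcpp.h>
#include "geno.h"
using namespace Rcpp;

#define geno_prob spmig_geno_prob

static const double OFF = 0.1; // floor added to Dirichlet proposal shapes

static double ddir_log(const std::vector<double> &x,
                       const std::vector<double> &sh) {
  double s = 0.0, ssh = 0.0;
  for (size_t a = 0; a < x.size(); ++a) {
    if (x[a] <= 0.0) return R_NegInf;
    s += (sh[a] - 1.0) * std::log(x[a]) - R::lgammafn(sh[a]);
    ssh += sh[a];
  }
  return s + R::lgammafn(ssh);
}

// Metropolis-Hastings sweep over all (population, locus) allele-frequency
// rows. Proposal: Dirichlet centred at the current row with concentration
// h(j,l) (plus a small floor). Target: F-model Dirichlet prior
// Dir(q_l (1-FST_j)/FST_j) times the genotype likelihood of individuals
// whose maternal or paternal gametes were drawn from population j (given the
// current latent origins). Uses the R RNG. Returns the updated frequency
// list and a K x L acceptance indicator matrix.
// [[Rcpp::export]]
List update_p_cpp(IntegerMatrix A1, IntegerMatrix A2, List p, List q,
                  NumericVector fst, IntegerVector jm, IntegerVector jp,
                  NumericVector Fi, NumericVector eps, NumericMatrix h) {
  const int N = A1.nrow(), L = A1.ncol();
  List pout(L);
  for (int l = 0; l < L; ++l) pout[l] = clone(as<NumericMatrix>(p[l]));
  const int K = as<NumericMatrix>(pout[0]).nrow();
  NumericMatrix acc(K, L);

  for (int l = 0; l < L; ++l) {
    NumericMatrix P = pout[l];
    NumericVector ql = q[l];
    const int A = P.ncol();
    std::vector<double> cur(A), prop(A), sh(A), shp(A), shc(A);
    for (int j = 0; j < K; ++j) {
      for (int a = 0; a < A; ++a) cur[a] = P(j, a);
      const double hjl = h(j, l);
      double s = 0.0;
      for (int a = 0; a < A; ++a) {
        sh[a] = hjl * cur[a] + OFF;
        prop[a] = R::rgamma(sh[a], 1.0);
        s += prop[a];
      }
      if (s <= 0.0) continue;
      bool ok = true;
      for (int a = 0; a < A; ++a) {
        prop[a] /= s;
        if (prop[a] <= 0.0) ok = false;
      }
      if (!ok) continue;
      const double thc = (1.0 - fst[j]) / fst[j];
      for (int a = 0; a < A; ++a) {
        shc[a] = ql[a] * thc;               // prior concentrations
        shp[a] = hjl * prop[a] + OFF;       // reverse-proposal shapes
      }
      double lr = ddir_log(prop, shc) - ddir_log(cur, shc)
                + ddir_log(cur, shp) - ddir_log(prop, sh);
      // likelihood ratio over individuals drawing a gamete from pop j
      for (int i = 0; i < N && std::isfinite(lr); ++i) {
        const int mj = jm[i] - 1, pj = jp[i] - 1;
        if (mj != j && pj != j) continue;
        const int a1 = A1(i, l);
        if (a1 == NA_INTEGER) continue;
        const int a2 = A2(i, l);
        const bool same = (mj == pj);
        double m1o = P(mj, a1 - 1), m2o = P(mj, a2 - 1);
        double p1o = P(pj, a1 - 1), p2o = P(pj, a2 - 1);
        double m1n = (mj == j) ? prop[a1 - 1] : m1o;
        double m2n = (mj == j) ? prop[a2 - 1] : m2o;
        double p1n = (pj == j) ? prop[a1 - 1] : p1o;
        double p2n = (pj == j) ? prop[a2 - 1] : p2o;
        double vold = geno_prob(a1, a2, m1o, m2o, p1o, p2o, same, Fi[i], eps[l]);
        double vnew = geno_prob(a1, a2, m1n, m2n, p1n, p2n, same, Fi[i], eps[l]);
        if (vnew <= 0.0) { lr = R_NegInf; break; }
        if (vold <= 0.0) { lr = R_PosInf; break; }
        lr += std::log(vnew) - std::log(vold);
      }
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        for (int a = 0; a < A; ++a) P(j, a) = prop[a];
        acc(j, l) = 1.0;
      }
    }
  }
  return List::create(_["p"] = pout, _["acc"] = acc);
}
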