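#include <Rcpp.h>
#include "geno.h"
using namespace Rcpp;

#define geno_prob spmig_geno_prob

// Log-likelihood table: N x K^2 matrix of log Pr_jk(G_i | p, F_i, eps),
// column index (j-1)*K + k (1-based j, k). Missing loci (NA) contribute 1.
// Products are accumulated in double precision with periodic log flushes so
// SNP-scale locus counts do not underflow.
// [[Rcpp::export]]
NumericMatrix loglik_table_cpp(IntegerMatrix A1, IntegerMatrix A2, List p,
                               NumericVector Fi, NumericVector eps) {
  const int N = A1.nrow(), L = A1.ncol();
  const NumericMatrix p0 = as<NumericMatrix>(p[0]);
  const int K = p0.nrow();
  const int K2 = K * K;
  NumericMatrix out(N, K2);
  std::vector<double> acc(K2), lacc(K2);
  std::vector<double> f1(K), f2(K);
  std::vector<NumericMatrix> pl(L);
  for (int l = 0; l < L; ++l) pl[l] = as<NumericMatrix>(p[l]);

  for (int i = 0; i < N; ++i) {
    const double F = Fi[i];
    std::fill(acc.begin(), acc.end(), 1.0);
    std::fill(lacc.begin(), lacc.end(), 0.0);
    for (int l = 0; l < L; ++l) {
      const int a1 = A1(i, l), a2 = A2(i, l);
      if (a1 == NA_INTEGER) continue;
      const double e = eps[l];
      const NumericMatrix &P = pl[l];
      for (int j = 0; j < K; ++j) {
        f1[j] = P(j, a1 - 1);
        f2[j] = P(j, a2 - 1);
      }
      for (int j = 0; j < K; ++j) {
        const double pj1 = f1[j], pj2 = f2[j];
        for (int k = 0; k < K; ++k) {
          const int c = j * K + k;
          double v = geno_prob(a1, a2, pj1, pj2, f1[k], f2[k], j == k, F, e);
          acc[c] *= v;
          if (acc[c] < 1e-280) {
            if (acc[c] <= 0.0) { lacc[c] = R_NegInf; acc[c] = 1.0; }
            else { lacc[c] += std::log(acc[c]); acc[c] = 1.0; }
          }
        }
      }
    }
    for (int c = 0; c < K2; ++c)
      out(i, c) = (lacc[c] == R_NegInf) ? R_NegInf : lacc[c] + std::log(acc[c]);
  }
  return out;
}

// Per-individual log genotype probability at one locus given fixed origins.
// [[Rcpp::export]]
NumericVector locus_loglik_cpp(IntegerVector a1, IntegerVector a2,
                               NumericMatrix pl, IntegerVector jm,
                               IntegerVector jp, NumericVector Fi,
                               double eps_l) {
  const int N = a1.size();
  NumericVector out(N);
  for (int i = 0; i < N; ++i) {
    if (a1[i] == NA_INTEGER) { out[i] = 0.0; continue; }
    const int j = jm[i] - 1, k = jp[i] - 1;
    double v = geno_prob(a1[i], a2[i],
                         pl(j, a1[i] - 1), pl(j, a2[i] - 1),
                         pl(k, a1[i] - 1), pl(k, a2[i] - 1),
                         j == k, Fi[i], eps_l);
    out[i] = (v > 0.0) ? std::log(v) : R_NegInf;
  }
  return out;
}

// Total log-likelihood of one individual across loci given fixed origins.
// [[Rcpp::export]]
double indiv_loglik_cpp(IntegerMatrix A1, IntegerMatrix A2, List p,
                        int i, int j, int k, double F, NumericVector eps) {
  const int L = A1.ncol();
  const int i0 = i - 1, j0 = j - 1, k0 = k - 1;
  double ll = 0.0;
  for (int l = 0; l < L; ++l) {
    const int a1 = A1(i0, l), a2 = A2(i0, l);
    if (a1 == NA_INTEGER) continue;
    const NumericMatrix pl = as<NumericMatrix>(p[l]);
    double v = geno_prob(a1, a2,
                         pl(j0, a1 - 1), pl(j0, a2 - 1),
                         pl(k0, a1 - 1), pl(k0, a2 - 1),
                         j0 == k0, F, eps[l]);
    if (v <= 0.0) return R_NegInf;
    ll += std::log(v);
  }
  return ll;
}

// Draw one origin pair per individual from unnormalized log weights.
// W: N x K^2 row-wise log weights; u: N uniforms from the R RNG.
// Returns 1-based column indices.
// [[Rcpp::export]]
IntegerVector sample_rows_cpp(NumericMatrix W, NumericVector u) {
  const int N = W.nrow(), C = W.ncol();
  IntegerVector out(N);
  std::vector<double> w(C);
  for (int i = 0; i < N; ++i) {
    double mx = R_NegInf;
    for (int c = 0; c < C; ++c) if (W(i, c) > mx) mx = W(i, c);
    double s = 0.0;
    for (int c = 0; c < C; ++c) { w[c] = std::exp(W(i, c) - mx); s += w[c]; }
    double target = u[i] * s, cum = 0.0;
    int pick = C - 1;
    for (int c = 0; c < C; ++c) { cum += w[c]; if (cum >= target) { pick = c; break; } }
    out[i] = pick + 1;
  }
  return out;
}
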