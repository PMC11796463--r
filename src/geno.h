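#ifndef SPMIG_GENO_H
#define SPMIG_GENO_H

// Four-branch single-locus genotype probability. F (inbreeding) only enters
// when both gametes share a source population; eps is the allelic dropout
// rate (a true heterozygote is scored as either homozygote, eps/2 each).
static inline double spmig_geno_prob(int a1, int a2,
                                     double pj1, double pj2,
                                     double pk1, double pk2,
                                     bool same_pop, double F, double e) {
  if (a1 == a2) {
    if (same_pop)
      return F * pj1 + (1.0 - F) * (pj1 * pj1 + e * pj1 * (1.0 - pj1));
    return pj1 * pk1 + 0.5 * e * (pj1 * (1.0 - pk1) + pk1 * (1.0 - pj1));
  }
  if (same_pop)
    return (1.0 - F) * (1.0 - e) * 2.0 * pj1 * pj2;
  return (1.0 - e) * (pj1 * pk2 + pk1 * pj2);
}

#endif
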