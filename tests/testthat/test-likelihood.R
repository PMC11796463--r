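# Genotypic likelihood: four-branch single-locus probabilities, multilocus
# products, and the mixture over latent origins.

test_that("single-locus probabilities match their limiting cases", {
  p_l <- rand_p(2, 3)
  # fully inbred limit, same source: P(a/a) = p_a
  expect_equal(genotype_prob(c(2, 2), 1, 1, p_l, F_i = 1, eps_l = 0),
               p_l[1, 2])
  # Hardy-Weinberg limit: P(a/b) = 2 p_a p_b
  expect_equal(genotype_prob(c(1, 3), 2, 2, p_l, F_i = 0, eps_l = 0),
               2 * p_l[2, 1] * p_l[2, 3])
  # complete dropout: heterozygotes are never observed
  expect_equal(genotype_prob(c(1, 2), 1, 2, p_l, F_i = 0, eps_l = 1), 0)
  expect_equal(genotype_prob(c(1, 2), 1, 1, p_l, F_i = 0.3, eps_l = 1), 0)
  # missing locus is uninformative
  expect_equal(genotype_prob(NA, 1, 2, p_l, 0.5, 0.5), 1)
  # dropout-free homozygote branch reduces to F p + (1-F) p^2
  Fi <- 0.4
  expect_equal(genotype_prob(c(3, 3), 2, 2, p_l, Fi, 0),
               Fi * p_l[2, 3] + (1 - Fi) * p_l[2, 3]^2)
})

test_that("probabilities over observable genotypes sum to one for every branch", {
  set.seed(42)
  for (A in 2:6) {
    p_l <- rand_p(3, A)
    for (case in list(c(1, 1, 0.3, 0.2), c(1, 2, 0.3, 0.2),
                      c(2, 2, 0, 0.9), c(1, 3, 0.9, 0))) {
      j <- case[1]; k <- case[2]; Fi <- case[3]; e <- case[4]
      s <- 0
      for (a in seq_len(A)) for (b in a:A) {
        s <- s + genotype_prob(c(a, b), j, k, p_l, Fi, e)
      }
      expect_equal(s, 1, tolerance = 1e-12)
    }
  }
})

test_that("biallelic dropout probabilities over the 3 observable genotypes sum to 1", {
  p_l <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  s <- sum(vapply(list(c(1, 1), c(1, 2), c(2, 2)), function(g) {
    genotype_prob(g, 1, 2, p_l, F_i = 0, eps_l = 0.1)
  }, 0))
  expect_equal(s, 1, tolerance = 1e-12)
})

test_that("invalid allele indices are reported", {
  p_l <- rand_p(2, 2)
  expect_error(genotype_prob(c(1, 3), 1, 1, p_l), "invalid allele")
})

test_that("multilocus log-likelihood is the sum of per-locus logs", {
  dat <- toy_dataset(K = 2, N = 5, L = 3, A = 3, missing = 2)
  par <- toy_params(dat, F_i = 0.2, eps = 0.1)
  for (i in c(1, 4)) for (jk in list(c(1, 1), c(2, 1))) {
    manual <- 0
    for (l in 1:3) {
      g <- c(dat$a1[i, l], dat$a2[i, l])
      manual <- manual + log(genotype_prob(if (anyNA(g)) NA else g,
                                           jk[1], jk[2], par$p[[l]],
                                           0.2, 0.1))
    }
    expect_equal(individual_lik(i, jk[1], jk[2], par, dat), manual)
  }
  # all loci missing: log 1 = 0
  dat2 <- toy_dataset(K = 1, N = 2, L = 2, A = 2)
  dat2$a1[] <- NA; dat2$a2[] <- NA
  par2 <- toy_params(dat2)
  expect_equal(individual_lik(1, 1, 1, par2, dat2), 0)
})

test_that("the origin mixture matches brute-force enumeration", {
  dat <- toy_dataset(K = 2, N = 6, L = 3, A = 3)
  par <- toy_params(dat, F_i = 0.1, eps = 0.05)
  alpha <- rbind(c(0.8, 0.2), c(0.3, 0.7))
  beta <- rbind(c(0.9, 0.1), c(0.4, 0.6))
  for (i in c(1, 2)) {
    s_i <- dat$pop[i]
    brute <- 0
    for (j in 1:2) for (k in 1:2) {
      brute <- brute + alpha[s_i, j] * beta[j, k] *
        exp(individual_lik(i, j, k, par, dat))
    }
    expect_equal(marginal_lik(i, alpha[s_i, ], beta, par, dat), log(brute),
                 tolerance = 1e-12)
  }
  # degenerate no-migration weights collapse to the local-origin likelihood
  expect_equal(marginal_lik(1, c(1, 0), diag(2), par, dat),
               individual_lik(1, 1, 1, par, dat))
})

test_that("origin conditionals normalize and respect structure", {
  dat <- toy_dataset(K = 2, N = 6, L = 3, A = 3)
  par <- toy_params(dat, F_i = 0.1, eps = 0.05)
  alpha <- rbind(c(0.8, 0.2), c(0.3, 0.7))
  beta <- rbind(c(0.9, 0.1), c(0.4, 0.6))
  tab <- origin_conditional(2, alpha[dat$pop[2], ], beta, par, dat)
  expect_equal(sum(tab), 1, tolerance = 1e-12)
  # brute force
  brute <- matrix(0, 2, 2)
  for (j in 1:2) for (k in 1:2) {
    brute[j, k] <- alpha[dat$pop[2], j] * beta[j, k] *
      exp(individual_lik(2, j, k, par, dat))
  }
  expect_equal(tab, brute / sum(brute), tolerance = 1e-12)
  # uninformative genotypes: conditional equals the prior outer structure
  dat$a1[] <- NA; dat$a2[] <- NA
  tab0 <- origin_conditional(1, alpha[1, ], beta, par, dat)
  expect_equal(tab0, alpha[1, ] * beta, tolerance = 1e-12)
  # fully diagnostic alleles put all mass on the only compatible origin
  datd <- toy_dataset(K = 2, N = 2, L = 1, A = 2)
  datd$a1[, 1] <- 1L; datd$a2[, 1] <- 1L
  pard <- genetic_params(list(rbind(c(1 - 1e-12, 1e-12), c(1e-12, 1 - 1e-12))))
  tabd <- origin_conditional(1, c(0.5, 0.5),
                             matrix(0.5, 2, 2), pard, datd)
  expect_gt(tabd[1, 1], 0.999)
})

test_that("marginal likelihood is invariant to allele relabeling and locus order", {
  dat <- toy_dataset(K = 2, N = 5, L = 4, A = 3)
  par <- toy_params(dat, F_i = 0.15, eps = 0.07)
  alpha <- rbind(c(0.7, 0.3), c(0.4, 0.6))
  beta <- rbind(c(0.8, 0.2), c(0.1, 0.9))
  base <- marginal_lik(3, alpha[dat$pop[3], ], beta, par, dat)
  # relabel alleles at locus 2 with a permutation
  perm <- c(3L, 1L, 2L)
  dat2 <- dat
  dat2$a1[, 2] <- perm[dat$a1[, 2]]; dat2$a2[, 2] <- perm[dat$a2[, 2]]
  swap <- dat2$a1[, 2] > dat2$a2[, 2]
  tmp <- dat2$a1[swap, 2]; dat2$a1[swap, 2] <- dat2$a2[swap, 2]
  dat2$a2[swap, 2] <- tmp
  par2 <- par
  par2$p[[2]] <- par$p[[2]][, order(perm)]
  expect_equal(marginal_lik(3, alpha[dat$pop[3], ], beta, par2, dat2), base)
  # permute locus order
  ord <- c(4, 2, 1, 3)
  dat3 <- dat
  dat3$a1 <- dat$a1[, ord]; dat3$a2 <- dat$a2[, ord]
  dat3$allele_counts <- dat$allele_counts[ord]
  par3 <- par
  par3$p <- par$p[ord]; par3$dropout <- par$dropout[ord]
  expect_equal(marginal_lik(3, alpha[dat$pop[3], ], beta, par3, dat3), base)
})

test_that("an individual incompatible with every origin raises an error", {
  dat <- toy_dataset(K = 2, N = 2, L = 1, A = 2)
  dat$a1[1, 1] <- 2L; dat$a2[1, 1] <- 2L
  par <- genetic_params(list(rbind(c(1, 0), c(1, 0))))
  expect_error(marginal_lik(1, c(0.5, 0.5), matrix(0.5, 2, 2), par, dat),
               "incompatible with every origin")
})

test_that("the compiled likelihood table agrees with the reference implementation", {
  set.seed(7)
  dat <- toy_dataset(K = 3, N = 10, L = 4, A = 4, missing = 5)
  par <- toy_params(dat, F_i = 0, eps = 0)
  par$f_ind <- runif(dat$n, 0, 0.5)
  par$dropout <- runif(dat$L, 0, 0.3)
  tab <- ns$loglik_table(dat, par)
  for (i in c(1, 5, 10)) for (j in 1:3) for (k in 1:3) {
    expect_equal(tab[i, (j - 1) * 3 + k],
                 individual_lik(i, j, k, par, dat), tolerance = 1e-12)
  }
})
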