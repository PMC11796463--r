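# Shared fixture builders and the joint-distribution (Geweke-style) test
# machinery. Everything is generated in code; no stored fixtures.

ns <- asNamespace("spmig")

# Random valid frequency matrix (K x A) with interior entries.
rand_p <- function(K, A) {
  m <- matrix(rgamma(K * A, 1) + 0.05, K, A)
  m / rowSums(m)
}

# Small genotype dataset with known shapes; optionally some missing loci.
toy_dataset <- function(K = 2, N = 8, L = 3, A = 3, missing = 0,
                        seed = 1) {
  set.seed(seed)
  a1 <- matrix(sample.int(A, N * L, replace = TRUE), N, L)
  a2 <- matrix(sample.int(A, N * L, replace = TRUE), N, L)
  if (missing > 0) {
    idx <- sample(N * L, missing)
    a1[idx] <- NA; a2[idx] <- NA
  }
  pop <- rep_len(seq_len(K), N)
  genotype_data(a1, a2, pop, allele_counts = rep(A, L),
                pop_levels = as.character(seq_len(K)))
}

toy_params <- function(data, F_i = 0, eps = 0, seed = 2) {
  set.seed(seed)
  p <- lapply(seq_len(data$L), function(l) rand_p(data$K, data$allele_counts[l]))
  genetic_params(p, f_ind = rep(F_i, data$n), dropout = rep(eps, data$L))
}

# -- joint-distribution validation (forward vs successive-conditional) --------

geweke_forward_draw <- function(K, L, N, A, pop, lam = 2 / 3) {
  st <- list(tau_a = runif(1), gam_a = runif(1), b_a = 0, ind_a = 0L,
             tau_b = runif(1), gam_b = runif(1), b_b = 0, ind_b = 0L,
             mu_fst = runif(1), mu_f = runif(1), gam_f = runif(1),
             loglik = NA_real_)
  st$fst <- ns$rtgamma(K, st$mu_fst)
  st$q <- lapply(seq_len(L), function(l) ns$rdirichlet_one(rep(1, A)))
  st$p <- lapply(seq_len(L), function(l) t(sapply(seq_len(K), function(j)
    ns$rdirichlet_one(st$q[[l]] * (1 - st$fst[j]) / st$fst[j]))))
  st$Fi <- ns$rbeta_md_trunc(N, st$mu_f, st$gam_f)
  st$eps <- ns$reps_prior(L)
  pia <- ns$pi_matrix(lam, st$tau_a, 0, NULL, K)
  pib <- ns$pi_matrix(lam, st$tau_b, 0, NULL, K)
  st$alpha <- t(sapply(seq_len(K), function(i)
    ns$rdirichlet_one(dirichlet_concentration(pia[i, ], st$gam_a))))
  st$beta <- t(sapply(seq_len(K), function(i)
    ns$rdirichlet_one(dirichlet_concentration(pib[i, ], st$gam_b))))
  st$jm <- integer(N); st$jp <- integer(N)
  for (i in seq_len(N)) {
    st$jm[i] <- sample.int(K, 1, prob = st$alpha[pop[i], ])
    st$jp[i] <- sample.int(K, 1, prob = st$beta[st$jm[i], ])
  }
  st
}

geweke_stats <- function(st) {
  c(tau_a = st$tau_a, gam_a = st$gam_a, tau_b = st$tau_b, gam_b = st$gam_b,
    mu_fst = st$mu_fst, mu_f = st$mu_f, gam_f = st$gam_f,
    a12 = st$alpha[1, 2], b21 = st$beta[2, 1], fst1 = st$fst[1],
    Fbar = mean(st$Fi), eps1 = st$eps[1])
}

# Runs both simulations and returns mean differences (successive - forward).
geweke_compare <- function(Tn = 2500, sweeps = 2, K = 2L, L = 2L, N = 10L,
                           A = 2L) {
  pop <- rep_len(seq_len(K), N)
  fwd <- matrix(NA_real_, Tn, 12)
  for (t in seq_len(Tn)) {
    fwd[t, ] <- geweke_stats(geweke_forward_draw(K, L, N, A, pop))
  }
  ctl <- spmig_control(cycles = sweeps, burnin = 0, thin = sweeps,
                       estimate_b = FALSE, adapt = FALSE)
  st <- geweke_forward_draw(K, L, N, A, pop)
  sc <- matrix(NA_real_, Tn, 12)
  for (t in seq_len(Tn)) {
    g <- ns$draw_genotypes_given_origins(st$jm, st$jp, st$p, st$Fi, st$eps,
                                         rep(A, L))
    dat <- genotype_data(g$a1, g$a2, pop, allele_counts = rep(A, L),
                         pop_levels = as.character(seq_len(K)))
    st <- run_chain(dat, control = ctl, state0 = st)$state
    sc[t, ] <- geweke_stats(st)
  }
  nm <- names(geweke_stats(st))
  list(fwd = setNames(colMeans(fwd), nm), sc = setNames(colMeans(sc), nm),
       diff = setNames(colMeans(sc) - colMeans(fwd), nm))
}
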