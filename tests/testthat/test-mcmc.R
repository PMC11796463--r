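# Sampler correctness: conjugate updates, stationarity of the scalar moves,
# reproducibility, prior recovery, and reversible-jump behaviour.

test_that("conjugate migration-row update matches the closed form", {
  set.seed(5)
  # counts (10, 0) with unit prior concentrations: posterior Beta(11, 1)
  pi_mat <- matrix(0.5, 2, 2)
  gam <- 1 / 3  # (1 - gamma)/gamma = 2 -> a = (1, 1)
  counts <- rbind(c(10, 0), c(0, 0))
  draws <- replicate(20000, gibbs_migration_rows(counts, pi_mat, gam)[1, 1])
  expect_equal(mean(draws), 11 / 12, tolerance = 0.005)
  # zero counts draw from the prior
  draws0 <- replicate(20000, gibbs_migration_rows(counts * 0, pi_mat, gam)[1, 1])
  expect_equal(mean(draws0), 0.5, tolerance = 0.01)
  # huge counts pin the posterior at the empirical proportions
  big <- rbind(c(9000, 1000), c(5000, 5000))
  drawsb <- gibbs_migration_rows(big, pi_mat, gam)
  expect_equal(drawsb[1, 1], 0.9, tolerance = 0.02)
})

test_that("origin Gibbs sampling frequencies match the conditional table", {
  set.seed(6)
  dat <- toy_dataset(K = 2, N = 3, L = 2, A = 3)
  par <- toy_params(dat, F_i = 0.1, eps = 0.05)
  alpha <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  beta <- rbind(c(0.6, 0.4), c(0.3, 0.7))
  want <- origin_conditional(2, alpha[dat$pop[2], ], beta, par, dat)
  hits <- matrix(0, 2, 2)
  for (r in 1:20000) {
    o <- gibbs_origins(alpha, beta, par, dat)
    hits[o$maternal[2], o$paternal[2]] <- hits[o$maternal[2], o$paternal[2]] + 1
  }
  expect_equal(hits / sum(hits), want, tolerance = 0.02)
})

test_that("scalar Metropolis moves leave a known density invariant", {
  set.seed(8)
  # target Beta(2, 5); alternate logit random walk and uniform independence
  tgt <- function(x) dbeta(x, 2, 5, log = TRUE)
  x <- 0.5; kept <- numeric(30000)
  for (t in seq_along(kept)) {
    r <- if (t %% 2 == 0) ns$mh_logit(x, tgt, 1) else
      ns$mh_prior_indep(x, tgt, function() runif(1))
    x <- r$value; kept[t] <- x
  }
  expect_equal(mean(kept), 2 / 7, tolerance = 0.01)
  expect_equal(var(kept), 2 * 5 / (49 * 8), tolerance = 0.002)
})

test_that("chains are exactly reproducible from the seed", {
  sc <- scenario_config(K = 2, N = 12, assay = "custom", L = 3, alleles = 3,
                        mu_fst = 0.3)
  sim <- simulate_scenario(sc, seed = 9)
  ctl <- spmig_control(cycles = 120, burnin = 40, thin = 2)
  t1 <- run_chain(sim$data, control = ctl, seed = 77)
  t2 <- run_chain(sim$data, control = ctl, seed = 77)
  expect_identical(t1$scalars, t2$scalars)
  expect_identical(t1$alpha, t2$alpha)
  expect_identical(t1$eps, t2$eps)
  t3 <- run_chain(sim$data, control = ctl, seed = 78)
  expect_false(identical(t1$scalars, t3$scalars))
})

test_that("every retained state has a finite complete-data log likelihood", {
  sc <- scenario_config(K = 3, N = 24, assay = "custom", L = 4, alleles = 4,
                        mu_fst = 0.2, dropout = 0.1)
  sim <- simulate_scenario(sc, seed = 10)
  tr <- run_chain(sim$data, control = spmig_control(cycles = 300, burnin = 100,
                                                    thin = 2), seed = 11)
  expect_true(all(is.finite(tr$scalars[, "loglik"])))
  expect_true(all(abs(apply(tr$alpha, c(1, 2), sum) - 1) < 1e-9))
})

test_that("with uninformative data every parameter recovers its prior", {
  dat <- toy_dataset(K = 2, N = 4, L = 2, A = 2)
  dat$a1[] <- NA; dat$a2[] <- NA
  ctl <- spmig_control(cycles = 16000, burnin = 1000, thin = 2)
  tr <- run_chain(dat, control = ctl, seed = 12)
  sc <- tr$scalars
  # uniform hyperpriors
  expect_lt(abs(mean(sc[, "tau_seed"]) - 0.5), 0.04)
  expect_lt(abs(mean(sc[, "gamma_seed"]) - 0.5), 0.04)
  expect_lt(abs(mean(sc[, "tau_pollen"]) - 0.5), 0.04)
  expect_lt(abs(mean(sc[, "mu_fst"]) - 0.5), 0.04)
  expect_lt(abs(mean(sc[, "mu_f"]) - 0.5), 0.04)
  # E[alpha_ii] = lambda + (1 - lambda) E[tau] = 2/3 + 1/3 * 0.5 = 5/6,
  # E[alpha_12] = (1 - lambda) E[1 - tau] = 1/6 at K = 2
  expect_lt(abs(mean(tr$alpha[, 1, 1]) - 5 / 6), 0.025)
  expect_lt(abs(mean(tr$alpha[, 1, 2]) - 1 / 6), 0.025)
  # dropout prior is symmetric around 0.5
  expect_lt(abs(mean(tr$eps) - 0.5), 0.06)
  # F_i ~ Beta(mu_F, gamma_F) marginalized over uniform hyperpriors: mean 0.5
  expect_lt(abs(mean(tr$F_mean) - 0.5), 0.06)
})

test_that("forward and successive-conditional simulations agree (joint distribution test)", {
  set.seed(13)
  g <- geweke_compare(Tn = 2500, sweeps = 2)
  # uniform-hyperprior parameters: forward means are near 0.5
  for (nm in c("tau_a", "gam_a", "tau_b", "gam_b", "mu_fst", "mu_f",
               "gam_f")) {
    expect_lt(abs(g$diff[nm]), 0.1)
  }
  expect_lt(abs(g$diff["a12"]), 0.08)
  expect_lt(abs(g$diff["b21"]), 0.08)
  expect_lt(abs(g$diff["Fbar"]), 0.1)
  expect_lt(abs(g$diff["eps1"]), 0.12)
  expect_lt(abs(g$diff["fst1"]), 0.15)
})

test_that("reversible jump recovers the prior model probability under a flat likelihood", {
  dat <- toy_dataset(K = 3, N = 6, L = 2, A = 2)
  dat$a1[] <- NA; dat$a2[] <- NA
  ly <- spatial_layout(coords = cbind(c(0, 3, 7), c(0, 2, 1)))
  # a tight b prior keeps between-model jumps frequent, so the visit
  # fraction estimates the (exact) 0.5 prior probability with useful ESS
  ctl <- spmig_control(cycles = 16000, burnin = 1000, thin = 2,
                       b_prior_sd = 2)
  tr <- run_chain(dat, layout = ly, control = ctl, seed = 14)
  expect_lt(abs(mean(tr$scalars[, "model_seed"]) - 0.5), 0.07)
  expect_lt(abs(mean(tr$scalars[, "model_pollen"]) - 0.5), 0.07)
})

test_that("the long-run default protocol retains 2000 samples", {
  ctl <- spmig_control()
  expect_equal((ctl$cycles - ctl$burnin) %/% ctl$thin, 2000L)
  # retained-count invariant on an actual short run
  sc <- scenario_config(K = 2, N = 8, assay = "custom", L = 2, alleles = 2,
                        mu_fst = 0.3)
  sim <- simulate_scenario(sc, seed = 15)
  tr <- run_chain(sim$data, control = spmig_control(cycles = 130, burnin = 50,
                                                    thin = 4), seed = 16)
  expect_equal(tr$retained, 20L)
  expect_equal(nrow(tr$scalars), 20L)
})

test_that("posterior summaries compute means, SEs and shortest HPDIs", {
  # HPDI of a standard normal sample
  set.seed(17)
  x <- rnorm(50000)
  h <- hpdi(x, 0.95)
  expect_equal(h[1], -1.96, tolerance = 0.05)
  expect_equal(h[2], 1.96, tolerance = 0.05)
  # constant trace: zero-width interval
  expect_equal(hpdi(rep(3.3, 100)), c(3.3, 3.3))
  # shortest-window definition on a skewed toy sample
  y <- c(rep(0.1, 90), seq(5, 50, length.out = 10))
  h2 <- hpdi(y, 0.9)
  expect_equal(h2[1], 0.1)
  expect_lt(h2[2], 10)
  expect_error(hpdi(numeric(0)), "empty")
})
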