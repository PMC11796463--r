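# Scenario simulator: generative draws match the model's statistical
# structure and the published scenario settings.

test_that("population genetics draws follow the F-model", {
  cfg <- scenario_config(K = 4, N = 40, assay = "custom", L = 3, alleles = 4,
                         mu_fst = 0.1, gamma_fst = 0.01)
  g <- draw_population_genetics(cfg, seed = 21)
  expect_length(g$q, 3)
  expect_equal(dim(g$p[[1]]), c(4, 4))
  for (l in 1:3) {
    expect_equal(rowSums(g$p[[l]]), rep(1, 4), tolerance = 1e-12)
    expect_equal(sum(g$q[[l]]), 1, tolerance = 1e-12)
  }
  # weak divergence limit: p approximately q
  cfg0 <- scenario_config(K = 3, N = 30, assay = "custom", L = 2, alleles = 3,
                          mu_fst = 0.002, gamma_fst = 5e-4)
  g0 <- draw_population_genetics(cfg0, seed = 22)
  for (l in 1:2) {
    expect_lt(mean(abs(sweep(g0$p[[l]], 2, g0$q[[l]]))), 0.03)
  }
  # moment oracle for the divergence distribution
  set.seed(23)
  fst <- replicate(3000, draw_population_genetics(cfg)$fst)
  expect_equal(mean(fst), 0.1, tolerance = 0.005)
  # reproducibility
  expect_identical(draw_population_genetics(cfg, seed = 21),
                   draw_population_genetics(cfg, seed = 21))
})

test_that("migration draws reproduce the published prior means", {
  cfg10 <- scenario_config(K = 10, N = 100)
  set.seed(24)
  off <- replicate(400, {
    a <- draw_migration(cfg10)$alpha
    mean(a[row(a) != col(a)])
  })
  expect_lt(abs(mean(off) - 0.25 / 9), 0.0015)
  cfg20 <- scenario_config(K = 20, N = 100)
  off20 <- replicate(400, {
    a <- draw_migration(cfg20)$alpha
    mean(a[row(a) != col(a)])
  })
  expect_lt(abs(mean(off20) - 0.25 / 19), 0.001)
  # complete isolation
  cfgI <- scenario_config(K = 5, N = 10, tau_seed = 1 - 1e-12,
                          tau_pollen = 1 - 1e-12)
  expect_equal(draw_migration(cfgI, seed = 25)$alpha, diag(5),
               tolerance = 1e-6)
})

test_that("genotype generation respects inbreeding and dropout limits", {
  p <- lapply(1:6, function(l) rand_p(2, 4))
  # full inbreeding with same-source parents: every locus homozygous
  g <- draw_origins_and_genotypes(rep(1, 30), matrix(c(1, 0, 0, 1), 2),
                                  diag(2), p, f_ind = 1, dropout = 0,
                                  seed = 26)
  expect_true(all(g$a1 == g$a2))
  # complete dropout: no observed heterozygotes
  g2 <- draw_origins_and_genotypes(rep(1:2, 15), matrix(0.5, 2, 2),
                                   matrix(0.5, 2, 2), p, f_ind = 0,
                                   dropout = 1, seed = 27)
  expect_true(all(g2$a1 == g2$a2))
  # origin frequencies match alpha and beta (multinomial oracle)
  alpha <- rbind(c(0.6, 0.4), c(0.1, 0.9))
  beta <- rbind(c(0.8, 0.2), c(0.35, 0.65))
  set.seed(28)
  g3 <- draw_origins_and_genotypes(rep(1, 40000), alpha, beta,
                                   p[1], f_ind = 0, dropout = 0)
  expect_equal(mean(g3$maternal == 1), 0.6, tolerance = 0.01)
  expect_equal(mean(g3$paternal[g3$maternal == 1] == 1), 0.8,
               tolerance = 0.01)
  expect_equal(mean(g3$paternal[g3$maternal == 2] == 1), 0.35,
               tolerance = 0.015)
})

test_that("assay presets give the published genotyping designs", {
  sim <- simulate_scenario(scenario_config(K = 2, N = 6, assay = "SSR",
                                           mu_fst = 0.2), seed = 29)
  expect_s3_class(sim$data, "genotype_data")
  expect_equal(sim$data$L, 20L)
  expect_equal(unique(sim$data$allele_counts), 6L)
  sim2 <- simulate_scenario(scenario_config(K = 2, N = 4, assay = "SNP",
                                            mu_fst = 0.2), seed = 30)
  expect_equal(sim2$data$L, 1000L)
  expect_equal(unique(sim2$data$allele_counts), 2L)
  # sample sizes split equally with the remainder spread deterministically
  sim3 <- simulate_scenario(scenario_config(K = 3, N = 11, assay = "custom",
                                            L = 2, alleles = 2,
                                            mu_fst = 0.2), seed = 31)
  expect_equal(tabulate(sim3$data$pop), c(4L, 4L, 3L))
  # ideal mode carries origins only
  simI <- simulate_scenario(scenario_config(K = 4, N = 20, ideal = TRUE),
                            seed = 32)
  expect_s3_class(simI$data, "origin_data")
  expect_null(simI$data$a1)
})

test_that("realized genetic differentiation increases with the simulated mean", {
  # crude multi-allele FST estimate: 1 - Hs/Ht on realized genotype counts
  fst_hat <- function(data) {
    hs <- 0; ht <- 0
    for (l in seq_len(data$L)) {
      tots <- matrix(0, data$K, data$allele_counts[l])
      for (i in seq_len(data$n)) {
        s <- data$pop[i]
        tots[s, data$a1[i, l]] <- tots[s, data$a1[i, l]] + 1
        tots[s, data$a2[i, l]] <- tots[s, data$a2[i, l]] + 1
      }
      pj <- tots / rowSums(tots)
      pbar <- colSums(tots) / sum(tots)
      hs <- hs + mean(1 - rowSums(pj^2))
      ht <- ht + (1 - sum(pbar^2))
    }
    1 - hs / ht
  }
  vals <- vapply(c(0.025, 0.2), function(mf) {
    mean(vapply(1:4, function(r) {
      sim <- simulate_scenario(scenario_config(K = 5, N = 100,
                                               assay = "custom", L = 10,
                                               alleles = 4, mu_fst = mf),
                               seed = 33 + r)
      fst_hat(sim$data)
    }, 0))
  }, 0)
  expect_lt(vals[1], vals[2])
})

test_that("a strong distance effect shortens realized migration distances", {
  ly <- yew_layout()
  mean_migrant_dist <- function(b, seed) {
    cfg <- scenario_config(K = 9, N = 3000, ideal = TRUE, b_seed = b,
                           b_pollen = b, layout = ly)
    sim <- simulate_scenario(cfg, seed = seed)
    mig <- sim$truth$maternal != sim$data$pop
    mean(ly$dist[cbind(sim$data$pop[mig], sim$truth$maternal[mig])])
  }
  d_strong <- mean(vapply(1:3, function(r) mean_migrant_dist(2.1274, 40 + r), 0))
  d_null <- mean(vapply(1:3, function(r) mean_migrant_dist(0, 50 + r), 0))
  expect_lt(d_strong, d_null)
})
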