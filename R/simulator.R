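#' Scenario configuration for the simulator
#'
#' Describes one synthetic study: K populations with N individuals sampled
#' in total (split equally, remainder assigned to the first populations),
#' genotyped with either an SSR-type assay (20 loci x 6 alleles), an
#' SNP-type assay (1,000 biallelic loci), or a custom assay. Population
#' allele frequencies follow the F-model around flat-Dirichlet ancestral
#' frequencies with Beta-distributed divergence (mean `mu_fst`, dispersion
#' `gamma_fst`); migration matrices are drawn from the same competing-sources
#' Dirichlet prior used in inference.
#'
#' @param K number of populations.
#' @param N total number of sampled individuals.
#' @param assay `"SSR"`, `"SNP"` or `"custom"`.
#' @param L,alleles loci count and alleles per locus (custom assay only).
#' @param mu_fst,gamma_fst mean and dispersion of population divergence.
#' @param mu_f,gamma_f mean and dispersion of individual inbreeding
#'   (`mu_f = 0` means no inbreeding).
#' @param dropout per-locus allelic dropout rate(s) applied to simulated
#'   heterozygotes (recycled across loci).
#' @param lambda_seed,lambda_pollen,tau_seed,tau_pollen,gamma_seed,gamma_pollen
#'   migration-prior parameters for the two channels.
#' @param b_seed,b_pollen distance-effect scales (need a `layout` if
#'   nonzero).
#' @param layout optional [spatial_layout()].
#' @param ideal if `TRUE`, the scenario records true origins only (no
#'   genotypes) — the categorical-discrimination benchmark.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(K = 10, N = 500, assay = c("SSR", "SNP", "custom"),
                            L = 20, alleles = 6,
                            mu_fst = 0.1, gamma_fst = 0.01,
                            mu_f = 0, gamma_f = 0.1, dropout = 0,
                            lambda_seed = 2 / 3, lambda_pollen = 2 / 3,
                            tau_seed = 0.25, tau_pollen = 0.25,
                            gamma_seed = 0.1, gamma_pollen = 0.1,
                            b_seed = 0, b_pollen = 0,
                            layout = NULL, ideal = FALSE) {
  assay <- match.arg(assay)
  if (assay == "SSR") { L <- 20L; alleles <- 6L }
  if (assay == "SNP") { L <- 1000L; alleles <- 2L }
  if ((b_seed != 0 || b_pollen != 0) && is.null(layout)) {
    stop("distance effects need a spatial layout")
  }
  if (!is.null(layout) && layout$K != K) stop("layout and K disagree")
  stopifnot(K >= 1, N >= 1, L >= 1, alleles >= 2,
            mu_fst > 0, mu_fst < 1, mu_f >= 0, mu_f < 1)
  structure(list(K = as.integer(K), N = as.integer(N), assay = assay,
                 L = as.integer(L), alleles = as.integer(alleles),
                 mu_fst = mu_fst, gamma_fst = gamma_fst,
                 mu_f = mu_f, gamma_f = gamma_f,
                 dropout = rep_len(dropout, L),
                 lambda_seed = lambda_seed, lambda_pollen = lambda_pollen,
                 tau_seed = tau_seed, tau_pollen = tau_pollen,
                 gamma_seed = gamma_seed, gamma_pollen = gamma_pollen,
                 b_seed = b_seed, b_pollen = b_pollen,
                 layout = layout, ideal = isTRUE(ideal)),
            class = "scenario_config")
}

# Equal split of N over K with the remainder on the first populations.
sample_sizes <- function(N, K) {
  base <- N %/% K
  out <- rep(base, K)
  r <- N - base * K
  if (r > 0) out[seq_len(r)] <- out[seq_len(r)] + 1L
  out
}

#' Draw population genetic structure
#'
#' Ancestral frequencies `q_l` from a flat Dirichlet, per-population
#' divergence `FST_j` from Beta(mean `mu_fst`, dispersion `gamma_fst`), and
#' population frequencies `p_jl` from the F-model Dirichlet
#' `Dir(q_l (1-FST_j)/FST_j)`.
#'
#' @param cfg a [scenario_config()].
#' @param seed optional RNG seed.
#' @return list with `q` (list), `fst` (vector), `p` (list of `K x A`
#'   matrices).
#' @export
draw_population_genetics <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- cfg$K; L <- cfg$L; A <- cfg$alleles
  fst <- rbeta_md(K, cfg$mu_fst, cfg$gamma_fst)
  fst <- pmin(pmax(fst, 1e-6), 1 - 1e-6)
  q <- vector("list", L); p <- vector("list", L)
  for (l in seq_len(L)) {
    q[[l]] <- rdirichlet_one(rep(1, A))
    p[[l]] <- t(vapply(seq_len(K), function(j) {
      rdirichlet_one(q[[l]] * (1 - fst[j]) / fst[j])
    }, numeric(A)))
  }
  list(q = q, fst = fst, p = p)
}

#' Draw migration matrices from the prior
#'
#' Rows of the seed and pollen migration matrices from the
#' competing-sources Dirichlet prior at the scenario's hyperparameter
#' values.
#'
#' @param cfg a [scenario_config()].
#' @param seed optional RNG seed.
#' @return list with row-stochastic `alpha` and `beta`.
#' @export
draw_migration <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- cfg$K
  D <- if (!is.null(cfg$layout)) cfg$layout$dist else NULL
  pia <- pi_matrix(cfg$lambda_seed, cfg$tau_seed, cfg$b_seed, D, K)
  pib <- pi_matrix(cfg$lambda_pollen, cfg$tau_pollen, cfg$b_pollen, D, K)
  alpha <- t(vapply(seq_len(K), function(i) {
    rdirichlet_one(dirichlet_concentration(pia[i, ], cfg$gamma_seed))
  }, numeric(K)))
  beta <- t(vapply(seq_len(K), function(i) {
    rdirichlet_one(dirichlet_concentration(pib[i, ], cfg$gamma_pollen))
  }, numeric(K)))
  list(alpha = alpha, beta = beta)
}

#' Draw origins and genotypes
#'
#' For each individual sampled in population `s`: a maternal source `j` from
#' `alpha[s, ]`, a paternal source `k` from `beta[j, ]`; then per locus a
#' maternal allele from `p_j` and a paternal allele from `p_k`, with the
#' paternal copy replaced by the maternal one (identity by descent) with
#' probability `F_i` when `j == k`; finally a true heterozygote is scored as
#' either homozygote with probability `dropout_l` (split evenly).
#'
#' @param pop sampling population per individual.
#' @param alpha,beta migration matrices.
#' @param p list of `K x A_l` frequency matrices.
#' @param f_ind per-individual inbreeding coefficients (recycled).
#' @param dropout per-locus dropout rates (recycled).
#' @param allele_counts alleles per locus.
#' @param seed optional RNG seed.
#' @return list with `maternal`, `paternal`, `a1`, `a2`.
#' @export
draw_origins_and_genotypes <- function(pop, alpha, beta, p, f_ind = 0,
                                       dropout = 0, allele_counts = NULL,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(pop); K <- nrow(alpha); L <- length(p)
  f_ind <- rep_len(f_ind, n); dropout <- rep_len(dropout, L)
  if (is.null(allele_counts)) allele_counts <- vapply(p, ncol, 0L)
  jm <- integer(n); jp <- integer(n)
  for (i in seq_len(n)) {
    jm[i] <- sample.int(K, 1, prob = alpha[pop[i], ])
    jp[i] <- sample.int(K, 1, prob = beta[jm[i], ])
  }
  g <- draw_genotypes_given_origins(jm, jp, p, f_ind, dropout, allele_counts)
  list(maternal = jm, paternal = jp, a1 = g$a1, a2 = g$a2)
}

# Genotypes conditional on known parental origins (also used to regenerate
# data in joint-distribution validation).
draw_genotypes_given_origins <- function(jm, jp, p, f_ind, dropout,
                                         allele_counts) {
  n <- length(jm); L <- length(p)
  f_ind <- rep_len(f_ind, n); dropout <- rep_len(dropout, L)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    pl <- p[[l]]; A <- allele_counts[l]
    for (i in seq_len(n)) {
      am <- sample.int(A, 1, prob = pl[jm[i], ])
      ap <- if (jm[i] == jp[i] && f_ind[i] > 0 && runif(1) < f_ind[i]) {
        am                                   # identical by descent
      } else {
        sample.int(A, 1, prob = pl[jp[i], ])
      }
      if (am != ap && dropout[l] > 0 && runif(1) < dropout[l]) {
        keep <- if (runif(1) < 0.5) am else ap
        am <- keep; ap <- keep
      }
      a1[i, l] <- min(am, ap); a2[i, l] <- max(am, ap)
    }
  }
  list(a1 = a1, a2 = a2)
}

#' Simulate a full scenario
#'
#' Assembles one replicate dataset: population genetics, migration matrices,
#' origins, genotypes (unless `ideal`), and the truth snapshot used by the
#' evaluation harness.
#'
#' @param cfg a [scenario_config()].
#' @param seed RNG seed; the draw is fully reproducible from `(cfg, seed)`.
#' @return list with `data` (a [genotype_data()] or [origin_data()]) and
#'   `truth` (realized `alpha`, `beta`, `p`, `q`, `fst`, `f_ind`, `dropout`,
#'   `maternal`, `paternal`).
#' @export
simulate_scenario <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- cfg$K; N <- cfg$N
  pop <- rep(seq_len(K), sample_sizes(N, K))
  mig <- draw_migration(cfg)
  if (cfg$ideal) {
    jm <- integer(N); jp <- integer(N)
    for (i in seq_len(N)) {
      jm[i] <- sample.int(K, 1, prob = mig$alpha[pop[i], ])
      jp[i] <- sample.int(K, 1, prob = mig$beta[jm[i], ])
    }
    truth <- c(mig, list(maternal = jm, paternal = jp))
    return(list(data = origin_data(pop, jm, jp, K), truth = truth))
  }
  gen <- draw_population_genetics(cfg)
  f_ind <- if (cfg$mu_f > 0) rbeta_md(N, cfg$mu_f, cfg$gamma_f) else
    rep(0, N)
  dg <- draw_origins_and_genotypes(pop, mig$alpha, mig$beta, gen$p,
                                   f_ind = f_ind, dropout = cfg$dropout,
                                   allele_counts = rep(cfg$alleles, cfg$L))
  data <- genotype_data(dg$a1, dg$a2, pop,
                        allele_counts = rep(cfg$alleles, cfg$L),
                        pop_levels = as.character(seq_len(K)))
  truth <- c(mig, gen,
             list(f_ind = f_ind, dropout = cfg$dropout,
                  maternal = dg$maternal, paternal = dg$paternal))
  list(data = data, truth = truth)
}
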