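#' MCMC run configuration
#'
#' Collects every tunable of a sampler run. The defaults reproduce the
#' standard long-run protocol: 10,000 burn-in cycles followed by 20,000
#' sampling cycles thinned to every 10th, yielding 2,000 retained samples.
#'
#' @param cycles total MCMC cycles including burn-in.
#' @param burnin burn-in cycles (discarded; proposal scales adapt here and
#'   are frozen afterwards).
#' @param thin keep every `thin`-th post-burn-in cycle.
#' @param lambda_seed,lambda_pollen fixed prior probabilities of local seed
#'   and pollen dispersal, in (0,1).
#' @param estimate_F estimate individual inbreeding coefficients? If `FALSE`
#'   all `F_i` are fixed at 0.
#' @param estimate_dropout estimate per-locus allelic dropout rates? If
#'   `FALSE` all `eps_l` are fixed at 0.
#' @param estimate_b reversible-jump estimation of the distance-effect
#'   scales `b`? Requires a spatial layout; if `FALSE`, `b` is fixed at 0
#'   (spatially uniform migration priors).
#' @param b_prior_sd standard deviation of the Normal(0, sd^2) prior on the
#'   distance-effect scales (default 10, i.e. variance 100).
#' @param d_max kernel truncation distance in km for reporting migration
#'   distance kernels; defaults to the maximum interpopulation distance,
#'   rounded up.
#' @param hpdi_prob mass of reported highest posterior density intervals.
#' @param adapt adapt proposal scales during burn-in?
#' @param verbose print cycle progress to stderr?
#' @return object of class `spmig_control`.
#' @export
spmig_control <- function(cycles = 30000, burnin = 10000, thin = 10,
                          lambda_seed = 2 / 3, lambda_pollen = 2 / 3,
                          estimate_F = TRUE, estimate_dropout = TRUE,
                          estimate_b = TRUE, b_prior_sd = 10,
                          d_max = NULL, hpdi_prob = 0.95,
                          adapt = TRUE, verbose = FALSE) {
  stopifnot(cycles > burnin, burnin >= 0, thin >= 1,
            lambda_seed > 0, lambda_seed < 1,
            lambda_pollen > 0, lambda_pollen < 1,
            b_prior_sd > 0, hpdi_prob > 0, hpdi_prob < 1)
  structure(list(cycles = as.integer(cycles), burnin = as.integer(burnin),
                 thin = as.integer(thin),
                 lambda_seed = lambda_seed, lambda_pollen = lambda_pollen,
                 estimate_F = isTRUE(estimate_F),
                 estimate_dropout = isTRUE(estimate_dropout),
                 estimate_b = isTRUE(estimate_b),
                 b_prior_sd = b_prior_sd, d_max = d_max,
                 hpdi_prob = hpdi_prob, adapt = isTRUE(adapt),
                 verbose = isTRUE(verbose)),
            class = "spmig_control")
}

#' Observed-origin dataset (ideal categorical discrimination)
#'
#' Benchmark data object for the case where the maternal and paternal source
#' populations of every sampled individual are known exactly, so migration
#' rates are estimated from origin counts alone (no genotypes).
#'
#' @param s sampling population index per individual.
#' @param maternal,paternal known source population indices per individual.
#' @param K number of populations.
#' @return object of class `origin_data`.
#' @export
origin_data <- function(s, maternal, paternal, K) {
  n <- length(s)
  stopifnot(length(maternal) == n, length(paternal) == n,
            all(s >= 1 & s <= K), all(maternal >= 1 & maternal <= K),
            all(paternal >= 1 & paternal <= K))
  structure(list(n = n, K = as.integer(K), pop = as.integer(s),
                 jm = as.integer(maternal), jp = as.integer(paternal)),
            class = "origin_data")
}
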