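#' Bias and RMSE of pooled estimates
#'
#' Pools estimate/truth pairs (e.g. all off-diagonal migration entries
#' across replicates) into a single bias `mean(est - truth)` and
#' `rmse = sqrt(mean((est - truth)^2))`.
#'
#' @param estimates,truths numeric vectors/matrices (or lists of them) of
#'   identical shape.
#' @return named numeric vector `c(bias, rmse)`.
#' @export
bias_rmse <- function(estimates, truths) {
  if (is.list(estimates)) estimates <- unlist(estimates)
  if (is.list(truths)) truths <- unlist(truths)
  if (length(estimates) != length(truths)) stop("shape mismatch")
  if (length(estimates) == 0) stop("no replicates")
  d <- as.numeric(estimates) - as.numeric(truths)
  c(bias = mean(d), rmse = sqrt(mean(d^2)))
}

#' Model-selection rate across replicates
#'
#' A replicate counts as selecting the distance-effect model when its
#' posterior model probability exceeds the criterion (majority visit
#' fraction, 0.5, by default).
#'
#' @param pr vector of per-replicate posterior probabilities `Pr(b > 0)`.
#' @param criterion selection threshold.
#' @return list with `n_pos` (count selected) and `mean_pr`.
#' @export
selection_rate <- function(pr, criterion = 0.5) {
  list(n_pos = sum(pr > criterion), mean_pr = mean(pr))
}

off_diag <- function(m) m[row(m) != col(m)]

#' Replicated simulate-estimate-evaluate benchmark
#'
#' Runs `reps` independent replicates of a scenario: simulate a dataset,
#' fit the model, and pool estimation errors. Off-diagonal migration
#' entries are pooled across replicates and population pairs into a single
#' bias/RMSE per scenario.
#'
#' @param cfg a [scenario_config()].
#' @param reps number of replicates.
#' @param control a [spmig_control()] for the fits.
#' @param seed base RNG seed; replicate `r` uses `seed + r`.
#' @return a one-row `data.frame` with pooled bias/RMSE for seed and pollen
#'   migration (plus divergence, inbreeding, and distance-effect columns
#'   where estimated), selection counts, and the replicate table in
#'   attribute `"replicates"`.
#' @export
run_benchmark <- function(cfg, reps, control = spmig_control(), seed = 1) {
  if (reps < 1) stop("need at least one replicate")
  est_a <- list(); tru_a <- list(); est_b <- list(); tru_b <- list()
  est_fst <- list(); tru_fst <- list(); est_F <- list(); tru_F <- list()
  est_ba <- numeric(reps); est_bb <- numeric(reps)
  pr_ba <- numeric(reps); pr_bb <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_scenario(cfg, seed = seed + r)
    fit <- run_chain(sim$data, layout = cfg$layout, control = control,
                     seed = seed + 100000L + r)
    s <- summary(fit)
    est_a[[r]] <- off_diag(s$alpha$mean); tru_a[[r]] <- off_diag(sim$truth$alpha)
    est_b[[r]] <- off_diag(s$beta$mean); tru_b[[r]] <- off_diag(sim$truth$beta)
    if (!fit$ideal) {
      est_fst[[r]] <- s$fst$mean; tru_fst[[r]] <- sim$truth$fst
      if (control$estimate_F) {
        est_F[[r]] <- s$F_mean; tru_F[[r]] <- sim$truth$f_ind
      }
    }
    est_ba[r] <- s$b_seed_mean; est_bb[r] <- s$b_pollen_mean
    pr_ba[r] <- s$pr_b_seed; pr_bb[r] <- s$pr_b_pollen
  }
  br_a <- bias_rmse(est_a, tru_a); br_b <- bias_rmse(est_b, tru_b)
  out <- data.frame(
    K = cfg$K, N = cfg$N, assay = cfg$assay, mu_fst = cfg$mu_fst,
    mu_f = cfg$mu_f, b_seed = cfg$b_seed, b_pollen = cfg$b_pollen,
    reps = reps,
    bias_alpha = br_a["bias"], rmse_alpha = br_a["rmse"],
    bias_beta = br_b["bias"], rmse_beta = br_b["rmse"],
    row.names = NULL)
  if (length(est_fst)) {
    br <- bias_rmse(est_fst, tru_fst)
    out$bias_fst <- br["bias"]; out$rmse_fst <- br["rmse"]
  }
  if (length(est_F)) {
    br <- bias_rmse(est_F, tru_F)
    out$bias_F <- br["bias"]; out$rmse_F <- br["rmse"]
  }
  if (control$estimate_b && !is.null(cfg$layout)) {
    sa <- selection_rate(pr_ba); sb <- selection_rate(pr_bb)
    out$bias_b_seed <- mean(est_ba) - cfg$b_seed
    out$rmse_b_seed <- sqrt(mean((est_ba - cfg$b_seed)^2))
    out$pr_b_seed <- sa$mean_pr; out$npos_seed <- sa$n_pos
    out$bias_b_pollen <- mean(est_bb) - cfg$b_pollen
    out$rmse_b_pollen <- sqrt(mean((est_bb - cfg$b_pollen)^2))
    out$pr_b_pollen <- sb$mean_pr; out$npos_pollen <- sb$n_pos
  }
  attr(out, "replicates") <- data.frame(
    rep = seq_len(reps), pr_b_seed = pr_ba, pr_b_pollen = pr_bb,
    b_seed_mean = est_ba, b_pollen_mean = est_bb)
  out
}
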