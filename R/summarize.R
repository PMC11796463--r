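#' Posterior summary of a chain
#'
#' Posterior mean, SE (posterior standard deviation) and shortest 95% (by
#' default) highest posterior density interval for every scalar parameter,
#' elementwise summaries for the migration matrices, posterior model
#' probabilities `Pr(b_seed > 0)` and `Pr(b_pollen > 0)` (reversible-jump
#' visit fractions), and per-individual origin posteriors. A migration rate
#' is flagged as significantly nonzero when its HPDI lower limit is at least
#' `1e-4` (rates with lower limits below numerical precision are treated as
#' indistinguishable from zero).
#'
#' @param object a `spmig_trace` from [run_chain()].
#' @param prob HPDI mass (defaults to the run's control setting).
#' @param ... unused.
#' @return object of class `spmig_summary`.
#' @export
summary.spmig_trace <- function(object, prob = NULL, ...) {
  tr <- object
  if (tr$retained < 1) stop("empty trace")
  prob <- prob %||% tr$control$hpdi_prob
  K <- tr$K

  summ_vec <- function(x) {
    h <- hpdi(x, prob)
    c(mean = mean(x), se = sd(x), lower = h[1], upper = h[2])
  }
  sc <- tr$scalars
  keep <- setdiff(colnames(sc), c("model_seed", "model_pollen", "loglik"))
  scalars <- t(vapply(keep, function(nm) summ_vec(sc[, nm]), numeric(4)))
  scalars <- data.frame(parameter = keep, scalars, row.names = NULL)

  mat_summ <- function(arr) {
    m <- apply(arr, c(2, 3), mean)
    lo <- apply(arr, c(2, 3), function(x) hpdi(x, prob)[1])
    hi <- apply(arr, c(2, 3), function(x) hpdi(x, prob)[2])
    dimnames(m) <- dimnames(lo) <- dimnames(hi) <-
      list(tr$pop_levels, tr$pop_levels)
    list(mean = m, lower = lo, upper = hi, significant = lo >= 1e-4)
  }
  alpha <- mat_summ(tr$alpha)
  beta <- mat_summ(tr$beta)

  fst <- if (!is.null(tr$fst)) {
    data.frame(pop = tr$pop_levels,
               t(apply(tr$fst, 2, summ_vec)), row.names = NULL)
  }
  eps <- if (!is.null(tr$eps)) {
    data.frame(locus = seq_len(ncol(tr$eps)),
               t(apply(tr$eps, 2, summ_vec)), row.names = NULL)
  }

  origin <- tr$origin_counts / rowSums(tr$origin_counts)

  structure(list(
    scalars = scalars, alpha = alpha, beta = beta, fst = fst, eps = eps,
    F_mean = tr$F_mean, F_se = tr$F_se,
    pr_b_seed = mean(sc[, "model_seed"]),
    pr_b_pollen = mean(sc[, "model_pollen"]),
    b_seed_mean = mean(sc[, "b_seed"]),
    b_pollen_mean = mean(sc[, "b_pollen"]),
    origin_posterior = origin,
    retained = tr$retained, prob = prob, K = K,
    pop_levels = tr$pop_levels, ideal = tr$ideal
  ), class = "spmig_summary")
}

#' @export
print.spmig_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Posterior summary (%d retained samples, %.0f%% HPDI)\n\n",
              x$retained, 100 * x$prob))
  df <- x$scalars
  df[, -1] <- round(df[, -1], digits)
  print(df, row.names = FALSE)
  cat(sprintf("\nPr(b_seed > 0)   = %.4f\nPr(b_pollen > 0) = %.4f\n",
              x$pr_b_seed, x$pr_b_pollen))
  cat("\nPosterior mean seed migration (alpha):\n")
  print(round(x$alpha$mean, digits))
  cat("\nPosterior mean pollen migration (beta):\n")
  print(round(x$beta$mean, digits))
  invisible(x)
}

#' @export
print.spmig_trace <- function(x, ...) {
  cat(sprintf("spmig_trace: %d retained samples (%d cycles, %d burn-in, thin %d)\n",
              x$retained, x$cycles, x$burnin, x$thin))
  cat(sprintf("  %d populations, %d individuals%s\n", x$K, x$n,
              if (x$ideal) ", ideal mode (origins observed)" else
                sprintf(", %d loci", x$L)))
  invisible(x)
}
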