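#' Fit the spatially explicit migration model
#'
#' Main fitting function. Estimates recent seed (zygotic) and pollen
#' (gametic) migration rates among discrete populations from multilocus
#' genotypes by hierarchical Bayesian MCMC, jointly with population allele
#' frequencies (F-model), population divergence, individual inbreeding and
#' per-locus allelic dropout. When a spatial layout is supplied, reversible
#' jump moves assess a distance-decay effect on migration separately for the
#' seed and pollen channels.
#'
#' @param genotypes a [genotype_data()] (or, for the ideal
#'   observed-origins benchmark, an [origin_data()]).
#' @param layout optional [spatial_layout()] of the sampled populations.
#' @param control a [spmig_control()].
#' @param seed integer RNG seed (chains are reproducible given the seed).
#' @return an object of class `spmig` with components `trace` (the
#'   [run_chain()] output), `summary` (a [summary.spmig_trace()]), `call`,
#'   `layout` and `control`.
#' @examples
#' sc <- scenario_config(K = 3, N = 45, assay = "custom", L = 8,
#'                       alleles = 4, mu_fst = 0.3)
#' sim <- simulate_scenario(sc, seed = 1)
#' fit <- spmig(sim$data, control = spmig_control(
#'   cycles = 600, burnin = 300, thin = 3,
#'   estimate_F = FALSE, estimate_dropout = FALSE), seed = 1)
#' coef(fit)$alpha
#' @export
spmig <- function(genotypes, layout = NULL, control = spmig_control(),
                  seed = NULL) {
  cl <- match.call()
  trace <- run_chain(genotypes, layout = layout, control = control,
                     seed = seed)
  structure(list(trace = trace, summary = summary(trace), call = cl,
                 layout = layout, control = control),
            class = "spmig")
}

#' @export
print.spmig <- function(x, ...) {
  cat("Spatially explicit seed/pollen migration model\n")
  cat("Call: "); print(x$call)
  print(x$trace)
  cat(sprintf("Pr(b_seed > 0) = %.3f, Pr(b_pollen > 0) = %.3f\n",
              x$summary$pr_b_seed, x$summary$pr_b_pollen))
  invisible(x)
}

#' @export
summary.spmig <- function(object, ...) object$summary

#' Posterior point estimates
#'
#' Posterior means of the main parameters: the seed and pollen migration
#' matrices, the scalar hyperparameters, and (full model) divergence,
#' inbreeding and dropout.
#'
#' @param object a fitted [spmig()] model.
#' @param ... unused.
#' @return named list of posterior means.
#' @export
coef.spmig <- function(object, ...) {
  s <- object$summary
  out <- list(alpha = s$alpha$mean, beta = s$beta$mean,
              b_seed = s$b_seed_mean, b_pollen = s$b_pollen_mean,
              pr_b_seed = s$pr_b_seed, pr_b_pollen = s$pr_b_pollen)
  sc <- s$scalars
  out <- c(out, setNames(as.list(sc$mean), sc$parameter))
  if (!is.null(s$fst)) out$fst <- setNames(s$fst$mean, s$fst$pop)
  if (!is.null(s$F_mean)) out$F_ind <- s$F_mean
  if (!is.null(s$eps)) out$dropout <- setNames(s$eps$mean, s$eps$locus)
  out
}

#' Posterior origin assignment of individuals
#'
#' Posterior probability, per individual, of each (maternal, paternal)
#' source pair, estimated as MCMC visit frequencies of the latent origins.
#'
#' @param object a fitted [spmig()] model.
#' @param type `"pair"` for the full `N x K^2` table, `"maternal"` or
#'   `"paternal"` for the marginal `N x K` tables.
#' @param ... unused.
#' @return probability matrix with one row per individual.
#' @export
predict.spmig <- function(object, type = c("pair", "maternal", "paternal"),
                          ...) {
  type <- match.arg(type)
  P <- object$summary$origin_posterior
  K <- object$summary$K
  if (type == "pair") {
    colnames(P) <- paste0(rep(object$summary$pop_levels, each = K), ":",
                          rep(object$summary$pop_levels, K))
    return(P)
  }
  idx <- if (type == "maternal") rep(seq_len(K), each = K) else
    rep(seq_len(K), K)
  out <- t(apply(P, 1, function(r) tapply(r, idx, sum)))
  colnames(out) <- object$summary$pop_levels
  out
}

#' Trace plots of scalar parameters
#'
#' @param x a fitted [spmig()] model.
#' @param pars which scalar traces to draw.
#' @param ... passed to [plot()].
#' @export
plot.spmig <- function(x, pars = c("tau_seed", "gamma_seed", "tau_pollen",
                                   "gamma_pollen"), ...) {
  sc <- x$trace$scalars
  pars <- intersect(pars, colnames(sc))
  old <- par(mfrow = c(length(pars), 1), mar = c(2.5, 4, 1, 1))
  on.exit(par(old))
  for (p in pars) {
    plot(sc[, p], type = "l", ylab = p, xlab = "", ...)
  }
  invisible(x)
}

#' Posterior predictive datasets
#'
#' Draws genotype datasets from the generative model at parameter values
#' taken from retained posterior samples (one sample per simulated dataset).
#'
#' @param object a fitted [spmig()] (full model, not ideal mode).
#' @param nsim number of datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of [genotype_data()] objects.
#' @export
simulate.spmig <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tr <- object$trace
  if (tr$ideal) stop("posterior predictive simulation needs the full model")
  draws <- sample.int(tr$retained, nsim, replace = TRUE)
  lapply(draws, function(m) {
    alpha <- tr$alpha[m, , ]
    beta <- tr$beta[m, , ]
    # posterior-mean nuisance fields; per-draw p is not stored in full
    gen <- draw_origins_and_genotypes(
      pop = tr$pop, alpha = alpha, beta = beta, p = tr$p_mean,
      f_ind = tr$F_mean, dropout = tr$eps[m, ],
      allele_counts = vapply(tr$p_mean, ncol, 0L))
    genotype_data(gen$a1, gen$a2, tr$pop_levels[tr$pop],
                  allele_counts = vapply(tr$p_mean, ncol, 0L),
                  pop_levels = tr$pop_levels)
  })
}
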