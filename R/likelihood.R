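#' Single-locus genotype probability
#'
#' Probability of an observed diploid genotype at one locus given the
#' maternal source `j`, paternal source `k`, the locus allele frequencies,
#' the individual inbreeding coefficient `F` and the locus allelic dropout
#' rate `eps`. Identical-by-descent alleles must share a source, so `F`
#' enters only when `j == k`; a true heterozygote drops to either homozygote
#' with probability `eps` (split evenly between the two alleles). A missing
#' genotype (`NA`) is uninformative and returns 1.
#'
#' @param g integer vector of the two allele indices (unordered), or `NA`.
#' @param j,k maternal and paternal source population indices.
#' @param p_l `K x A_l` allele frequency matrix for the locus.
#' @param F_i inbreeding coefficient in `[0,1]`.
#' @param eps_l dropout rate in `[0,1]`.
#' @return probability (scalar).
#' @export
genotype_prob <- function(g, j, k, p_l, F_i = 0, eps_l = 0) {
  stopifnot(F_i >= 0, F_i <= 1, eps_l >= 0, eps_l <= 1)
  if (length(g) == 1 || anyNA(g)) return(1)
  A <- ncol(p_l)
  if (any(g < 1 | g > A)) {
    stop(sprintf("invalid allele index %s (locus has %d alleles)",
                 paste(g, collapse = "/"), A))
  }
  p_j <- p_l[j, ]; p_k <- p_l[k, ]
  a <- g[1]; b <- g[2]
  if (a == b) {
    if (j == k) {
      F_i * p_j[a] + (1 - F_i) * (p_j[a]^2 + eps_l * p_j[a] * (1 - p_j[a]))
    } else {
      p_j[a] * p_k[a] +
        eps_l / 2 * (p_j[a] * (1 - p_k[a]) + p_k[a] * (1 - p_j[a]))
    }
  } else {
    if (j == k) {
      (1 - F_i) * (1 - eps_l) * 2 * p_j[a] * p_j[b]
    } else {
      (1 - eps_l) * (p_j[a] * p_k[b] + p_k[a] * p_j[b])
    }
  }
}

#' Multilocus genotype log-likelihood for a fixed origin pair
#'
#' Log probability of individual `i`'s whole multilocus genotype given a
#' maternal source `j` and paternal source `k`: the product over loci of
#' [genotype_prob()], computed in log space.
#'
#' @param i individual index.
#' @param j,k source population indices.
#' @param params a [genetic_params()].
#' @param data a [genotype_data()].
#' @return log probability.
#' @export
individual_lik <- function(i, j, k, params, data) {
  Fi <- if (length(params$f_ind) >= i) params$f_ind[i] else params$f_ind[1]
  ll <- 0
  for (l in seq_len(data$L)) {
    g <- c(data$a1[i, l], data$a2[i, l])
    pr <- genotype_prob(if (anyNA(g)) NA else g, j, k, params$p[[l]],
                        Fi, params$dropout[l])
    if (pr <= 0) return(-Inf)
    ll <- ll + log(pr)
  }
  ll
}

#' Marginal genotype log-likelihood under the migration mixture
#'
#' Log probability of individual `i`'s genotype with the latent origin pair
#' summed out: `sum_{j,k} alpha[s_i, j] * beta[j, k] * Pr_jk(G_i)`, evaluated
#' by log-sum-exp over the `K^2` origin pairs.
#'
#' @param i individual index.
#' @param alpha_row seed-migration row for the individual's sampling
#'   population (length `K`, sums to 1).
#' @param beta `K x K` row-stochastic pollen-migration matrix.
#' @param params a [genetic_params()].
#' @param data a [genotype_data()].
#' @return log probability.
#' @export
marginal_lik <- function(i, alpha_row, beta, params, data) {
  K <- data$K
  terms <- matrix(-Inf, K, K)
  for (j in seq_len(K)) {
    if (alpha_row[j] <= 0) next
    for (k in seq_len(K)) {
      if (beta[j, k] <= 0) next
      terms[j, k] <- log(alpha_row[j]) + log(beta[j, k]) +
        individual_lik(i, j, k, params, data)
    }
  }
  out <- log_sum_exp(terms)
  if (!is.finite(out)) {
    stop(sprintf("individual %d incompatible with every origin", i))
  }
  out
}

#' Posterior origin table for one individual
#'
#' Conditional probability of each maternal/paternal origin pair `(j, k)`
#' given the individual's genotype, proportional to
#' `alpha[s_i, j] * beta[j, k] * Pr_jk(G_i)`; normalized to sum to 1.
#'
#' @inheritParams marginal_lik
#' @return `K x K` probability matrix (rows: maternal source `j`, columns:
#'   paternal source `k`).
#' @export
origin_conditional <- function(i, alpha_row, beta, params, data) {
  K <- data$K
  lt <- matrix(-Inf, K, K)
  for (j in seq_len(K)) {
    if (alpha_row[j] <= 0) next
    for (k in seq_len(K)) {
      if (beta[j, k] <= 0) next
      lt[j, k] <- log(alpha_row[j]) + log(beta[j, k]) +
        individual_lik(i, j, k, params, data)
    }
  }
  z <- log_sum_exp(lt)
  if (!is.finite(z)) {
    stop(sprintf("individual %d incompatible with every origin", i))
  }
  exp(lt - z)
}

# Fast path: N x K^2 table of log Pr_jk(G_i) from the compiled kernel.
# Column index (j-1)*K + k. Mirrors genotype_prob()/individual_lik() exactly.
loglik_table <- function(data, params) {
  Fi <- rep_len(params$f_ind, data$n)
  loglik_table_cpp(data$a1, data$a2, params$p, Fi,
                   rep_len(params$dropout, data$L))
}
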