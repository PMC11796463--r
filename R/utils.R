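# Small numerical helpers shared across the package.

logit <- function(x) log(x) - log1p(-x)
inv_logit <- function(x) 1 / (1 + exp(-x))

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Dirichlet log density
#'
#' Log density of a Dirichlet distribution in the standard concentration
#' parameterization. Rows containing exact zeros return `-Inf` rather than
#' erroring, matching how interior-support priors are handled in the sampler.
#'
#' @param x simplex vector.
#' @param a concentration vector, all entries > 0.
#' @return log density (scalar).
#' @keywords internal
ddirichlet_log <- function(x, a) {
  if (any(x <= 0)) return(-Inf)
  sum((a - 1) * log(x)) - sum(lgamma(a)) + lgamma(sum(a))
}

# One Dirichlet draw via normalized gammas.
rdirichlet_one <- function(a) {
  g <- rgamma(length(a), shape = a, rate = 1)
  s <- sum(g)
  if (s == 0) { # pathological tiny shapes: fall back to the largest component
    g[which.max(a)] <- 1
    s <- 1
  }
  g / s
}

#' Beta distribution in mean/dispersion form
#'
#' Converts the (mean, dispersion) parameterization used throughout the model
#' — variance `mu*(1-mu)*gamma` — to the standard `shape1`/`shape2` pair:
#' `shape1 = mu*(1-gamma)/gamma`, `shape2 = (1-mu)*(1-gamma)/gamma`.
#'
#' @param mu mean in (0,1).
#' @param gamma dispersion in (0,1).
#' @return numeric vector `c(shape1, shape2)`.
#' @export
beta_shapes <- function(mu, gamma) {
  stopifnot(mu > 0, mu < 1, gamma > 0, gamma < 1)
  c(mu * (1 - gamma) / gamma, (1 - mu) * (1 - gamma) / gamma)
}

dbeta_md_log <- function(x, mu, gamma) {
  s <- beta_shapes(mu, gamma)
  dbeta(x, s[1], s[2], log = TRUE)
}

rbeta_md <- function(n, mu, gamma) {
  s <- beta_shapes(mu, gamma)
  rbeta(n, s[1], s[2])
}

# Boundary-spiked Beta priors (tiny shapes) put appreciable mass at values
# that round to exactly 0 or 1 in double precision — and they round
# asymmetrically (denormals survive near 0, everything within ~1e-17 of 1
# rounds to 1). The sampler therefore works with explicitly truncated
# versions, drawn by inverse CDF so proposal and target agree exactly.
EPS_TRUNC <- 1e-4    # domain floor for allelic dropout rates
F_TRUNC <- 1e-12     # domain floor for inbreeding coefficients

rbeta_trunc <- function(n, shape1, shape2, lo, hi) {
  plo <- pbeta(lo, shape1, shape2)
  phi <- pbeta(hi, shape1, shape2)
  qbeta(plo + runif(n) * (phi - plo), shape1, shape2)
}

reps_prior <- function(n = 1) {
  rbeta_trunc(n, 0.01, 0.01, EPS_TRUNC, 1 - EPS_TRUNC)
}

rbeta_md_trunc <- function(n, mu, gamma, lo = F_TRUNC) {
  s <- beta_shapes(mu, gamma)
  rbeta_trunc(n, s[1], s[2], lo, 1 - lo)
}

# Log density of the truncated mean/dispersion Beta; the normalizing mass
# depends on (mu, gamma) and must be kept when those hyperparameters move.
dbeta_md_trunc_log <- function(x, mu, gamma, lo = F_TRUNC) {
  s <- beta_shapes(mu, gamma)
  z <- pbeta(1 - lo, s[1], s[2]) - pbeta(lo, s[1], s[2])
  if (z <= 0) return(rep(-Inf, length(x)))
  out <- dbeta(x, s[1], s[2], log = TRUE) - log(z)
  out[x < lo | x > 1 - lo] <- -Inf
  out
}

# Gamma(shape = mu, rate = 1) truncated to (FST_MIN, 1): the prior for
# population divergence F_ST. The lower truncation keeps the F-model
# concentrations q*(1-FST)/FST finite; FST below 1e-4 is indistinguishable
# from no structure.
FST_MIN <- 1e-4

dtgamma_log <- function(x, mu) {
  if (x <= FST_MIN || x >= 1) return(-Inf)
  dgamma(x, shape = mu, rate = 1, log = TRUE) -
    log(pgamma(1, shape = mu, rate = 1) -
          pgamma(FST_MIN, shape = mu, rate = 1))
}

rtgamma <- function(n, mu) {
  lo <- pgamma(FST_MIN, shape = mu, rate = 1)
  hi <- pgamma(1, shape = mu, rate = 1)
  qgamma(lo + runif(n) * (hi - lo), shape = mu, rate = 1)
}

#' Highest posterior density interval
#'
#' Shortest interval containing a given mass of an empirical sample, found by
#' scanning all windows of the sorted draws.
#'
#' @param x numeric vector of posterior draws.
#' @param prob interval mass (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) stop("empty sample")
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}
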