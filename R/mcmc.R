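# Data-augmentation MCMC engine.
#
# Sweep composition (full model):
#   1. latent origins o_i = (j, k): exact Gibbs from the conditional table
#   2. alpha/beta rows: conjugate Dirichlet Gibbs given origin counts
#   3. tau, gamma (both channels): scalar MH on the migration-prior terms
#   4. b (both channels): within-model random walk + reversible jump
#   5. allele frequencies p: Dirichlet-proposal MH per (population, locus)
#   6. ancestral frequencies q: Dirichlet-proposal MH per locus
#   7. FST_j and mu_FST: scalar MH (truncated-Gamma prior terms)
#   8. F_i (inbreeding): Gibbs from the Beta prior when the two gametes come
#      from different sources (F absent from the likelihood), MH otherwise;
#      mu_F, gamma_F by scalar MH
#   9. eps_l (dropout): scalar MH per locus
# Scalar MH alternates a logit-scale random walk with an independence draw
# from the prior, so flat-likelihood directions still mix well.

# -- scalar MH helpers --------------------------------------------------------

mh_logit <- function(cur, logtarget, scale) {
  x <- logit(cur) + rnorm(1, 0, scale)
  prop <- inv_logit(x)
  if (prop <= 0 || prop >= 1) return(list(value = cur, acc = FALSE))
  lr <- logtarget(prop) - logtarget(cur) +
    log(prop * (1 - prop)) - log(cur * (1 - cur))
  acc <- is.finite(lr) && log(runif(1)) < lr
  list(value = if (acc) prop else cur, acc = acc)
}

mh_prior_indep <- function(cur, loglik, rprior) {
  prop <- rprior()
  if (prop <= 0 || prop >= 1) return(list(value = cur, acc = FALSE))
  lr <- loglik(prop) - loglik(cur)
  acc <- is.finite(lr) && log(runif(1)) < lr
  list(value = if (acc) prop else cur, acc = acc)
}

# Dirichlet-proposal MH step for a simplex vector (used for q rows).
mh_simplex <- function(cur, logtarget, h) {
  sh <- h * cur + 0.1
  prop <- rdirichlet_one(sh)
  if (any(prop <= 0)) return(list(value = cur, acc = FALSE))
  shp <- h * prop + 0.1
  lr <- logtarget(prop) - logtarget(cur) +
    ddirichlet_log(cur, shp) - ddirichlet_log(prop, sh)
  acc <- is.finite(lr) && log(runif(1)) < lr
  list(value = if (acc) prop else cur, acc = acc)
}

# -- origin augmentation ------------------------------------------------------

#' Gibbs draw of latent origins
#'
#' Draws, independently for each individual, a maternal/paternal origin pair
#' from its conditional posterior table (proportional to
#' `alpha[s_i, j] * beta[j, k] * Pr_jk(G_i)`).
#'
#' @param alpha,beta row-stochastic migration matrices.
#' @param params a [genetic_params()].
#' @param data a [genotype_data()].
#' @return list with integer vectors `maternal` and `paternal`.
#' @export
gibbs_origins <- function(alpha, beta, params, data) {
  tab <- loglik_table(data, params)
  draw_origins_from_table(tab, alpha, beta, data$pop, data$K)
}

draw_origins_from_table <- function(tab, alpha, beta, pop, K) {
  n <- nrow(tab)
  la <- log(alpha)[pop, , drop = FALSE]
  lb <- as.vector(t(log(beta)))              # index (j-1)*K + k
  W <- tab + la[, rep(seq_len(K), each = K), drop = FALSE] +
    matrix(lb, n, K * K, byrow = TRUE)
  cc <- sample_rows_cpp(W, runif(n))
  list(maternal = (cc - 1L) %/% K + 1L, paternal = (cc - 1L) %% K + 1L,
       logw = W, pick = cc)
}

#' Tally origin counts
#'
#' Seed counts `n[s, j]`: individuals sampled in population `s` whose seed
#' came from `j`. Pollen counts `m[j, k]`: individuals whose seed came from
#' `j` and pollen from `k`.
#'
#' @param pop sampling population per individual.
#' @param maternal,paternal origin indices per individual.
#' @param K number of populations.
#' @return list of two `K x K` integer matrices `seed` and `pollen`.
#' @export
tally_origins <- function(pop, maternal, paternal, K) {
  seed <- matrix(tabulate((pop - 1L) * K + maternal, K * K), K, K, byrow = TRUE)
  pollen <- matrix(tabulate((maternal - 1L) * K + paternal, K * K), K, K,
                   byrow = TRUE)
  list(seed = seed, pollen = pollen)
}

#' Conjugate Gibbs update of a migration matrix
#'
#' Given origin counts, each row of the migration matrix is conditionally
#' Dirichlet with concentration `pi_i (1-gamma)/gamma + counts_i`.
#'
#' @param counts `K x K` origin count matrix (rows = recipients for seed,
#'   maternal sources for pollen).
#' @param pi_mat `K x K` matrix of prior mean rows.
#' @param gamma dispersion parameter in (0,1).
#' @return a row-stochastic `K x K` draw.
#' @export
gibbs_migration_rows <- function(counts, pi_mat, gamma) {
  K <- nrow(counts)
  out <- matrix(0, K, K)
  for (i in seq_len(K)) {
    out[i, ] <- rdirichlet_one(dirichlet_concentration(pi_mat[i, ], gamma) +
                                 counts[i, ])
  }
  out
}

# Prior mean matrix for one channel given current hyperparameters.
pi_matrix <- function(lambda, tau, b, D, K) {
  if (K == 1) return(matrix(1, 1, 1))
  if (is.null(D) || b == 0) {  # uniform competing sources
    m <- matrix((1 - lambda) * (1 - tau) / (K - 1), K, K)
    diag(m) <- lambda + (1 - lambda) * tau
    return(m)
  }
  t(vapply(seq_len(K),
           function(i) expected_proportions(lambda, tau, b, D, i, K = K),
           numeric(K)))
}

# -- chain --------------------------------------------------------------------

default_tuning <- function(K, L, n) {
  list(tau_a = 0.8, gam_a = 0.8, tau_b = 0.8, gam_b = 0.8,
       b_a = 0.8, b_b = 0.8, mu_fst = 0.8, mu_f = 0.8, gam_f = 0.8,
       fst = rep(0.8, K), eps = rep(1.5, L), Fi = 1.5,
       p = matrix(200, K, L), q = rep(200, L))
}

#' Run the MCMC sampler
#'
#' Low-level engine behind [spmig()]. Accepts either a [genotype_data()]
#' (full model) or an [origin_data()] (ideal categorical discrimination:
#' origins observed, genetic blocks skipped).
#'
#' @param data a [genotype_data()] or [origin_data()].
#' @param layout optional [spatial_layout()]; required for distance-effect
#'   estimation.
#' @param control a [spmig_control()].
#' @param seed integer RNG seed; chains are exactly reproducible given the
#'   seed.
#' @param state0 optional starting state (as returned in the `state` field
#'   of a previous trace); used to continue a chain.
#' @return object of class `spmig_trace`: retained samples of all
#'   parameters, model indicators, posterior origin counts, acceptance
#'   rates, the final `state`, and run metadata.
#' @export
run_chain <- function(data, layout = NULL, control = spmig_control(),
                      seed = NULL, state0 = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ideal <- inherits(data, "origin_data")
  if (!ideal && !inherits(data, "genotype_data")) {
    stop("data must be a genotype_data or origin_data object")
  }
  K <- data$K; n <- data$n
  L <- if (ideal) 0L else data$L
  D <- if (!is.null(layout)) layout$dist else NULL
  if (!is.null(D) && nrow(D) != K) stop("layout and data disagree on K")
  use_b <- control$estimate_b && !is.null(D) && K >= 2
  la <- control$lambda_seed; lb <- control$lambda_pollen

  M <- (control$cycles - control$burnin) %/% control$thin
  if (M < 1) stop("no retained samples: increase cycles or reduce thinning")

  st <- state0 %||% init_state(data, control, ideal)
  tun <- default_tuning(K, max(L, 1L), n)
  scalars_names <- c("tau_seed", "gamma_seed", "b_seed", "model_seed",
                     "tau_pollen", "gamma_pollen", "b_pollen", "model_pollen",
                     "mu_fst", "mu_f", "gamma_f", "loglik")
  tr <- list(
    scalars = matrix(NA_real_, M, length(scalars_names),
                     dimnames = list(NULL, scalars_names)),
    alpha = array(NA_real_, c(M, K, K)), beta = array(NA_real_, c(M, K, K)),
    fst = if (!ideal) matrix(NA_real_, M, K) else NULL,
    eps = if (!ideal) matrix(NA_real_, M, L) else NULL,
    F_sum = if (!ideal) numeric(n) else NULL,
    F_sq = if (!ideal) numeric(n) else NULL,
    p_sum = if (!ideal) lapply(st$p, function(m) m * 0) else NULL,
    origin_counts = matrix(0L, n, K * K)
  )
  acc <- new.env(parent = emptyenv())
  nprop <- new.env(parent = emptyenv())
  bump <- function(name, a) {
    acc[[name]] <- (acc[[name]] %||% 0) + a
    nprop[[name]] <- (nprop[[name]] %||% 0) + 1
  }

  if (ideal) {
    counts <- tally_origins(data$pop, data$jm, data$jp, K)
  }

  # initial feasibility check
  if (!ideal) {
    tab0 <- loglik_table(data, state_params(st, data))
    if (any(!is.finite(apply(tab0, 1, max)))) {
      stop("non-finite genotype likelihood at initialization; ",
           "check allele indexing and frequencies")
    }
  }

  adapt_every <- 50L
  win <- new.env(parent = emptyenv())   # windowed acceptance for adaptation
  wbump <- function(name, a) {
    win[[name]] <- (win[[name]] %||% c(0, 0)) + c(a, 1)
  }

  midx <- 0L
  for (cyc in seq_len(control$cycles)) {
    rw <- cyc %% 2L == 0L   # alternate RW and prior-independence moves

    ## -- latent origins + migration matrices ---------------------------------
    if (!ideal) {
      params <- state_params(st, data)
      tab <- loglik_table(data, params)
      dr <- draw_origins_from_table(tab, st$alpha, st$beta, data$pop, K)
      st$jm <- dr$maternal; st$jp <- dr$paternal
      st$loglik <- sum(dr$logw[cbind(seq_len(n), dr$pick)])
      counts <- tally_origins(data$pop, st$jm, st$jp, K)
    } else {
      st$loglik <- sum(log(st$alpha[cbind(data$pop, data$jm)])) +
        sum(log(st$beta[cbind(data$jm, data$jp)]))
    }

    pia <- pi_matrix(la, st$tau_a, st$b_a, D, K)
    pib <- pi_matrix(lb, st$tau_b, st$b_b, D, K)
    st$alpha <- gibbs_migration_rows(counts$seed, pia, st$gam_a)
    st$beta <- gibbs_migration_rows(counts$pollen, pib, st$gam_b)

    ## -- migration hyperparameters -------------------------------------------
    for (ch in c("a", "b")) {
      lam <- if (ch == "a") la else lb
      mat <- if (ch == "a") st$alpha else st$beta
      taun <- paste0("tau_", ch); gamn <- paste0("gam_", ch)
      bn <- paste0("b_", ch); indn <- paste0("ind_", ch)
      prior_term <- function(tau, gam, b) {
        log_prior_migration(mat, lam, tau, gam, b, D)
      }
      # tau
      tgt <- function(x) prior_term(x, st[[gamn]], st[[bn]])
      r <- if (rw) mh_logit(st[[taun]], tgt, tun[[taun]]) else
        mh_prior_indep(st[[taun]], tgt, function() runif(1))
      st[[taun]] <- r$value; bump(taun, r$acc); if (rw) wbump(taun, r$acc)
      # gamma
      tgt <- function(x) prior_term(st[[taun]], x, st[[bn]])
      r <- if (rw) mh_logit(st[[gamn]], tgt, tun[[gamn]]) else
        mh_prior_indep(st[[gamn]], tgt, function() runif(1))
      st[[gamn]] <- r$value; bump(gamn, r$acc); if (rw) wbump(gamn, r$acc)
      # distance effect: within-model RW + reversible jump
      if (use_b) {
        if (st[[indn]] == 1L) {
          prop <- st[[bn]] + rnorm(1, 0, tun[[bn]])
          lr <- prior_term(st[[taun]], st[[gamn]], prop) -
            prior_term(st[[taun]], st[[gamn]], st[[bn]]) +
            dnorm(prop, 0, control$b_prior_sd, log = TRUE) -
            dnorm(st[[bn]], 0, control$b_prior_sd, log = TRUE)
          ok <- is.finite(lr) && log(runif(1)) < lr
          if (ok) st[[bn]] <- prop
          bump(bn, ok); wbump(bn, ok)
        }
        # jump: prior-draw birth / deterministic death (prior odds 1:1)
        if (st[[indn]] == 0L) {
          bstar <- rnorm(1, 0, control$b_prior_sd)
          lr <- prior_term(st[[taun]], st[[gamn]], bstar) -
            prior_term(st[[taun]], st[[gamn]], 0)
          if (is.finite(lr) && log(runif(1)) < lr) {
            st[[indn]] <- 1L; st[[bn]] <- bstar
          }
        } else {
          lr <- prior_term(st[[taun]], st[[gamn]], 0) -
            prior_term(st[[taun]], st[[gamn]], st[[bn]])
          if (is.finite(lr) && log(runif(1)) < lr) {
            st[[indn]] <- 0L; st[[bn]] <- 0
          }
        }
      }
    }

    ## -- genetic blocks -------------------------------------------------------
    if (!ideal) {
      st <- update_genetics(st, data, control, tun, rw, bump, wbump)
    }

    ## -- adaptation -----------------------------------------------------------
    if (control$adapt && cyc <= control$burnin && cyc %% adapt_every == 0L) {
      tun <- adapt_tuning(tun, win)
      rm(list = ls(win), envir = win)
    }

    ## -- retention ------------------------------------------------------------
    if (cyc > control$burnin &&
        (cyc - control$burnin) %% control$thin == 0L) {
      midx <- midx + 1L
      tr$scalars[midx, ] <- c(st$tau_a, st$gam_a, st$b_a, st$ind_a,
                              st$tau_b, st$gam_b, st$b_b, st$ind_b,
                              st$mu_fst, st$mu_f, st$gam_f, st$loglik)
      tr$alpha[midx, , ] <- st$alpha
      tr$beta[midx, , ] <- st$beta
      if (!ideal) {
        tr$fst[midx, ] <- st$fst
        tr$eps[midx, ] <- st$eps
        tr$F_sum <- tr$F_sum + st$Fi
        tr$F_sq <- tr$F_sq + st$Fi^2
        for (l in seq_len(L)) tr$p_sum[[l]] <- tr$p_sum[[l]] + st$p[[l]]
        oc <- (st$jm - 1L) * K + st$jp
        tr$origin_counts[cbind(seq_len(n), oc)] <-
          tr$origin_counts[cbind(seq_len(n), oc)] + 1L
      } else {
        oc <- (data$jm - 1L) * K + data$jp
        tr$origin_counts[cbind(seq_len(n), oc)] <-
          tr$origin_counts[cbind(seq_len(n), oc)] + 1L
      }
    }
    if (control$verbose && cyc %% 1000L == 0L) {
      message(sprintf("cycle %d/%d loglik %.2f", cyc, control$cycles,
                      st$loglik))
    }
  }

  rates <- setNames(
    vapply(ls(acc), function(nm) acc[[nm]] / nprop[[nm]], 0), ls(acc))
  structure(list(
    scalars = tr$scalars, alpha = tr$alpha, beta = tr$beta,
    fst = tr$fst, eps = tr$eps,
    F_mean = if (!ideal) tr$F_sum / M else NULL,
    F_se = if (!ideal) sqrt(pmax(tr$F_sq / M - (tr$F_sum / M)^2, 0)) else NULL,
    p_mean = if (!ideal) lapply(tr$p_sum, function(m) m / M) else NULL,
    origin_counts = tr$origin_counts,
    accept = rates, retained = M, state = st,
    burnin = control$burnin, thin = control$thin, cycles = control$cycles,
    seed = seed, K = K, L = L, n = n, ideal = ideal,
    pop_levels = if (!ideal) data$pop_levels else paste0("pop", seq_len(K)),
    pop = data$pop, control = control,
    layout = layout
  ), class = "spmig_trace")
}

# Parameters bundle for likelihood evaluation from the current state.
state_params <- function(st, data) {
  structure(list(p = st$p, q = st$q, fst = st$fst, f_ind = st$Fi,
                 dropout = st$eps, mu_fst = st$mu_fst, mu_f = st$mu_f,
                 gamma_f = st$gam_f, K = data$K, L = data$L),
            class = "genetic_params")
}

init_state <- function(data, control, ideal) {
  K <- data$K
  st <- list(tau_a = 0.5, gam_a = 0.5, b_a = 0, ind_a = 0L,
             tau_b = 0.5, gam_b = 0.5, b_b = 0, ind_b = 0L,
             mu_fst = 0.1, mu_f = 0.1, gam_f = 0.5, loglik = NA_real_)
  st$alpha <- pi_matrix(control$lambda_seed, st$tau_a, 0, NULL, K)
  st$beta <- pi_matrix(control$lambda_pollen, st$tau_b, 0, NULL, K)
  if (!ideal) {
    L <- data$L
    st$p <- vector("list", L); st$q <- vector("list", L)
    for (l in seq_len(L)) {
      A <- data$allele_counts[l]
      cnt <- matrix(1, K, A)  # pseudocount 1
      for (i in seq_len(data$n)) {
        if (is.na(data$a1[i, l])) next
        s <- data$pop[i]
        cnt[s, data$a1[i, l]] <- cnt[s, data$a1[i, l]] + 1
        cnt[s, data$a2[i, l]] <- cnt[s, data$a2[i, l]] + 1
      }
      st$p[[l]] <- cnt / rowSums(cnt)
      st$q[[l]] <- colSums(cnt) / sum(cnt)
    }
    st$fst <- rep(0.1, K)
    st$Fi <- rep(if (control$estimate_F) 0.01 else 0, data$n)
    st$eps <- rep(if (control$estimate_dropout) 0.01 else 0, L)
    st$jm <- data$pop; st$jp <- data$pop
  }
  st
}

update_genetics <- function(st, data, control, tun, rw, bump, wbump) {
  K <- data$K; L <- data$L; n <- data$n

  # allele frequencies p (compiled MH sweep over (j, l))
  res <- update_p_cpp(data$a1, data$a2, st$p, st$q, st$fst, st$jm, st$jp,
                      st$Fi, st$eps, tun$p)
  st$p <- res$p
  bump("p", mean(res$acc)); wbump("p", mean(res$acc))

  # ancestral frequencies q
  for (l in seq_len(L)) {
    fstv <- st$fst
    pl <- st$p[[l]]
    tgt <- function(qv) {
      s <- 0
      for (j in seq_len(K)) {
        s <- s + ddirichlet_log(pl[j, ], qv * (1 - fstv[j]) / fstv[j])
        if (!is.finite(s)) return(-Inf)
      }
      s
    }
    r <- mh_simplex(st$q[[l]], tgt, tun$q[l])
    st$q[[l]] <- r$value
    bump("q", r$acc); wbump("q", r$acc)
  }

  # population divergence
  for (j in seq_len(K)) {
    pj <- lapply(st$p, function(m) m[j, ])
    qv <- st$q
    lik <- function(f) {
      s <- 0
      for (l in seq_len(L)) {
        s <- s + ddirichlet_log(pj[[l]], qv[[l]] * (1 - f) / f)
        if (!is.finite(s)) return(-Inf)
      }
      s
    }
    tgt <- function(f) dtgamma_log(f, st$mu_fst) + lik(f)
    r <- if (rw) mh_logit(st$fst[j], tgt, tun$fst[j]) else
      mh_prior_indep(st$fst[j], lik, function() rtgamma(1, st$mu_fst))
    st$fst[j] <- r$value
    bump("fst", r$acc); if (rw) wbump(paste0("fst", j), r$acc)
  }
  # mu_FST (uniform hyperprior)
  tgt <- function(m) sum(vapply(st$fst, dtgamma_log, 0, mu = m))
  r <- if (rw) mh_logit(st$mu_fst, tgt, tun$mu_fst) else
    mh_prior_indep(st$mu_fst, tgt, function() runif(1))
  st$mu_fst <- r$value; bump("mu_fst", r$acc); if (rw) wbump("mu_fst", r$acc)

  # inbreeding
  if (control$estimate_F) {
    diff_origin <- st$jm != st$jp
    ndiff <- sum(diff_origin)
    if (ndiff > 0) {       # F absent from likelihood: Gibbs from the prior
      st$Fi[diff_origin] <- rbeta_md_trunc(ndiff, st$mu_f, st$gam_f)
    }
    for (i in which(!diff_origin)) {
      j <- st$jm[i]
      lik <- function(f) indiv_loglik_cpp(data$a1, data$a2, st$p, i, j, j,
                                          f, st$eps)
      tgt <- function(f) {
        dbeta_md_trunc_log(f, st$mu_f, st$gam_f) + lik(f)
      }
      r <- if (rw) mh_logit(st$Fi[i], tgt, tun$Fi) else
        mh_prior_indep(st$Fi[i], lik,
                       function() rbeta_md_trunc(1, st$mu_f, st$gam_f))
      st$Fi[i] <- r$value
      bump("F", r$acc); if (rw) wbump("Fi", r$acc)
    }
    Fv <- st$Fi
    tgt <- function(m) sum(dbeta_md_trunc_log(Fv, m, st$gam_f))
    r <- if (rw) mh_logit(st$mu_f, tgt, tun$mu_f) else
      mh_prior_indep(st$mu_f, tgt, function() runif(1))
    st$mu_f <- r$value; bump("mu_f", r$acc); if (rw) wbump("mu_f", r$acc)
    tgt <- function(g) sum(dbeta_md_trunc_log(Fv, st$mu_f, g))
    r <- if (rw) mh_logit(st$gam_f, tgt, tun$gam_f) else
      mh_prior_indep(st$gam_f, tgt, function() runif(1))
    st$gam_f <- r$value; bump("gam_f", r$acc); if (rw) wbump("gam_f", r$acc)
  }

  # allelic dropout
  if (control$estimate_dropout) {
    for (l in seq_len(L)) {
      a1 <- data$a1[, l]; a2 <- data$a2[, l]; pl <- st$p[[l]]
      lik <- function(e) {
        sum(locus_loglik_cpp(a1, a2, pl, st$jm, st$jp, st$Fi, e))
      }
      tgt <- function(e) {
        if (e < EPS_TRUNC || e > 1 - EPS_TRUNC) return(-Inf)
        dbeta(e, 0.01, 0.01, log = TRUE) + lik(e)
      }
      r <- if (rw) mh_logit(st$eps[l], tgt, tun$eps[l]) else
        mh_prior_indep(st$eps[l], lik, reps_prior)
      st$eps[l] <- r$value
      bump("eps", r$acc); if (rw) wbump(paste0("eps", l), r$acc)
    }
  }
  st
}

adapt_tuning <- function(tun, win) {
  adj <- function(scale, key, invert = FALSE) {
    w <- win[[key]]
    if (is.null(w) || w[2] < 5) return(scale)
    rate <- w[1] / w[2]
    f <- exp(0.8 * (rate - 0.3))
    if (invert) f <- 1 / f
    min(max(scale * f, if (invert) 5 else 0.02), if (invert) 2e4 else 15)
  }
  for (nm in c("tau_a", "gam_a", "tau_b", "gam_b", "b_a", "b_b",
               "mu_fst", "mu_f", "gam_f", "Fi")) {
    tun[[nm]] <- adj(tun[[nm]], nm)
  }
  for (j in seq_along(tun$fst)) {
    tun$fst[j] <- adj(tun$fst[j], paste0("fst", j))
  }
  for (l in seq_along(tun$eps)) {
    tun$eps[l] <- adj(tun$eps[l], paste0("eps", l))
  }
  # concentration-type scales move opposite to RW scales
  tun$p <- matrix(adj(tun$p[1], "p", invert = TRUE),
                  nrow(tun$p), ncol(tun$p))
  w <- win[["q"]]
  if (!is.null(w) && w[2] >= 5) {
    tun$q <- rep(adj(tun$q[1], "q", invert = TRUE), length(tun$q))
  }
  tun
}
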