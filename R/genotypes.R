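#' Multilocus genotype dataset
#'
#' Container for diploid codominant genotypes of `N` individuals at `L`
#' unlinked loci, each individual tagged with the population it was sampled
#' from. Alleles are stored as per-locus integer indices in `1..A_l`; a locus
#' is either fully observed (both alleles) or fully missing (`NA` in both
#' slots) — half-missing loci are rejected.
#'
#' @param a1,a2 integer matrices (`N x L`) with the two allele indices per
#'   individual and locus; `NA` (in both) marks a missing locus.
#' @param pop integer or factor of length `N`: sampling population of each
#'   individual.
#' @param allele_counts integer vector of length `L`: number of distinct
#'   alleles per locus (defaults to the maximum observed index, floored at 2).
#' @param pop_levels character vector of population labels defining the
#'   population order (defaults to order of first appearance).
#' @param ids,loci optional individual and locus labels.
#' @return an object of class `genotype_data` with fields `n`, `L`, `K`,
#'   `a1`, `a2`, `pop` (integer codes), `pop_levels`, `allele_counts`,
#'   `ids`, `loci`.
#' @seealso [read_genotypes()], [simulate_scenario()]
#' @export
genotype_data <- function(a1, a2, pop, allele_counts = NULL,
                          pop_levels = NULL, ids = NULL, loci = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2))) stop("a1 and a2 must have the same shape")
  n <- nrow(a1); L <- ncol(a1)
  if (n < 1 || L < 1) stop("need at least one individual and one locus")
  if (length(pop) != n) stop("pop must have one entry per individual")
  if (is.null(pop_levels)) {
    pop_levels <- as.character(unique(as.character(pop)))
  }
  popc <- match(as.character(pop), pop_levels)
  if (anyNA(popc)) {
    stop("unknown population label(s): ",
         paste(unique(as.character(pop)[is.na(popc)]), collapse = ", "))
  }
  K <- length(pop_levels)
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1, ]
    stop(sprintf("half-missing genotype: individual %d, locus %d", w[1], w[2]))
  }
  # store unordered pairs in canonical order a1 <= a2
  swap <- !is.na(a1) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  obs_max <- apply(a2, 2, function(x) if (all(is.na(x))) 2L else max(x, na.rm = TRUE))
  if (is.null(allele_counts)) allele_counts <- pmax(obs_max, 2L)
  allele_counts <- as.integer(allele_counts)
  if (length(allele_counts) != L) stop("allele_counts must have one entry per locus")
  obs_min <- apply(a1, 2, function(x) if (all(is.na(x))) 1L else min(x, na.rm = TRUE))
  bad <- which(obs_max > allele_counts | obs_min < 1L)
  if (length(bad)) {
    l <- bad[1]
    i <- which(!is.na(a1[, l]) &
                 (a1[, l] < 1L | a2[, l] > allele_counts[l]))[1]
    stop(sprintf("invalid allele index: individual %d, locus %d", i, l))
  }
  structure(list(
    n = n, L = L, K = K, a1 = a1, a2 = a2,
    pop = as.integer(popc), pop_levels = pop_levels,
    allele_counts = allele_counts,
    ids = ids %||% paste0("ind", seq_len(n)),
    loci = loci %||% paste0("loc", seq_len(L))
  ), class = "genotype_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d individuals, %d loci, %d populations\n",
              x$n, x$L, x$K))
  cat(sprintf("  alleles/locus: %s; missing: %.1f%%\n",
              paste(range(x$allele_counts), collapse = "-"),
              100 * mean(is.na(x$a1))))
  invisible(x)
}

#' Genetic parameter set
#'
#' Bundles allele frequencies and nuisance genetic parameters entering the
#' genotypic likelihood: per-population frequencies `p` (list of `K x A_l`
#' matrices), ancestral frequencies `q` (list of length-`A_l` vectors),
#' per-population divergence `fst`, per-individual inbreeding `f_ind`,
#' per-locus allelic dropout `dropout`, and the hypermeans `mu_fst`, `mu_f`,
#' `gamma_f`.
#'
#' @param p list of `K x A_l` row-stochastic frequency matrices.
#' @param q list of ancestral frequency vectors (defaults to column means of
#'   `p`).
#' @param fst per-population divergence values in (0,1).
#' @param f_ind per-individual inbreeding coefficients in `[0,1]`.
#' @param dropout per-locus dropout rates in `[0,1]`.
#' @param mu_fst,mu_f,gamma_f hypermeans/dispersion in (0,1).
#' @return object of class `genetic_params`.
#' @export
genetic_params <- function(p, q = NULL, fst = NULL, f_ind = 0, dropout = 0,
                           mu_fst = 0.1, mu_f = 0.1, gamma_f = 0.1) {
  stopifnot(is.list(p))
  K <- nrow(p[[1]]); L <- length(p)
  for (l in seq_len(L)) {
    rs <- rowSums(p[[l]])
    if (any(abs(rs - 1) > 1e-12)) stop("p rows must sum to 1 (locus ", l, ")")
  }
  if (is.null(q)) q <- lapply(p, colMeans)
  for (l in seq_len(L)) {
    if (abs(sum(q[[l]]) - 1) > 1e-12) stop("q must sum to 1 (locus ", l, ")")
  }
  if (is.null(fst)) fst <- rep(mu_fst, K)
  f_ind <- rep_len(f_ind, if (length(f_ind) > 1) length(f_ind) else length(f_ind))
  dropout <- rep_len(dropout, L)
  if (any(f_ind < 0 | f_ind > 1)) stop("f_ind must lie in [0,1]")
  if (any(dropout < 0 | dropout > 1)) stop("dropout must lie in [0,1]")
  structure(list(p = p, q = q, fst = fst, f_ind = f_ind, dropout = dropout,
                 mu_fst = mu_fst, mu_f = mu_f, gamma_f = gamma_f,
                 K = K, L = L),
            class = "genetic_params")
}
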