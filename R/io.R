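#' Read a genotype table
#'
#' Native delimited format: header `id,pop,loc1_a,loc1_b,...,locL_a,locL_b`;
#' one row per individual; allele codes are arbitrary strings or integers;
#' a missing locus has `NA` in both of its columns. Alleles are re-indexed
#' per locus to `1..A_l` (order of first appearance); the allele map is kept
#' in the returned object so codes survive a round trip.
#'
#' @param path file path.
#' @param sep field separator.
#' @param pop_levels optional explicit population ordering.
#' @return a [genotype_data()] with an `allele_maps` attribute.
#' @export
read_genotypes <- function(path, sep = ",", pop_levels = NULL) {
  tab <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                    check.names = FALSE)
  if (ncol(tab) < 4 || ncol(tab) %% 2 != 0) {
    stop("expected columns id, pop, then two columns per locus")
  }
  L <- (ncol(tab) - 2L) %/% 2L
  n <- nrow(tab)
  raw1 <- as.matrix(tab[, 2L + 2L * seq_len(L) - 1L])
  raw2 <- as.matrix(tab[, 2L + 2L * seq_len(L)])
  raw1[raw1 == "NA" | raw1 == ""] <- NA
  raw2[raw2 == "NA" | raw2 == ""] <- NA
  half <- which(xor(is.na(raw1), is.na(raw2)), arr.ind = TRUE)
  if (nrow(half) > 0) {
    stop(sprintf("half-missing genotype at line %d, locus %d",
                 half[1, 1] + 1L, half[1, 2]))
  }
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  maps <- vector("list", L)
  loci <- sub("_a$", "", colnames(tab)[2L + 2L * seq_len(L) - 1L])
  for (l in seq_len(L)) {
    codes <- unique(c(raw1[, l], raw2[, l]))
    codes <- codes[!is.na(codes)]
    codes <- codes[order(match(codes, codes))]     # first appearance
    maps[[l]] <- codes
    a1[, l] <- match(raw1[, l], codes)
    a2[, l] <- match(raw2[, l], codes)
  }
  gd <- genotype_data(a1, a2, tab$pop, pop_levels = pop_levels,
                      ids = tab$id, loci = loci)
  attr(gd, "allele_maps") <- maps
  gd
}

#' Write a genotype table in the format read by [read_genotypes()]
#'
#' @param data a [genotype_data()].
#' @param path file path.
#' @param sep field separator.
#' @export
write_genotypes <- function(data, path, sep = ",") {
  maps <- attr(data, "allele_maps")
  code <- function(m, l) {
    v <- m[, l]
    if (is.null(maps)) as.character(v) else maps[[l]][v]
  }
  out <- data.frame(id = data$ids, pop = data$pop_levels[data$pop])
  for (l in seq_len(data$L)) {
    out[[paste0(data$loci[l], "_a")]] <- code(data$a1, l)
    out[[paste0(data$loci[l], "_b")]] <- code(data$a2, l)
  }
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
              na = "NA")
}

#' Import a STRUCTURE-format genotype file
#'
#' Two-row-per-individual variant: whitespace-delimited, each row
#' `id pop allele_1 ... allele_L`, consecutive row pairs holding the two
#' allele copies; missing alleles coded `-9` (a locus is treated as missing
#' when either copy is).
#'
#' @param path file path.
#' @param missing missing-allele code.
#' @return a [genotype_data()].
#' @export
read_structure <- function(path, missing = -9) {
  tab <- read.table(path, header = FALSE, colClasses = "character")
  if (nrow(tab) %% 2 != 0) stop("expected two rows per individual")
  odd <- seq(1, nrow(tab), by = 2); even <- odd + 1L
  if (!all(tab[odd, 1] == tab[even, 1])) {
    stop("row pairs must carry the same individual id")
  }
  L <- ncol(tab) - 2L
  raw1 <- as.matrix(tab[odd, 2L + seq_len(L)])
  raw2 <- as.matrix(tab[even, 2L + seq_len(L)])
  raw1[raw1 == as.character(missing)] <- NA
  raw2[raw2 == as.character(missing)] <- NA
  both_na <- is.na(raw1) & is.na(raw2)
  raw1[both_na] <- NA; raw2[both_na] <- NA
  # a half-missing locus is demoted to fully missing
  hm <- xor(is.na(raw1), is.na(raw2))
  raw1[hm] <- NA; raw2[hm] <- NA
  n <- length(odd)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  maps <- vector("list", L)
  for (l in seq_len(L)) {
    codes <- unique(c(raw1[, l], raw2[, l]))
    codes <- codes[!is.na(codes)]
    maps[[l]] <- codes
    a1[, l] <- match(raw1[, l], codes)
    a2[, l] <- match(raw2[, l], codes)
  }
  gd <- genotype_data(a1, a2, tab[odd, 2], ids = tab[odd, 1])
  attr(gd, "allele_maps") <- maps
  gd
}

#' Write posterior output files
#'
#' Writes, under `outdir`: `parameters.tsv` (scalar posterior summaries),
#' `alpha_mean.tsv`/`beta_mean.tsv` with HPDI companions, `fst.tsv`,
#' `dropout.tsv`, `origins.tsv` (per-individual marginal origin
#' posteriors), and `model_probabilities.tsv`.
#'
#' @param fit a fitted [spmig()] (or a `spmig_summary`).
#' @param outdir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_summaries <- function(fit, outdir) {
  s <- if (inherits(fit, "spmig")) fit$summary else fit
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(x, name, rn = FALSE) {
    p <- file.path(outdir, name)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = rn)
    paths <<- c(paths, p)
  }
  wt(s$scalars, "parameters.tsv")
  wt(s$alpha$mean, "alpha_mean.tsv", rn = TRUE)
  wt(s$alpha$lower, "alpha_hpdi_lower.tsv", rn = TRUE)
  wt(s$alpha$upper, "alpha_hpdi_upper.tsv", rn = TRUE)
  wt(s$beta$mean, "beta_mean.tsv", rn = TRUE)
  wt(s$beta$lower, "beta_hpdi_lower.tsv", rn = TRUE)
  wt(s$beta$upper, "beta_hpdi_upper.tsv", rn = TRUE)
  if (!is.null(s$fst)) wt(s$fst, "fst.tsv")
  if (!is.null(s$eps)) wt(s$eps, "dropout.tsv")
  wt(data.frame(model = c("b_seed>0", "b_pollen>0"),
                pr = c(s$pr_b_seed, s$pr_b_pollen)),
     "model_probabilities.tsv")
  K <- s$K
  orig <- as.data.frame(s$origin_posterior)
  names(orig) <- paste0(rep(s$pop_levels, each = K), ":",
                        rep(s$pop_levels, K))
  wt(orig, "origins.tsv")
  invisible(paths)
}

#' Write full parameter traces
#'
#' One tab-delimited file per parameter block (`scalars.tsv`, `alpha.tsv`,
#' `beta.tsv`, `fst.tsv`, `dropout.tsv`) plus a `manifest.txt` echoing the
#' run configuration, seed and acceptance rates.
#'
#' @param trace a `spmig_trace`.
#' @param outdir output directory.
#' @return invisibly, the paths written.
#' @export
write_trace <- function(trace, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  K <- trace$K
  cyc <- trace$burnin + trace$thin * seq_len(trace$retained)
  paths <- character(0)
  wt <- function(x, name) {
    p <- file.path(outdir, name)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wt(data.frame(cycle = cyc, trace$scalars, check.names = FALSE),
     "scalars.tsv")
  flat <- function(arr) {
    m <- matrix(arr, nrow = dim(arr)[1])
    colnames(m) <- paste0(rep(seq_len(K), K), "_", rep(seq_len(K), each = K))
    data.frame(cycle = cyc, m, check.names = FALSE)
  }
  wt(flat(trace$alpha), "alpha.tsv")
  wt(flat(trace$beta), "beta.tsv")
  if (!is.null(trace$fst)) {
    wt(data.frame(cycle = cyc, trace$fst), "fst.tsv")
  }
  if (!is.null(trace$eps)) {
    wt(data.frame(cycle = cyc, trace$eps), "dropout.tsv")
  }
  mf <- file.path(outdir, "manifest.txt")
  ctl <- trace$control
  lines <- c(
    sprintf("seed=%s", trace$seed %||% "NA"),
    sprintf("cycles=%d", trace$cycles),
    sprintf("burnin=%d", trace$burnin),
    sprintf("thin=%d", trace$thin),
    sprintf("retained=%d", trace$retained),
    sprintf("lambda_seed=%g", ctl$lambda_seed),
    sprintf("lambda_pollen=%g", ctl$lambda_pollen),
    sprintf("estimate_F=%s", ctl$estimate_F),
    sprintf("estimate_dropout=%s", ctl$estimate_dropout),
    sprintf("estimate_b=%s", ctl$estimate_b),
    sprintf("accept_%s=%.4f", names(trace$accept), trace$accept))
  writeLines(lines, mf)
  invisible(c(paths, mf))
}

#' Read a key=value run configuration file
#'
#' Lines of the form `key=value`; `#` starts a comment. Recognized keys
#' match the arguments of [spmig_control()] plus `genotypes`, `distances`,
#' `coords`, `out`.
#'
#' @param path file path.
#' @return named list of values (numeric where possible).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  vals <- lapply(kv, function(x) {
    v <- trimws(x[2])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else if (v %in% c("TRUE", "FALSE")) as.logical(v)
    else v
  })
  setNames(vals, vapply(kv, function(x) trimws(x[1]), ""))
}
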