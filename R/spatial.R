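#' Spatial layout of populations
#'
#' Population identifiers plus geography: planar coordinates in km and/or a
#' symmetric pairwise distance matrix in km. User-supplied distance matrices
#' are accepted as-is (triangle-inequality violations allowed) but negative
#' entries are rejected.
#'
#' @param coords optional `K x 2` matrix of planar coordinates (km).
#' @param dist optional `K x K` symmetric nonnegative distance matrix (km),
#'   zero diagonal; computed from `coords` when omitted.
#' @param pop_ids population labels.
#' @return object of class `spatial_layout` with fields `pop_ids`, `coords`,
#'   `dist`, `K`.
#' @export
spatial_layout <- function(coords = NULL, dist = NULL, pop_ids = NULL) {
  if (is.null(coords) && is.null(dist)) stop("need coords or dist")
  if (is.null(dist)) {
    coords <- as.matrix(coords)
    dist <- as.matrix(stats::dist(coords))
  }
  dist <- as.matrix(dist)
  K <- nrow(dist)
  if (ncol(dist) != K) stop("distance matrix must be square")
  if (any(dist < 0)) stop("negative distances are not allowed")
  if (max(abs(dist - t(dist))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(abs(diag(dist)) > 1e-9)) stop("distance matrix diagonal must be zero")
  diag(dist) <- 0
  if (is.null(pop_ids)) pop_ids <- rownames(dist) %||% paste0("pop", seq_len(K))
  dimnames(dist) <- list(pop_ids, pop_ids)
  structure(list(pop_ids = pop_ids, coords = coords, dist = dist, K = K),
            class = "spatial_layout")
}

#' @export
print.spatial_layout <- function(x, ...) {
  cat(sprintf("spatial_layout: %d populations, pairwise distances %.2f-%.2f km\n",
              x$K, min(x$dist[x$dist > 0]), max(x$dist)))
  invisible(x)
}

#' Competing-sources distance weights
#'
#' Relative weight of each external source population `j` for a recipient
#' `i`, `rho_ij = (1+d_ij)^(-b) / sum_{k != i} (1+d_ik)^(-b)`. With `b = 0`
#' all external sources are equivalent and each weight is `1/(K-1)`.
#'
#' @param b distance-effect scale (real; larger values concentrate mass on
#'   near sources).
#' @param D `K x K` distance matrix (km).
#' @param i recipient population index.
#' @return length-`K` vector summing to 1 over `j != i`, with a structural
#'   zero at position `i`.
#' @export
distance_weights <- function(b, D, i) {
  K <- nrow(D)
  if (K < 2) stop("distance weights need at least two populations")
  lw <- -b * log1p(D[i, ])
  lw[i] <- -Inf
  w <- exp(lw - max(lw[-i]))
  w / sum(w)
}

#' Prior mean migration proportions
#'
#' Expected migration proportions into population `i`:
#' `pi_ii = lambda + (1-lambda) tau` for the local source and
#' `pi_ij = (1-lambda)(1-tau) rho_ij` for external sources, where `lambda` is
#' the fixed prior probability of local dispersal, `tau` the isolation
#' parameter, and `rho` the competing-sources distance weights.
#'
#' @param lambda fixed local-dispersal constant in (0,1).
#' @param tau isolation parameter in (0,1).
#' @param b distance-effect scale.
#' @param D distance matrix; ignored when `K = 1`.
#' @param i recipient population index.
#' @param K number of populations (defaults to `nrow(D)`).
#' @return length-`K` simplex.
#' @export
expected_proportions <- function(lambda, tau, b, D = NULL, i, K = nrow(D)) {
  stopifnot(lambda > 0, lambda < 1, tau >= 0, tau <= 1)
  if (K == 1) return(1)
  if (is.null(D)) { # no geography: uniform competing sources
    rho <- rep(1 / (K - 1), K); rho[i] <- 0
  } else {
    rho <- distance_weights(b, D, i)
  }
  pi_i <- (1 - lambda) * (1 - tau) * rho
  pi_i[i] <- lambda + (1 - lambda) * tau
  pi_i
}

#' Dirichlet concentration from mean/dispersion
#'
#' Maps the (mean simplex, dispersion) parameterization of the migration
#' prior to standard Dirichlet concentrations `a = pi * (1-gamma)/gamma`,
#' under which each component has variance `pi*(1-pi)*gamma`.
#'
#' @param pi mean simplex.
#' @param gamma dispersion in (0,1).
#' @return concentration vector.
#' @export
dirichlet_concentration <- function(pi, gamma) {
  if (gamma <= 0 || gamma >= 1) stop("gamma must lie in (0,1)")
  pi * (1 - gamma) / gamma
}

#' Log prior density of one migration-matrix row
#'
#' Dirichlet log density of a row of the seed or pollen migration matrix
#' under the mean/dispersion prior. Rows with exact zeros return `-Inf`.
#'
#' @param row simplex row of the migration matrix.
#' @param pi prior mean simplex (from [expected_proportions()]).
#' @param gamma dispersion in (0,1).
#' @return log density.
#' @export
log_prior_migration_row <- function(row, pi, gamma) {
  ddirichlet_log(row, dirichlet_concentration(pi, gamma))
}

# Sum of row log-priors for a whole migration matrix given hyperparameters.
log_prior_migration <- function(mat, lambda, tau, gamma, b, D) {
  K <- nrow(mat)
  if (any(mat <= 0)) return(-Inf)
  a <- pi_matrix(lambda, tau, b, D, K) * (1 - gamma) / gamma
  sum((a - 1) * log(mat)) - sum(lgamma(a)) + sum(lgamma(rowSums(a)))
}

#' Packaged nine-population layout
#'
#' A synthetic planar layout of nine populations whose minimum and maximum
#' pairwise distances (0.84 and 19.64 km) match the published range for the
#' Carpathian *Taxus baccata* remnants. The coordinates themselves are
#' synthetic — the true site coordinates are not public — so only the
#' distance range, not the geometry, mirrors the real system.
#'
#' @param doubled if `TRUE`, append the nine mirror images of the original
#'   populations through their barycenter, giving a point-symmetric
#'   18-population layout.
#' @return a [spatial_layout()].
#' @export
yew_layout <- function(doubled = FALSE) {
  xy <- matrix(c(
    0.0000, 0.0000,
    0.7513, 0.3757,
    3.4500, 2.1685,
    5.9142, 0.9857,
    8.3785, 3.9428,
    10.8427, 2.4643,
    13.7998, 5.4214,
    16.2641, 2.9571,
    18.7284, 5.9142), ncol = 2, byrow = TRUE)
  ids <- paste0("P", seq_len(9))
  if (doubled) {
    ctr <- colMeans(xy)
    mirrored <- sweep(-xy, 2, 2 * ctr, "+")   # 2*barycenter - x
    xy <- rbind(xy, mirrored)
    ids <- c(ids, paste0("M", seq_len(9)))
  }
  spatial_layout(coords = xy, pop_ids = ids)
}

#' Read a population distance matrix
#'
#' Square CSV with a header row and a leading column of population ids;
#' distances in km (a `unit` multiplier converts other units).
#'
#' @param path file path.
#' @param unit multiplier applied to all entries (e.g. `1e-3` for metres).
#' @return a [spatial_layout()].
#' @export
read_distances <- function(path, unit = 1) {
  tab <- read.table(path, header = TRUE, sep = ",", row.names = 1,
                    check.names = FALSE)
  D <- as.matrix(tab) * unit
  spatial_layout(dist = D, pop_ids = rownames(tab))
}

#' Read population coordinates
#'
#' CSV with columns `id,x,y` (km); Euclidean pairwise distances are computed.
#'
#' @inheritParams read_distances
#' @return a [spatial_layout()].
#' @export
read_coords <- function(path, unit = 1) {
  tab <- read.table(path, header = TRUE, sep = ",")
  xy <- as.matrix(tab[, c("x", "y")]) * unit
  spatial_layout(coords = xy, pop_ids = as.character(tab$id))
}

#' Write a distance matrix in the format read by [read_distances()]
#' @param layout a [spatial_layout()].
#' @param path file path.
#' @export
write_distances <- function(layout, path) {
  df <- data.frame(id = layout$pop_ids, layout$dist, check.names = FALSE)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
}
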