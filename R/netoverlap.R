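# Spatial similarity between component maps and reference network maps:
# Pearson correlation, voxel-coordinate permutation null, Dice overlap,
# library matching at the |r| > 0.25 rule, and time-series inter-correlation.

map_values <- function(m, mask = NULL) {
  if (inherits(m, "zmap")) m <- m$z
  if (!is.null(dim(m)) && !is.null(mask)) m[mask] else as.numeric(m)
}

#' Spatial Pearson correlation of two maps over a mask
#'
#' @param mapA,mapB numeric arrays or vectors on the same grid.
#' @param mask optional logical array restricting the comparison.
#' @return Pearson r.
#' @export
spatial_correlation <- function(mapA, mapB, mask = NULL) {
  a <- map_values(mapA, mask); b <- map_values(mapB, mask)
  if (length(a) != length(b)) stop("maps are not on a shared grid")
  if (length(a) < 10) stop("need at least 10 in-mask voxels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant map: correlation undefined")
  stats::cor(a, b)
}

#' Voxel-coordinate permutation null for spatial correlation
#'
#' Builds the null by randomly reassigning mapB's in-mask values to in-mask
#' coordinates (destroying spatial structure, preserving the value
#' histogram) and compares the observed |r| against the null |r|
#' distribution with the add-one rule.
#'
#' @param mapA,mapB,mask as in [spatial_correlation()].
#' @param n_perm number of permutations (default 1000; < 100 records a
#'   warning in the result).
#' @param seed integer seed.
#' @return object of class `overlap_result`: `r`, `p_perm`, `null_mean`,
#'   `null_ci` (2.5/97.5 percentiles), `n_perm`, `seed`, `warnings`.
#' @export
permutation_null <- function(mapA, mapB, mask = NULL, n_perm = 1000L,
                             seed = 1) {
  a <- map_values(mapA, mask); b <- map_values(mapB, mask)
  r_obs <- spatial_correlation(a, b)
  warn <- character(0)
  if (n_perm < 100)
    warn <- c(warn, sprintf("n_perm = %d is below 100; p-values are coarse", n_perm))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) sample(b), numeric(length(b)))
  r_null <- as.numeric(stats::cor(a, perm))
  p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (n_perm + 1)
  structure(list(r = r_obs, p_perm = p,
                 null_mean = mean(r_null),
                 null_ci = stats::quantile(r_null, c(0.025, 0.975),
                                           names = FALSE),
                 n_perm = n_perm, seed = seed, warnings = warn),
            class = "overlap_result")
}

#' Dice coefficient of two binary supports
#'
#' 2|A and B| / (|A| + |B|); defined as 0 (with a warning) when both
#' supports are empty.
#'
#' @param binA,binB logical arrays/vectors on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(binA, binB) {
  a <- as.logical(binA); b <- as.logical(binB)
  if (length(a) != length(b)) stop("supports are not on a shared grid")
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    warning("both supports are empty; Dice defined as 0")
    return(0)
  }
  2 * sum(a & b) / denom
}

#' Match component maps against a library of reference networks
#'
#' Computes all pairwise spatial correlations between component maps and
#' reference maps (same grid required), flags pairs with |r| above the
#' similarity threshold, and reports the best match per component.
#'
#' @param components K x voxels matrix, list of vectors, or `component_set`.
#' @param library L x voxels matrix or list of reference maps.
#' @param r_threshold similarity rule (default 0.25).
#' @return data.frame per component: `best_match`, `best_r`, `n_flagged`;
#'   full correlation matrix in attribute `r_matrix`, flagged pairs in
#'   attribute `flagged` (data.frame component/reference/r).
#' @export
match_components <- function(components, library, r_threshold = 0.25) {
  as_rows <- function(m) {
    if (inherits(m, "component_set")) return(m$spatial_maps)
    if (is.list(m)) return(do.call(rbind, lapply(m, as.numeric)))
    if (is.vector(m)) return(matrix(m, nrow = 1))
    as.matrix(m)
  }
  M <- as_rows(components); Lb <- as_rows(library)
  if (ncol(M) != ncol(Lb)) stop("component and library maps are not on a shared grid")
  R <- stats::cor(t(M), t(Lb))
  flags <- which(abs(R) > r_threshold, arr.ind = TRUE)
  flagged <- data.frame(component = flags[, 1], reference = flags[, 2],
                        r = R[flags])
  best <- apply(abs(R), 1, which.max)
  out <- data.frame(component = seq_len(nrow(M)),
                    best_match = best,
                    best_r = R[cbind(seq_len(nrow(M)), best)],
                    n_flagged = vapply(seq_len(nrow(M)), function(k)
                      sum(abs(R[k, ]) > r_threshold), integer(1)))
  attr(out, "r_matrix") <- R
  attr(out, "flagged") <- flagged
  attr(out, "r_threshold") <- r_threshold
  out
}

#' Inter-correlation of a selected set of network time series
#'
#' Tests whether the mean pairwise correlation of a selected set of series
#' exceeds that of randomly drawn same-size sets from the full collection
#' (rank-based p with the add-one rule).
#'
#' @param series T x m matrix of the selected series (m >= 3), or column
#'   indices into `collection`.
#' @param collection T x M matrix of all available series.
#' @param n_perm number of random sets (default 1000).
#' @param seed integer seed.
#' @return list: `mean_r`, `p_perm`, `null_mean`, `n_perm`.
#' @export
timeseries_intercorrelation <- function(series, collection, n_perm = 1000L,
                                        seed = 1) {
  if (is.numeric(series) && is.null(dim(series)))
    series <- collection[, series, drop = FALSE]
  m <- ncol(series)
  if (m < 3) stop("need at least 3 series in the selected set")
  if (m > ncol(collection)) stop("selected set exceeds the collection size")
  if (nrow(series) != nrow(collection)) stop("series lengths differ")
  mean_offdiag <- function(ts) {
    R <- stats::cor(ts)
    mean(R[upper.tri(R)])
  }
  obs <- mean_offdiag(series)
  set.seed(seed)
  nullr <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(ncol(collection), m)
    mean_offdiag(collection[, idx, drop = FALSE])
  }, numeric(1))
  p <- (1 + sum(nullr >= obs)) / (n_perm + 1)
  list(mean_r = obs, p_perm = p, null_mean = mean(nullr), n_perm = n_perm)
}
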