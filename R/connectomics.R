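# Healthy-reference connectomes: subject correlation matrices, Fisher-z
# group averaging, a simplified voxel-wise seed-connectivity t-map, and
# ACP-derived effective anatomical distances / graph geodesics.

#' Pairwise ROI correlation matrix for one subject
#'
#' @param timeseries T x n matrix of regional time series (T >= 3).
#' @return n x n symmetric Pearson correlation matrix.
#' @export
subject_correlation_matrix <- function(timeseries) {
  ts <- as.matrix(timeseries)
  if (nrow(ts) < 3) stop("need at least 3 time points")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- colnames(ts)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop(sprintf("constant time series for region(s): %s",
                 paste(nm, collapse = ", ")))
  }
  stats::cor(ts)
}

#' Fisher-z group average of subject connectivity matrices
#'
#' Element-wise z = atanh(r), averaged over subjects, back-transformed with
#' tanh: `R_group = tanh(mean(atanh(R_subject)))`. The diagonal is excluded
#' from averaging and set to 1 by convention (atanh(1) is undefined).
#'
#' @param subject_matrices list of same-shape correlation matrices with
#'   off-diagonal entries in (-1, 1).
#' @param clamp if TRUE, off-diagonal |r| = 1 entries are clamped to
#'   1 - `eps` instead of raising an error.
#' @param eps clamping margin.
#' @return object of class `functional_connectome`: `R_group`,
#'   `n_subjects`, `region_ids`.
#' @export
fisher_group_average <- function(subject_matrices, clamp = FALSE,
                                 eps = 1e-7) {
  mats <- lapply(subject_matrices, as.matrix)
  d <- dim(mats[[1]])
  if (d[1] != d[2]) stop("matrices must be square")
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("all subject matrices must have the same shape")
  n <- d[1]
  off <- !diag(n)
  mats <- lapply(mats, function(m) {
    if (any(abs(m[off]) >= 1)) {
      if (!clamp)
        stop("off-diagonal |r| >= 1: Fisher z is infinite (set clamp = TRUE to clamp)")
      m[off] <- pmin(pmax(m[off], -1 + eps), 1 - eps)
    }
    m
  })
  zsum <- matrix(0, n, n)
  for (m in mats) zsum <- zsum + atanh(m * off)
  R <- tanh(zsum / length(mats))
  # cells on which every subject agrees are fixed points of the transform;
  # return them exactly (tanh/atanh round trips are not bit-exact)
  lo <- Reduce(pmin, mats); hi <- Reduce(pmax, mats)
  same <- lo == hi
  R[same] <- mats[[1]][same]
  diag(R) <- 1
  ids <- rownames(mats[[1]]) %||% seq_len(n)
  structure(list(R_group = R, n_subjects = length(mats), region_ids = ids),
            class = "functional_connectome")
}

#' Group seed-connectivity t-map
#'
#' Simplified seed-based connectivity: per subject, each voxel's time
#' series is correlated with the mean series over the seed voxels, the
#' correlations are Fisher-z transformed, and a one-sample t-statistic is
#' computed across subjects per voxel. A parametric two-sided threshold is
#' available in place of random-field machinery.
#'
#' @param voxel_timeseries list of per-subject T x voxels matrices.
#' @param seed_voxels integer indices (or logical vector) of seed voxels.
#' @param alpha optional two-sided parametric threshold to apply.
#' @return list: `t` (per-voxel t), `df`, `mean_z`, and if `alpha` given,
#'   `significant` (logical per voxel) and `t_cutoff`.
#' @export
seed_connectivity_map <- function(voxel_timeseries, seed_voxels,
                                  alpha = NULL) {
  if (length(voxel_timeseries) < 2) stop("need at least 2 subjects")
  if (is.logical(seed_voxels)) seed_voxels <- which(seed_voxels)
  if (length(seed_voxels) == 0) stop("seed mask is empty")
  zs <- vapply(voxel_timeseries, function(ts) {
    seed_series <- rowMeans(ts[, seed_voxels, drop = FALSE])
    r <- as.numeric(stats::cor(seed_series, ts))
    atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  }, numeric(ncol(voxel_timeseries[[1]])))
  zs <- t(zs)                                # subjects x voxels
  N <- nrow(zs)
  mz <- colMeans(zs)
  sdz <- apply(zs, 2, stats::sd)
  tv <- mz / (sdz / sqrt(N))
  out <- list(t = tv, df = N - 1, mean_z = mz)
  if (!is.null(alpha)) {
    cut <- stats::qt(1 - alpha / 2, df = N - 1)
    out$significant <- abs(tv) >= cut
    out$t_cutoff <- cut
  }
  out
}

#' Effective anatomical distances from an ACP matrix
#'
#' Converts anatomical connection probabilities into edge lengths
#' (default -log ACP, so shortest paths are most-probable paths under
#' independence) and computes all-pairs shortest-path lengths; region pairs
#' with no connecting path get Inf.
#'
#' @param acp symmetric matrix in [0, 1] with zero diagonal; 0 = no edge.
#' @param transform `"neg_log"` (default), `"one_minus"`, or `"reciprocal"`.
#' @return object of class `structural_connectome`: `acp`,
#'   `effective_distance`, `edge_length_transform`.
#' @export
acp_effective_distance <- function(acp,
                                   transform = c("neg_log", "one_minus",
                                                 "reciprocal")) {
  transform <- match.arg(transform)
  acp <- as.matrix(acp)
  if (!isTRUE(all.equal(acp, t(acp), tolerance = 1e-10)))
    stop("ACP matrix must be symmetric")
  if (any(acp < 0 | acp > 1)) stop("ACP values must lie in [0, 1]")
  if (any(diag(acp) != 0)) stop("ACP diagonal must be zero")
  n <- nrow(acp)
  w <- matrix(0, n, n)
  pos <- acp > 0
  w[pos] <- switch(transform,
                   neg_log = -log(acp[pos]),
                   one_minus = 1 - acp[pos],
                   reciprocal = 1 / acp[pos])
  # build from an explicit edge list: -log(1) = 0 edges are legitimate
  # zero-length links and must not be dropped as "no edge"
  ut <- pos & upper.tri(pos)
  edges <- which(ut, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, as.vector(t(edges)))
  ew <- w[which(ut)]                        # column-major, same order as edges
  D <- if (nrow(edges) > 0)
    igraph::distances(g, weights = ew, algorithm = "dijkstra")
  else igraph::distances(g)
  D <- unclass(D)
  dimnames(D) <- dimnames(acp)
  structure(list(acp = acp, effective_distance = D,
                 edge_length_transform = transform),
            class = "structural_connectome")
}

#' Hop-count geodesic distances of a graph
#'
#' Breadth-first number of edges separating each pair of nodes; Inf for
#' disconnected pairs.
#'
#' @param adjacency symmetric binary (or thresholded-to-nonzero) matrix.
#' @return matrix of hop counts.
#' @export
graph_geodesic <- function(adjacency) {
  A <- as.matrix(adjacency) != 0
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  D <- igraph::distances(g, weights = NA)
  unclass(D)
}

#' Euclidean distances between parcellation centroids
#'
#' Pairwise distances (mm, template space via voxel spacing) between the
#' region centroids of a parcellation.
#'
#' @param parcellation a [make_parcellation()] result, or a data.frame with
#'   columns x/y/z in mm.
#' @return symmetric matrix of distances with zero diagonal.
#' @export
euclidean_centroid_distances <- function(parcellation) {
  tab <- if (inherits(parcellation, "parcellation")) parcellation$table
         else parcellation
  if (nrow(tab) < 2) stop("need at least 2 regions")
  if (any(!is.finite(as.matrix(tab[, c("x", "y", "z")]))))
    stop("missing centroid for an empty region")
  D <- as.matrix(stats::dist(tab[, c("x", "y", "z")]))
  dimnames(D) <- list(tab$region, tab$region)
  D
}
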