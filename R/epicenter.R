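# Propagation test: regional age-corrected atrophy t-scores, correlation of
# atrophy with connectivity/distance to a candidate epicenter (with optional
# Euclidean-proximity control), and ranking of every region as a propagator.

#' Age-corrected regional atrophy profile
#'
#' For each region, fits regional mean DBM ~ group + age by OLS and takes
#' the group coefficient's t-statistic, oriented so that negative t means
#' greater atrophy (lower DBM) in patients.
#'
#' @param regional_mat subjects x regions matrix of regional mean DBM values.
#' @param groups two-level factor (patients vs controls, >= 3 each).
#' @param ages numeric vector of subject ages.
#' @return an [atrophy_profile()].
#' @export
regional_atrophy <- function(regional_mat, groups, ages) {
  M <- as.matrix(regional_mat)
  g <- as_two_groups(groups)
  if (any(table(g) < 3)) stop("each group must have at least 3 subjects")
  if (length(ages) != nrow(M)) stop("ages length must match subjects")
  X <- stats::model.matrix(~ g + ages)
  check_full_rank(X)
  # one decomposition reused across regions
  XtXinv <- solve(crossprod(X))
  coefs <- XtXinv %*% crossprod(X, M)
  resid <- M - X %*% coefs
  dfree <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / dfree
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tv <- coefs[2, ] / se
  atrophy_profile(tv,
                  region_ids = colnames(M) %||% seq_len(ncol(M)),
                  n_per_group = stats::setNames(as.numeric(table(g)),
                                                levels(g)))
}

# extract the per-region predictor for a candidate seed: connectivity
# column (functional) or effective-distance column (structural)
seed_predictor <- function(connectome, seed_region,
                           mode = c("functional", "structural")) {
  mode <- match.arg(mode)
  if (mode == "functional") {
    R <- if (inherits(connectome, "functional_connectome"))
      connectome$R_group else as.matrix(connectome)
    R[, seed_region]
  } else {
    D <- if (inherits(connectome, "structural_connectome"))
      connectome$effective_distance else as.matrix(connectome)
    D[, seed_region]
  }
}

#' Epicenter correlation
#'
#' Correlates per-region atrophy severity (-t, so larger = more atrophy)
#' with each region's connectivity to the candidate epicenter (functional
#' mode) or effective anatomical distance to it (structural mode). With this
#' orientation a true functional epicenter yields a positive r and a true
#' structural (distance) epicenter a negative r. The seed itself is excluded
#' (its self-connectivity is undefined); structural-mode regions at infinite
#' distance are excluded pairwise with the count recorded.
#'
#' @param atrophy an [atrophy_profile()] (or numeric t-score vector).
#' @param connectome functional connectome (matrix or
#'   `functional_connectome`) or `structural_connectome`/distance matrix.
#' @param seed_region candidate epicenter index.
#' @param mode `"functional"` or `"structural"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list: `r`, `p` (two-sided), `n_used`, `n_excluded`, `mode`,
#'   `method`.
#' @export
epicenter_correlation <- function(atrophy, connectome, seed_region,
                                  mode = c("functional", "structural"),
                                  method = c("pearson", "spearman")) {
  mode <- match.arg(mode); method <- match.arg(method)
  sev <- atrophy_severity(atrophy)
  pred <- seed_predictor(connectome, seed_region, mode)
  if (length(pred) != length(sev))
    stop("connectome and atrophy profile have different region counts")
  keep <- setdiff(seq_along(sev), seed_region)
  excl <- 0L
  if (mode == "structural") {
    inf_idx <- keep[!is.finite(pred[keep])]
    excl <- length(inf_idx)
    keep <- setdiff(keep, inf_idx)
  }
  if (length(keep) < 10) stop("fewer than 10 usable regions")
  ct <- stats::cor.test(pred[keep], sev[keep], method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n_used = length(keep),
       n_excluded = excl, mode = mode, method = method)
}

#' Epicenter partial correlation controlling Euclidean proximity
#'
#' Partial Pearson correlation of (connectivity-or-distance, atrophy
#' severity) given Euclidean distance to the seed, computed by residualising
#' both variables on the covariate by OLS and correlating the residuals.
#'
#' @inheritParams epicenter_correlation
#' @param euclid symmetric matrix of centroid Euclidean distances (mm).
#' @return list: `partial_r`, `p` (two-sided, n - 3 df), `n_used`, `mode`.
#' @export
epicenter_partial_correlation <- function(atrophy, connectome, seed_region,
                                          euclid,
                                          mode = c("functional", "structural")) {
  mode <- match.arg(mode)
  sev <- atrophy_severity(atrophy)
  pred <- seed_predictor(connectome, seed_region, mode)
  ed <- as.matrix(euclid)[, seed_region]
  keep <- setdiff(seq_along(sev), seed_region)
  if (mode == "structural") keep <- keep[is.finite(pred[keep])]
  if (length(keep) < 10) stop("fewer than 10 usable regions")
  z <- ed[keep]
  if (stats::sd(z) == 0) stop("Euclidean covariate is constant")
  res <- function(y) stats::residuals(stats::lm(y ~ z))
  r <- stats::cor(res(pred[keep]), res(sev[keep]))
  n <- length(keep)
  tstat <- r * sqrt((n - 3) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 3)
  list(partial_r = r, p = p, n_used = n, mode = mode)
}

#' Rank every region as a candidate disease propagator
#'
#' Applies [epicenter_correlation()] (or the partial version when `euclid`
#' is supplied) with every region as the seed, and sorts candidates by
#' propagation strength: descending r in functional mode (more positive =
#' stronger propagator), ascending r in structural mode (more negative =
#' stronger, since connectivity there is a distance). Ties break by region
#' id, so the ranking is deterministic.
#'
#' @inheritParams epicenter_correlation
#' @param euclid optional Euclidean distance matrix for proximity control.
#' @return data.frame of class `propagator_ranking`: `region`, `r`, `p`,
#'   `rank`, `mode`, sorted by rank.
#' @export
rank_propagators <- function(atrophy, connectome,
                             mode = c("functional", "structural"),
                             euclid = NULL,
                             method = c("pearson", "spearman")) {
  mode <- match.arg(mode); method <- match.arg(method)
  ids <- if (inherits(atrophy, "atrophy_profile")) atrophy$region_ids
         else seq_along(atrophy)
  n <- length(ids)
  rows <- lapply(seq_len(n), function(sr) {
    if (is.null(euclid)) {
      ec <- epicenter_correlation(atrophy, connectome, sr, mode = mode,
                                  method = method)
      data.frame(region = ids[sr], r = ec$r, p = ec$p, stringsAsFactors = FALSE)
    } else {
      ec <- epicenter_partial_correlation(atrophy, connectome, sr, euclid,
                                          mode = mode)
      data.frame(region = ids[sr], r = ec$partial_r, p = ec$p,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  key <- if (mode == "functional") -out$r else out$r
  ord <- order(key, out$region)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(n)
  out$mode <- mode
  rownames(out) <- NULL
  class(out) <- c("propagator_ranking", class(out))
  out
}
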