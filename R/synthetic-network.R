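# Synthetic network-stage inputs: ROI time series with a known correlation
# structure, and connectome + atrophy pairs with a planted epicenter.

#' Random well-conditioned correlation matrix
#'
#' Low-rank factor model `cov2cor(B B' + diag)`, used as a ground-truth
#' functional connectome for the simulators.
#'
#' @param n number of regions.
#' @param n_factors latent factors controlling the correlation structure.
#' @param strength factor loading scale; larger = stronger correlations.
#' @param seed integer seed.
#' @return symmetric positive-definite correlation matrix with unit diagonal.
#' @export
random_correlation_matrix <- function(n, n_factors = 4, strength = 0.8,
                                      seed = 1) {
  set.seed(seed)
  B <- matrix(stats::rnorm(n * n_factors, 0, strength), n, n_factors)
  stats::cov2cor(tcrossprod(B) + diag(n))
}

#' Simulate per-subject ROI time series with a target correlation
#'
#' Draws stationary multivariate-normal series whose population correlation
#' equals `connectome_truth`, so the Fisher-averaged group connectome
#' converges to the truth as T and the number of subjects grow.
#'
#' @param connectome_truth symmetric PSD matrix with unit diagonal.
#' @param n_subjects number of subjects.
#' @param T_len time points per subject (T > n regions recommended).
#' @param seed integer seed.
#' @return list of `n_subjects` matrices, each `T_len` x n.
#' @export
simulate_roi_timeseries <- function(connectome_truth, n_subjects, T_len,
                                    seed = 1) {
  R <- as.matrix(connectome_truth)
  n <- nrow(R)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
    stop("connectome_truth must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-8))
    stop("connectome_truth must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop(sprintf("connectome_truth is not positive semi-definite (smallest eigenvalue %.3g)",
                 min(ev$values)))
  lam <- pmax(ev$values, 0)
  M <- ev$vectors %*% diag(sqrt(lam), n)    # M M' = R
  set.seed(seed)
  lapply(seq_len(n_subjects), function(s) {
    Z <- matrix(stats::rnorm(T_len * n), T_len, n)
    Z %*% t(M)
  })
}

#' Atrophy-profile container
#'
#' Per-region group-difference statistic (patient minus control, age
#' corrected). Sign convention: negative t = greater atrophy in patients.
#'
#' @param t numeric vector of per-region t-scores.
#' @param region_ids region identifiers.
#' @param n_per_group named vector of group sizes (may be NA for synthetic
#'   profiles generated directly at the t-score level).
#' @return object of class `atrophy_profile`.
#' @export
atrophy_profile <- function(t, region_ids = seq_along(t),
                            n_per_group = c(patient = NA, control = NA)) {
  stopifnot(all(is.finite(t)), length(region_ids) == length(t))
  structure(list(t = as.numeric(t), region_ids = region_ids,
                 n_per_group = n_per_group,
                 sign_convention = "negative = greater atrophy in patients"),
            class = "atrophy_profile")
}

# severity score used by the epicenter analyses: -t, so that larger values
# mean more atrophy and a true functional epicenter yields a positive r
atrophy_severity <- function(profile) {
  if (inherits(profile, "atrophy_profile")) -profile$t else -as.numeric(profile)
}

#' Simulate a connectome and an atrophy profile with a planted epicenter
#'
#' Generates the spread-model ground truth: regional atrophy is a linear
#' function of connectivity to the epicenter (functional mode: more
#' connected = more atrophy = more negative t) or of effective anatomical
#' distance to it (structural mode: larger distance = less atrophy), plus
#' Gaussian noise. `target_r` calibrates `noise_sd` so the attained
#' epicenter correlation magnitude is near a requested scale (e.g. 0.4).
#'
#' @param n_regions number of regions (default 112).
#' @param epicenter planted epicenter region id.
#' @param mode `"functional"` or `"structural"`.
#' @param slope atrophy change per unit connectivity (t-score units, > 0).
#' @param noise_sd residual sd on the t-scores; ignored if `target_r` given.
#' @param target_r if non-NULL, |r| the generator should attain on average.
#' @param density edge density of the structural ACP graph.
#' @param seed integer seed.
#' @return list: `connectome` (functional: correlation matrix; structural:
#'   `structural_connectome` with `acp` and `effective_distance`), `atrophy`
#'   ([atrophy_profile()]), `truth` (epicenter, slope, noise_sd, attained_r).
#' @export
simulate_acp_and_atrophy <- function(n_regions = 112, epicenter = 1,
                                     mode = c("functional", "structural"),
                                     slope = 2, noise_sd = 0,
                                     target_r = NULL, density = 0.3,
                                     seed = 1) {
  mode <- match.arg(mode)
  stopifnot(epicenter >= 1, epicenter <= n_regions, slope > 0, noise_sd >= 0)
  set.seed(seed)
  if (mode == "functional") {
    conn <- random_correlation_matrix(n_regions, seed = seed)
    predictor <- conn[, epicenter]
    connectome <- conn
  } else {
    acp <- matrix(0, n_regions, n_regions)
    upper <- upper.tri(acp)
    edge <- stats::runif(sum(upper)) < density
    w <- stats::runif(sum(upper), 0.05, 0.95) * edge
    acp[upper] <- w
    acp <- acp + t(acp)
    # ensure connectivity with a weak ring so distances are finite
    for (i in seq_len(n_regions)) {
      j <- if (i == n_regions) 1L else i + 1L
      if (acp[i, j] == 0) acp[i, j] <- acp[j, i] <- 0.05
    }
    connectome <- acp_effective_distance(acp, transform = "neg_log")
    predictor <- connectome$effective_distance[, epicenter]
  }
  others <- setdiff(seq_len(n_regions), epicenter)
  x <- predictor[others]
  # functional: severity increases with connectivity; structural: severity
  # decreases with distance
  sgn <- if (mode == "functional") +1 else -1
  signal <- sgn * slope * (x - mean(x))
  if (!is.null(target_r)) {
    stopifnot(target_r > 0, target_r < 1)
    noise_sd <- stats::sd(signal) * sqrt(1 / target_r^2 - 1)
  }
  severity <- signal + stats::rnorm(length(x), 0, noise_sd)
  # baseline shifts severity so t-scores sit in a plausible negative range;
  # the epicenter itself is assigned the largest severity (most atrophied)
  sev_all <- numeric(n_regions)
  sev_all[others] <- severity
  sev_all[epicenter] <- max(severity) + slope * 0.5
  t_scores <- -(sev_all + 1)
  atrophy <- atrophy_profile(t_scores, region_ids = seq_len(n_regions))
  attained <- stats::cor(x, severity)
  truth <- list(epicenter_index = epicenter, mode = mode, slope = slope,
                noise_sd = noise_sd, attained_r = attained)
  list(connectome = connectome, atrophy = atrophy, truth = truth)
}
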