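# Synthetic-data generators: parcellation, super-Gaussian source maps,
# cohort with planted disease component and correlated covariates, and
# displacement fields reproducing target DBM maps.

#' Synthetic parcellation of a spherical mask
#'
#' Partitions the in-mask voxels into `n_regions` compact regions by k-means
#' on voxel coordinates (Voronoi-like patches), emulating an anatomical
#' atlas with labelled structures. Label 0 is background.
#'
#' @param grid_shape integer vector of length 3.
#' @param n_regions number of regions (>= 2); the analysis default is 112.
#' @param seed integer seed; the result is reproducible bit-for-bit.
#' @param spacing voxel dimensions in mm.
#' @return object of class `parcellation`: `labels` (3-D integer array),
#'   `table` (data.frame: region, name, x/y/z centroid in mm, n_voxels),
#'   `mask`, `spacing`.
#' @export
make_parcellation <- function(grid_shape, n_regions, seed = 1,
                              spacing = c(1, 1, 1)) {
  stopifnot(n_regions >= 2)
  mask <- spherical_mask(grid_shape)
  nvox <- sum(mask)
  if (nvox < 8 * n_regions)
    stop(sprintf(
      "grid too small for %d regions: %d in-mask voxels < %d required (8 per region)",
      n_regions, nvox, 8 * n_regions))
  co <- mask_coords(mask)
  set.seed(seed)
  km <- stats::kmeans(co, centers = n_regions, iter.max = 300L,
                      nstart = 1L, algorithm = "Lloyd")
  labels <- array(0L, grid_shape)
  labels[mask] <- as.integer(km$cluster)
  sizes <- tabulate(km$cluster, nbins = n_regions)
  if (any(sizes < 1L))
    stop("parcellation produced an empty region; enlarge the grid")
  cent <- km$centers * matrix(rep_len(spacing, 3), n_regions, 3, byrow = TRUE)
  tab <- data.frame(region = seq_len(n_regions),
                    name = sprintf("R%03d", seq_len(n_regions)),
                    x = cent[, 1], y = cent[, 2], z = cent[, 3],
                    n_voxels = sizes)
  structure(list(labels = labels, table = tab, mask = mask,
                 spacing = as.numeric(rep_len(spacing, 3))),
            class = "parcellation")
}

# Build K sparse super-Gaussian spatial source maps on the mask.
# Each source is a smooth random field restricted to its own k-means patch
# of the mask (so distinct sources have disjoint supports), weighted by a
# Gaussian window around the patch centre, then soft-thresholded until its
# excess kurtosis over the mask exceeds `min_excess_kurtosis`; sign flipped
# to positive skew and peak scaled to 1.
simulate_sources <- function(mask, K, seed, window_sigma = 3,
                             field_sigma = 1.5, min_excess_kurtosis = 4) {
  set.seed(seed)
  co <- mask_coords(mask)
  km <- stats::kmeans(co, centers = K, iter.max = 300L, nstart = 1L,
                      algorithm = "Lloyd")
  centers <- km$centers
  membership <- km$cluster
  dims <- dim(mask)
  sources <- matrix(0, nrow = K, ncol = sum(mask))
  for (k in seq_len(K)) {
    raw <- smooth_volume(array(stats::rnorm(prod(dims)), dims), field_sigma)
    d2 <- array(0, dims)
    for (a in 1:3) d2 <- d2 + (slice.index(d2, a) - centers[k, a])^2
    win <- exp(-d2 / (2 * window_sigma^2))
    s <- (raw * win)[mask]
    s[membership != k] <- 0
    s <- s / max(abs(s))
    # raise the soft threshold until the map is sufficiently sparse
    thr <- 0
    repeat {
      st <- sign(s) * pmax(abs(s) - thr, 0)
      if (any(st != 0) &&
          moment_kurtosis(st) - 3 > min_excess_kurtosis) break
      thr <- thr + 0.02
      if (thr > 0.95) { st <- sign(s) * pmax(abs(s) - 0.95, 0); break }
    }
    if (sample_skewness(st) < 0) st <- -st
    sources[k, ] <- st / max(abs(st))
  }
  sources
}

#' Simulate a DBM cohort with a planted disease component
#'
#' Generates per-subject DBM maps under the linear mixing model that spatial
#' ICA inverts: map = sum_k loading_{sk} * source_k + Gaussian noise.
#' Exactly one component (the disease component) carries a group effect:
#' patient loadings are shifted down by `d` within-group standard deviations
#' (lower loading = more atrophy). Loadings of the disease component are
#' negatively correlated with age; motor severity (UPDRS-III) and striatal
#' binding ratio covariates are generated with the requested correlations to
#' the disease loading. Defaults reproduce the reference cohort: 232
#' patients / 117 controls, 30 components, age/UPDRS/SBR correlation scales
#' of -0.38 / -0.22 / +0.23.
#'
#' @param n_patients,n_controls group sizes (each >= 4).
#' @param K number of spatial components (>= 2).
#' @param d standardised group difference on the disease component (>= 0).
#' @param grid_shape voxel grid, default `c(24, 24, 24)`.
#' @param noise_sd per-voxel residual noise sd, on the loading/source scale
#'   (the signal-to-noise ratio is independent of `map_scale`).
#' @param map_scale amplitude converting the unit-scale mixing model to
#'   relative volume change; 0.15 keeps |J|-1 values in a physical range
#'   (well above -1).
#' @param age_r,updrs_r,sbr_r target loading-covariate correlations
#'   (patients; controls use `sbr_r_control`).
#' @param sbr_r_control SBR-loading correlation in controls.
#' @param n_sites number of acquisition sites.
#' @param site_sd sd of a per-site mean offset added to all loadings
#'   (0 = no site effect).
#' @param seed integer seed.
#' @return object of class `synthetic_cohort`: `records` (covariate
#'   data.frame), `maps` (list of [dbm_map()]), `truth` (ground truth:
#'   `source_maps` K x voxels, `loadings`, `disease_component_index`,
#'   `covariate_effects`, `noise_sd`), `mask`, `seed`.
#' @export
simulate_cohort <- function(n_patients = 232, n_controls = 117, K = 30,
                            d = 1, grid_shape = c(24, 24, 24),
                            noise_sd = 0.25, map_scale = 0.15,
                            age_r = -0.38, updrs_r = -0.22, sbr_r = 0.23,
                            sbr_r_control = 0.33,
                            n_sites = 4, site_sd = 0, seed = 1) {
  num_par <- c(n_patients, n_controls, K, d, noise_sd, age_r, updrs_r,
               sbr_r, sbr_r_control, n_sites, site_sd, seed)
  if (any(!is.finite(num_par))) stop("all generation parameters must be finite")
  stopifnot(K >= 2, d >= 0, n_patients >= 4, n_controls >= 4,
            abs(age_r) < 1, abs(updrs_r) < 1, abs(sbr_r) < 1)
  n <- n_patients + n_controls
  if (n < K) stop("need at least K subjects to identify K components")
  mask <- spherical_mask(grid_shape)
  sources <- simulate_sources(mask, K, seed = seed + 1L)

  set.seed(seed)
  group <- factor(rep(c("patient", "control"), c(n_patients, n_controls)),
                  levels = c("control", "patient"))
  is_pat <- group == "patient"
  age <- numeric(n)
  age[is_pat] <- stats::rnorm(n_patients, 61.2, 9.1)
  age[!is_pat] <- stats::rnorm(n_controls, 59.7, 11.3)
  sex <- factor(ifelse(stats::runif(n) < ifelse(is_pat, 0.668, 0.632),
                       "M", "F"), levels = c("F", "M"))
  site <- factor(sample(seq_len(n_sites), n, replace = TRUE))

  # loadings: independent N(0,1) per component; the disease component gets a
  # group shift of -d (patients) and an age slope giving correlation age_r
  loadings <- matrix(stats::rnorm(n * K), n, K)
  k_dis <- sample.int(K, 1L)
  z_age <- as.numeric(scale(age))
  l_dis <- ifelse(is_pat, -d, 0) +
    age_r * z_age + sqrt(1 - age_r^2) * stats::rnorm(n)
  loadings[, k_dis] <- l_dis
  if (site_sd > 0) {
    offs <- stats::rnorm(n_sites, 0, site_sd)
    loadings <- loadings + offs[as.integer(site)]
  }

  corr_noise <- function(target, r) {
    # a variable with correlation ~r to `target` (both standardised draws)
    z <- as.numeric(scale(target))
    r * z + sqrt(1 - r^2) * stats::rnorm(length(target))
  }
  updrs3 <- integer(n)
  updrs3[is_pat] <- pmax(0L, as.integer(round(
    21.9 + 9.1 * (-corr_noise(l_dis[is_pat], -updrs_r)))))
  updrs3[!is_pat] <- pmax(0L, as.integer(round(stats::rnorm(n_controls, 1, 1.2))))
  sbr <- numeric(n)
  sbr[is_pat] <- pmax(0.1, 1.4 + 0.4 * corr_noise(l_dis[is_pat], sbr_r))
  sbr[!is_pat] <- pmax(0.1, 2.6 + 0.6 * corr_noise(l_dis[!is_pat], sbr_r_control))
  duration <- ifelse(is_pat, pmax(0, stats::rnorm(n, 6.9, 7.1)), NA_real_)

  records <- data.frame(id = sprintf("S%04d", seq_len(n)),
                        group = group, age = age, sex = sex, site = site,
                        updrs3 = updrs3, sbr = sbr, duration = duration,
                        stringsAsFactors = FALSE)

  stopifnot(map_scale > 0)
  signal <- loadings %*% sources                      # n x voxels
  signal <- map_scale * (signal + noise_sd * matrix(stats::rnorm(length(signal)),
                                                    nrow(signal), ncol(signal)))
  maps <- vector("list", n)
  for (s in seq_len(n)) {
    vol <- array(0, grid_shape)
    vol[mask] <- signal[s, ]
    maps[[s]] <- dbm_map(vol, mask = mask,
                         provenance = list(subject = records$id[s],
                                           spacing = c(1, 1, 1)))
  }
  truth <- list(source_maps = sources, loadings = loadings,
                disease_component_index = k_dis,
                covariate_effects = c(age = age_r, updrs3 = updrs_r,
                                      sbr = sbr_r, group = -d),
                epicenter_index = NA_integer_, spread_slope = NA_real_,
                noise_sd = noise_sd)
  structure(list(records = records, maps = maps, truth = truth,
                 mask = mask, seed = seed,
                 params = list(n_patients = n_patients,
                               n_controls = n_controls, K = K, d = d,
                               grid_shape = grid_shape, noise_sd = noise_sd)),
            class = "synthetic_cohort")
}

#' Construct displacement fields whose DBM maps reproduce target maps
#'
#' The inverse of the DBM step, for end-to-end testing: for each subject's
#' target map t (the wanted |J|-1), builds the field u1(x) = trapezoidal
#' cumulative integral of t along the first axis, u2 = u3 = 0. Rows 2 and 3
#' of I + J are then unit rows, so det(I + J) - 1 equals the central
#' difference of u1 along x1, a locally smoothed copy of t: the round trip
#' through [jacobian_determinant_map()] reproduces smooth targets to within
#' a small interior tolerance, and constants exactly.
#'
#' @param cohort a `synthetic_cohort` (or a list of [dbm_map()]).
#' @return the cohort with a `fields` list of [displacement_field()] added.
#' @export
maps_to_displacement_fields <- function(cohort) {
  maps <- if (inherits(cohort, "synthetic_cohort")) cohort$maps else cohort
  fields <- lapply(maps, function(m) {
    t_map <- m$values
    if (any(t_map[m$mask] <= -1))
      stop("target map has values <= -1 (non-physical volume collapse)")
    delta <- m$provenance$spacing %||% c(1, 1, 1)
    u1 <- trapezoid_cumsum_axis1(t_map) * delta[1]
    u <- array(0, c(dim(t_map), 3))
    u[, , , 1] <- u1
    displacement_field(u, spacing = delta, mask = m$mask,
                       subject = m$provenance$subject %||% NA_character_)
  })
  if (inherits(cohort, "synthetic_cohort")) {
    cohort$fields <- fields
    cohort
  } else fields
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# trapezoidal cumulative sum along the first axis:
# C[1]=t[1]; C[i]=C[i-1]+(t[i-1]+t[i])/2, so the central difference
# (C[i+1]-C[i-1])/2 = (t[i-1]+2 t[i]+t[i+1])/4 (exact for constants)
trapezoid_cumsum_axis1 <- function(t_map) {
  d <- dim(t_map)
  m <- matrix(t_map, d[1], d[2] * d[3])
  cm <- apply(m, 2, function(col) {
    if (length(col) == 1) return(col)
    cumsum(c(col[1], (col[-length(col)] + col[-1]) / 2))
  })
  array(cm, d)
}
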