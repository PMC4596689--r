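# Synthetic-data generators: parcellation, cohort with planted disease
# component, displacement-field construction, ROI time series, and the
# connectome/atrophy spread simulator.

test_that("parcellation partitions the mask into the requested regions", {
  p <- make_parcellation(c(24, 24, 24), n_regions = 112, seed = 1)
  expect_equal(nrow(p$table), 112)
  expect_true(all(p$table$n_voxels >= 1))
  expect_equal(sort(unique(p$labels[p$mask])), 1:112)
  # centroids lie inside the bounding box of the mask
  co <- which(p$mask, arr.ind = TRUE)
  expect_true(all(p$table$x >= min(co[, 1]) & p$table$x <= max(co[, 1])))

  p2 <- make_parcellation(c(8, 8, 8), n_regions = 2, seed = 0)
  expect_true(all(p2$labels[p2$mask] %in% 1:2))   # union = mask
  expect_true(all(p2$labels[!p2$mask] == 0))      # background intact
  expect_equal(sum(p2$table$n_voxels), sum(p2$mask))

  pa <- make_parcellation(c(16, 16, 16), n_regions = 10, seed = 7)
  pb <- make_parcellation(c(16, 16, 16), n_regions = 10, seed = 7)
  expect_identical(pa$labels, pb$labels)

  expect_error(make_parcellation(c(4, 4, 4), n_regions = 50, seed = 1),
               "too small")
})

test_that("cohort plants the requested group effect and covariate structure", {
  ch <- simulate_cohort(n_patients = 100, n_controls = 100, K = 8, d = 1,
                        grid_shape = c(16, 16, 16), seed = 3)
  kd <- ch$truth$disease_component_index
  l <- ch$truth$loadings[, kd]
  g <- ch$records$group
  sp <- sqrt((99 * var(l[g == "patient"]) + 99 * var(l[g == "control"])) / 198)
  d_emp <- (mean(l[g == "control"]) - mean(l[g == "patient"])) / sp
  expect_gt(d_emp, 0.7)
  expect_lt(d_emp, 1.3)

  # covariate correlations near their targets (Monte-Carlo tolerance 3/sqrt(n))
  pat <- g == "patient"
  expect_lt(abs(cor(l, ch$records$age) - (-0.38)), 3 / sqrt(200))
  expect_lt(abs(cor(l[pat], ch$records$updrs3[pat]) - (-0.22)), 3 / sqrt(100))
  expect_lt(abs(cor(l[pat], ch$records$sbr[pat]) - 0.23), 3 / sqrt(100))

  # loadings of distinct components are independent draws: near-zero r
  CC <- cor(ch$truth$loadings)
  diag(CC) <- 0
  expect_lt(max(abs(CC)), 4 / sqrt(200))

  # sources are super-Gaussian in the strict excess sense
  kk <- check_super_gaussianity(ch$truth$source_maps)
  expect_true(all(kk$excess_kurtosis > 4))
  expect_true(all(kk$pass))

  # maps stay physical
  rng <- range(vapply(ch$maps, function(m) range(m$values), numeric(2)))
  expect_gt(rng[1], -1)
})

test_that("null cohort (d = 0) has no planted group difference", {
  ch <- simulate_cohort(n_patients = 60, n_controls = 60, K = 4, d = 0,
                        grid_shape = c(12, 12, 12), seed = 11)
  gt <- component_group_test(ch$truth$loadings, ch$records$group)
  expect_true(all(gt$p_bonferroni > 0.05))
})

test_that("cohort generation is reproducible bit-for-bit", {
  a <- simulate_cohort(n_patients = 6, n_controls = 6, K = 3,
                       grid_shape = c(10, 10, 10), seed = 5)
  b <- simulate_cohort(n_patients = 6, n_controls = 6, K = 3,
                       grid_shape = c(10, 10, 10), seed = 5)
  expect_identical(a$maps[[1]]$values, b$maps[[1]]$values)
  expect_identical(a$records, b$records)
  expect_error(simulate_cohort(d = NA, seed = 1), "finite")
})

test_that("displacement-field construction round-trips through the DBM map", {
  gs <- c(16, 16, 16)
  mask <- spherical_mask(gs)
  mk_map <- function(vals) dbm_map(vals, mask = mask,
                                   provenance = list(spacing = c(1, 1, 1)))
  int <- function(v) v[3:14, 3:14, 3:14]

  # zero target -> zero field
  f0 <- maps_to_displacement_fields(list(mk_map(array(0, gs))))[[1]]
  expect_true(all(f0$u == 0))

  # constant target 0.331 reproduced exactly in the interior
  fc <- maps_to_displacement_fields(list(mk_map(array(0.331, gs))))[[1]]
  m <- jacobian_determinant_map(fc)
  expect_lt(max(abs(int(m$values) - 0.331)), 1e-12)

  # smooth random target: interior mean absolute error < 0.02
  set.seed(8)
  tgt <- 0.3 * smooth_volume(array(rnorm(prod(gs)), gs), 1.5)
  fr <- maps_to_displacement_fields(list(mk_map(tgt)))[[1]]
  mr <- jacobian_determinant_map(fr)
  expect_lt(mean(abs(int(mr$values) - int(tgt))), 0.02)

  # non-physical target rejected
  bad <- array(0, gs); bad[8, 8, 8] <- -1.2
  expect_error(maps_to_displacement_fields(list(mk_map(bad))), "collapse")
})

test_that("ROI time series reproduce the target correlation structure", {
  n <- 10
  ts <- simulate_roi_timeseries(diag(n), n_subjects = 20, T_len = 500,
                                seed = 4)
  fc <- fisher_group_average(lapply(ts, subject_correlation_matrix))
  off <- fc$R_group[upper.tri(fc$R_group)]
  expect_lt(mean(abs(off)), 0.05)

  R <- diag(n); R[1, 2] <- R[2, 1] <- 0.8
  ts2 <- simulate_roi_timeseries(R, n_subjects = 30, T_len = 1000, seed = 6)
  fc2 <- fisher_group_average(lapply(ts2, subject_correlation_matrix))
  expect_lt(abs(fc2$R_group[1, 2] - 0.8), 0.05)

  expect_identical(simulate_roi_timeseries(diag(3), 2, 50, seed = 9),
                   simulate_roi_timeseries(diag(3), 2, 50, seed = 9))

  bad <- matrix(c(1, 2, 2, 1), 2, 2)   # eigenvalues 3, -1
  expect_error(simulate_roi_timeseries(bad, 2, 50), "eigenvalue")
})

test_that("spread simulator plants an exact epicenter relation at zero noise", {
  sp <- simulate_acp_and_atrophy(n_regions = 40, epicenter = 5,
                                 mode = "functional", noise_sd = 0, seed = 2)
  conn <- sp$connectome[, 5][-5]
  sev <- -sp$atrophy$t[-5]
  expect_equal(abs(cor(conn, sev)), 1, tolerance = 1e-12)

  st <- simulate_acp_and_atrophy(n_regions = 40, epicenter = 5,
                                 mode = "structural", noise_sd = 0, seed = 2)
  dist5 <- st$connectome$effective_distance[, 5][-5]
  expect_equal(cor(dist5, -st$atrophy$t[-5]), -1, tolerance = 1e-12)
  # ACP matrix contract
  acp <- st$connectome$acp
  expect_true(isSymmetric(acp))
  expect_true(all(acp >= 0 & acp <= 1))
  expect_true(all(diag(acp) == 0))

  # noise calibrated to a target |r| ~ 0.40 attains it on average
  rs <- vapply(1:100, function(s)
    simulate_acp_and_atrophy(n_regions = 112, epicenter = 3,
                             mode = "functional", target_r = 0.4,
                             seed = s)$truth$attained_r, numeric(1))
  expect_lt(abs(mean(rs) - 0.40), 0.05)
})
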