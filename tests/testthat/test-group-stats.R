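# Component-level inference: group t-tests, age correlations, clinical
# regressions and the site model, all cross-checked against formula oracles.

test_that("identical groups give t = 0, p = 1", {
  L <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 1)
  g <- rep(c("patient", "control"), each = 3)
  res <- component_group_test(L, g)
  expect_equal(res$t, 0)
  expect_equal(res$p_raw, 1)
  expect_equal(res$p_bonferroni, 1)
})

test_that("pooled t matches the textbook formula oracle", {
  set.seed(1)
  L <- matrix(rnorm(40 * 3), 40, 3)
  g <- rep(c("patient", "control"), each = 20)
  res <- component_group_test(L, g)
  for (k in 1:3) {
    to <- oracle_pooled_t(L[g == "patient", k], L[g == "control", k])
    expect_equal(res$t[k], to, tolerance = 1e-10)
  }
  expect_equal(res$p_bonferroni, pmin(1, 3 * res$p_raw))
  expect_error(component_group_test(L[1:21, ], g[1:21]), "at least 2")
})

test_that("the planted component is the only Bonferroni-significant one", {
  ch <- simulate_cohort(n_patients = 100, n_controls = 100, K = 30, d = 1,
                        grid_shape = c(16, 16, 16), seed = 17)
  gt <- component_group_test(ch$truth$loadings, ch$records$group)
  expect_equal(which(gt$significant), ch$truth$disease_component_index)
  # patients load lower: negative direction on the disease component
  expect_equal(gt$direction[ch$truth$disease_component_index], -1)
})

test_that("age correlation is exact on linear loadings and matches its oracle", {
  ages <- c(50, 55, 60, 65, 72, 80)
  L <- cbind(2 * ages - 7, -0.5 * ages + 3)
  res <- component_age_correlation(L, ages)
  expect_equal(res$r, c(1, -1), tolerance = 1e-12)
  set.seed(2)
  L2 <- matrix(rnorm(30 * 2), 30, 2)
  a2 <- rnorm(30, 60, 10)
  res2 <- component_age_correlation(L2, a2)
  for (k in 1:2)
    expect_equal(res2$r[k], oracle_pearson(L2[, k], a2), tolerance = 1e-12)
  expect_error(component_age_correlation(L2, rep(60, 30)), "constant")
})

test_that("raw age-correlation p-values are calibrated under the null", {
  set.seed(3)
  p <- replicate(1000, {
    cor.test(rnorm(20), rnorm(20))$p.value
  })
  # sanity anchor for the simulation itself
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
  # package path on the same null structure
  set.seed(4)
  hits <- replicate(500, {
    res <- component_age_correlation(matrix(rnorm(20), ncol = 1), rnorm(20))
    res$p_raw < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.03)
})

test_that("clinical regression is exact, matches normal equations, and recovers signs", {
  cov0 <- data.frame(group = rep(c("patient", "control"), each = 20),
                     age = rnorm(40, 60, 8),
                     updrs3 = rpois(40, 20), sbr = runif(40, 1, 3))
  y <- 2 * cov0$age
  tab <- suppressWarnings(clinical_regression(y, cov0))  # exact fit
  pt <- tab[tab$model == "patient", ]
  expect_equal(pt$estimate[pt$term == "age"], 2, tolerance = 1e-10)
  expect_equal(pt$r_squared[1], 1, tolerance = 1e-12)

  set.seed(5)
  y2 <- rnorm(40)
  tab2 <- clinical_regression(y2, cov0)
  pat <- cov0$group == "patient"
  X <- cbind(1, cov0$age[pat], cov0$updrs3[pat], cov0$sbr[pat])
  b <- oracle_ols(X, y2[pat])
  got <- tab2[tab2$model == "patient", "estimate"]
  expect_equal(unname(got), as.numeric(b), tolerance = 1e-10)

  # collinearity is reported by name
  cov_bad <- cov0
  cov_bad$updrs3 <- 2 * cov_bad$age
  expect_error(clinical_regression(y2, cov_bad), "collinear")

  # planted slopes recovered with the right signs in >= 95/100 seeds
  ok <- vapply(1:100, function(s) {
    ch <- simulate_cohort(n_patients = 232, n_controls = 117, K = 2, d = 1,
                          grid_shape = c(8, 8, 8), seed = s)
    l <- ch$truth$loadings[, ch$truth$disease_component_index]
    tb <- clinical_regression(l, ch$records)
    pt <- tb[tb$model == "patient", ]
    pt$estimate[pt$term == "age"] < 0 && pt$estimate[pt$term == "sbr"] > 0
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("site model flags planted offsets and stays quiet without them", {
  ch <- simulate_cohort(n_patients = 60, n_controls = 60, K = 4, d = 1,
                        grid_shape = c(10, 10, 10), site_sd = 0, seed = 23)
  st <- site_effect_test(ch$truth$loadings, ch$records$group,
                         ch$records$age, ch$records$sex, ch$records$site)
  expect_true(all(st$p_bonferroni > 0.1))

  ch2 <- simulate_cohort(n_patients = 100, n_controls = 100, K = 4, d = 1,
                         grid_shape = c(10, 10, 10), n_sites = 4,
                         site_sd = 2, seed = 24)
  st2 <- site_effect_test(ch2$truth$loadings, ch2$records$group,
                          ch2$records$age, ch2$records$sex,
                          ch2$records$site)
  expect_true(any(st2$p_bonferroni < 0.05))

  # F equals the nested-model RSS-ratio oracle
  df <- data.frame(l = ch$truth$loadings[, 1], g = ch$records$group,
                   age = ch$records$age, sex = ch$records$sex,
                   site = ch$records$site)
  full <- lm(l ~ g + age + sex + site, data = df)
  red <- lm(l ~ g + age + sex, data = df)
  rss_f <- sum(residuals(full)^2); rss_r <- sum(residuals(red)^2)
  df1 <- full$rank - red$rank; df2 <- nrow(df) - full$rank
  F_oracle <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  expect_equal(st$F[1], F_oracle, tolerance = 1e-10)

  expect_error(site_effect_test(ch$truth$loadings, ch$records$group,
                                ch$records$age, ch$records$sex,
                                rep(1, nrow(ch$records))), "2 levels")
})

test_that("statistics are invariant to affine rescaling of loadings", {
  set.seed(6)
  L <- matrix(rnorm(30), ncol = 1)
  g <- rep(c("patient", "control"), 15)
  ages <- rnorm(30, 60, 5)
  L2 <- 3.7 * L + 11
  expect_equal(component_group_test(L, g)$t,
               component_group_test(L2, g)$t, tolerance = 1e-10)
  expect_equal(component_age_correlation(L, ages)$r,
               component_age_correlation(L2, ages)$r, tolerance = 1e-12)
})

test_that("family-wise error of the Bonferroni group test is controlled", {
  set.seed(7)
  K <- 5
  fwer <- mean(replicate(500, {
    L <- matrix(rnorm(40 * K), 40, K)
    g <- rep(c("patient", "control"), each = 20)
    any(component_group_test(L, g)$significant)
  }))
  se <- sqrt(0.05 * 0.95 / 500)
  expect_lte(fwer, 0.05 + 2 * se)
})
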