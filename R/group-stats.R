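# Component-level inference: group t-tests with Bonferroni correction, age
# correlations, clinical regressions, and the acquisition-site model.

as_two_groups <- function(groups) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("`groups` must have exactly two levels")
  # orient so the second level is "patient" when the labels allow it
  if ("patient" %in% levels(g))
    g <- stats::relevel(g, ref = setdiff(levels(g), "patient"))
  g
}

#' Per-component two-sample group test with Bonferroni correction
#'
#' Unpaired t-test (pooled variance by default, Welch optional) of each
#' component's loadings between the two groups, Bonferroni-corrected over
#' the number of fitted components.
#'
#' @param loadings subjects x K matrix (or a `component_set`).
#' @param groups two-level factor (levels oriented so the direction is
#'   patient mean minus control mean when those labels are present).
#' @param K_for_correction Bonferroni m; defaults to the number of components.
#' @param var_equal pooled-variance t (default TRUE); FALSE gives Welch.
#' @return data.frame of class `component_test_result`: per component `t`,
#'   `p_raw`, `p_bonferroni`, `direction`, `significant`.
#' @export
component_group_test <- function(loadings, groups,
                                 K_for_correction = NULL, var_equal = TRUE) {
  if (inherits(loadings, "component_set")) loadings <- loadings$loadings
  L <- as.matrix(loadings)
  if (!all(is.finite(L))) stop("loadings contain non-finite values")
  g <- as_two_groups(groups)
  if (any(table(g) < 2)) stop("each group must have at least 2 subjects")
  K <- ncol(L)
  m <- if (is.null(K_for_correction)) K else K_for_correction
  res <- lapply(seq_len(K), function(k) {
    x2 <- L[g == levels(g)[2], k]   # patient (or second level)
    x1 <- L[g == levels(g)[1], k]
    tt <- stats::t.test(x2, x1, var.equal = var_equal)
    data.frame(component = k, t = unname(tt$statistic),
               p_raw = tt$p.value,
               direction = sign(mean(x2) - mean(x1)))
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, m * out$p_raw)
  out$significant <- out$p_bonferroni < 0.05
  attr(out, "m_correction") <- m
  attr(out, "var_equal") <- var_equal
  attr(out, "group_levels") <- levels(g)
  class(out) <- c("component_test_result", class(out))
  out
}

#' Per-component Pearson correlation of loadings with age
#'
#' @param loadings subjects x K matrix (or a `component_set`).
#' @param ages numeric vector (non-constant, n >= 4).
#' @param K_for_correction Bonferroni m; defaults to the number of components.
#' @return data.frame per component: `r`, `p_raw`, `p_bonferroni`,
#'   `significant`.
#' @export
component_age_correlation <- function(loadings, ages, K_for_correction = NULL) {
  if (inherits(loadings, "component_set")) loadings <- loadings$loadings
  L <- as.matrix(loadings)
  if (length(ages) != nrow(L)) stop("ages length must match loadings rows")
  if (length(ages) < 4) stop("need at least 4 subjects")
  if (stats::sd(ages) == 0) stop("ages are constant")
  K <- ncol(L)
  m <- if (is.null(K_for_correction)) K else K_for_correction
  res <- lapply(seq_len(K), function(k) {
    ct <- stats::cor.test(L[, k], ages)
    data.frame(component = k, r = unname(ct$estimate), p_raw = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, m * out$p_raw)
  out$significant <- out$p_bonferroni < 0.05
  out
}

check_full_rank <- function(mm) {
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    dropped <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                 paste(dropped, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Clinical regressions of the disease-component loading
#'
#' Ordinary least squares with intercept, fit separately in patients
#' (loading ~ age + UPDRS-III + SBR by default) and controls
#' (loading ~ age + SBR by default), mirroring the standard severity models.
#'
#' @param loading_disease numeric vector, one loading per subject.
#' @param covariates data.frame with at least the model variables and a
#'   `group` column (levels including "patient"/"control") unless `groups`
#'   is supplied.
#' @param patient_model,control_model right-hand-side formulas.
#' @param groups optional two-level factor overriding `covariates$group`.
#' @return data.frame: `model`, `term`, `estimate`, `t`, `p`, plus
#'   per-model `r_squared` attribute.
#' @export
clinical_regression <- function(loading_disease, covariates,
                                patient_model = ~ age + updrs3 + sbr,
                                control_model = ~ age + sbr,
                                groups = NULL) {
  g <- as_two_groups(if (is.null(groups)) covariates$group else groups)
  df <- data.frame(.loading = loading_disease, covariates)
  fit_one <- function(rhs, subset_lv, label) {
    sub <- df[g == subset_lv, , drop = FALSE]
    f <- stats::update(rhs, .loading ~ .)
    mm <- stats::model.matrix(f, data = sub)
    check_full_rank(mm)
    fit <- stats::lm(f, data = sub)
    sm <- summary(fit)
    co <- sm$coefficients
    data.frame(model = label, term = rownames(co), estimate = co[, 1],
               t = co[, 3], p = co[, 4], r_squared = sm$r.squared,
               row.names = NULL)
  }
  lv <- levels(g)
  pat_lv <- if ("patient" %in% lv) "patient" else lv[2]
  ctl_lv <- setdiff(lv, pat_lv)
  rbind(fit_one(patient_model, pat_lv, "patient"),
        fit_one(control_model, ctl_lv, "control"))
}

#' Acquisition-site effect test per component
#'
#' For each component, fits loading ~ group + age + sex + site and compares
#' it against the model without site by a joint F-test; p-values are
#' Bonferroni-corrected over components.
#'
#' @param loadings subjects x K matrix (or a `component_set`).
#' @param group,age,sex,site subject covariates; `site` must have >= 2
#'   levels, each with >= 2 subjects.
#' @return data.frame per component: `F`, `df1`, `df2`, `p_raw`,
#'   `p_bonferroni`, `significant`.
#' @export
site_effect_test <- function(loadings, group, age, sex, site) {
  if (inherits(loadings, "component_set")) loadings <- loadings$loadings
  L <- as.matrix(loadings)
  site <- factor(site)
  if (nlevels(site) < 2) stop("site must have at least 2 levels")
  if (any(table(site) < 2)) stop("every site must have at least 2 subjects")
  df <- data.frame(group = as_two_groups(group), age = age,
                   sex = factor(sex), site = site)
  K <- ncol(L)
  res <- lapply(seq_len(K), function(k) {
    df$.l <- L[, k]
    full <- stats::lm(.l ~ group + age + sex + site, data = df)
    red <- stats::lm(.l ~ group + age + sex, data = df)
    an <- stats::anova(red, full)
    data.frame(component = k, F = an$F[2], df1 = an$Df[2],
               df2 = an$Res.Df[2], p_raw = an$`Pr(>F)`[2])
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, K * out$p_raw)
  out$significant <- out$p_bonferroni < 0.05
  out
}
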