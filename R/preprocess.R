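#' Normalization, confound regression and regional group contrasts
#'
#' Regional uptake is first scaled by each subject's reference-region
#' (brainstem) mean — a reference preserved in the Alzheimer spectrum, unlike
#' the cerebral global mean which is itself depressed in patients. Nuisance
#' effects (age, sex, their interaction, total uptake, regional volume) are
#' then removed by ordinary least squares per region, and regional group
#' differences are tested on the confound-adjusted values.
#'
#' @name preprocess
NULL

#' Reference-region normalization
#'
#' Divides each subject's regional uptake by that subject's reference-region
#' mean uptake. Volumes are untouched. Scale-equivariant: multiplying both
#' uptake and reference by any per-subject constant leaves the output
#' unchanged.
#'
#' @param cohort A `cohort_table` with strictly positive `reference`.
#' @return A `cohort_table` with normalized `cmrgl` and `reference` reset to 1.
#' @export
normalize_reference <- function(cohort) {
  bad <- which(cohort$reference <= 0)
  if (length(bad) > 0)
    stop("non-positive reference value for subject(s): ",
         paste(cohort$subjects$subject_id[bad], collapse = ", "))
  cohort$cmrgl <- cohort$cmrgl / cohort$reference
  cohort$reference <- rep(1, n_subjects(cohort))
  cohort
}

# shared design columns (intercept first); volume is appended per region
.confound_design <- function(cohort, regressors) {
  n <- n_subjects(cohort)
  sex <- ifelse(cohort$subjects$sex == "M", 1, 0)
  age_c <- cohort$subjects$age - mean(cohort$subjects$age)
  cols <- list("(intercept)" = rep(1, n))
  for (r in regressors) {
    cols[[r]] <- switch(r,
      age = cohort$subjects$age,
      sex = sex,
      age_sex = age_c * sex,
      education = cohort$subjects$education,
      total_cmrgl = rowSums(cohort$cmrgl),
      volume = NULL,  # appended per region by the caller
      stop("unknown regressor: ", r))
  }
  do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
}

#' Screen a covariate for inclusion in the confound model
#'
#' Fits the per-region marginal regression of uptake on the covariate and
#' drops the covariate when no region shows a significant effect at the
#' family level. By default per-region p-values are Bonferroni-adjusted over
#' the N regions before comparison with `alpha`, so that a null covariate is
#' dropped in about `1 - alpha` of cohorts; `adjust = "none"` applies `alpha`
#' per region.
#'
#' @param cohort A `cohort_table`.
#' @param covariate One of `"education"`, `"age"`.
#' @param alpha Significance level for the keep decision.
#' @param adjust Multiplicity adjustment for the per-region p-values
#'   (any method of [stats::p.adjust()]).
#' @return List with `keep` (logical), `p_values`, `p_adjusted` (named by
#'   region), `covariate`, `alpha`.
#' @export
screen_covariate <- function(cohort, covariate = "education", alpha = 0.05,
                             adjust = "bonferroni") {
  x <- switch(covariate,
              education = cohort$subjects$education,
              age = cohort$subjects$age,
              stop("unknown covariate: ", covariate))
  if (stats::sd(x) == 0) stop("covariate '", covariate, "' is constant")
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  y <- cohort$cmrgl
  beta <- drop(crossprod(xc, y)) / sxx
  fitted <- outer(xc, beta)
  resid <- sweep(y, 2, colMeans(y)) - fitted
  sigma2 <- colSums(resid^2) / (n - 2)
  tval <- beta / sqrt(sigma2 / sxx)
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  names(p) <- cohort$atlas$regions$abbreviation
  p_adj <- stats::p.adjust(p, method = adjust)
  list(keep = any(p_adj <= alpha), p_values = p, p_adjusted = p_adj,
       covariate = covariate, alpha = alpha)
}

#' Remove confound effects by per-region linear regression
#'
#' For every region, replaces uptake by the ordinary-least-squares residuals
#' of uptake on an intercept plus the requested regressors. `total_cmrgl` is
#' the per-subject sum of regional uptake over all N regions (computed on the
#' table as passed, i.e. after reference normalization when that stage has
#' run); `volume` is the region-specific structure volume.
#'
#' @param cohort A `cohort_table`.
#' @param regressors Character vector from `age`, `sex`, `age_sex`,
#'   `total_cmrgl`, `volume`, `education`.
#' @return A `residual_matrix`: list with `values` (subjects x N residuals,
#'   columns zero-mean), `regressors`, `groups` (per-subject labels), `atlas`.
#' @export
remove_confounds <- function(cohort,
                             regressors = c("age", "sex", "age_sex",
                                            "total_cmrgl", "volume")) {
  n <- n_subjects(cohort)
  p <- length(regressors) + 1L
  if (n <= p)
    stop("need more subjects (", n, ") than regressors plus intercept (", p, ")")
  X0 <- .confound_design(cohort, regressors)
  per_region_vol <- "volume" %in% regressors
  res <- matrix(NA_real_, n, cohort$atlas$n_regions,
                dimnames = list(NULL, cohort$atlas$regions$abbreviation))
  for (j in seq_len(cohort$atlas$n_regions)) {
    X <- if (per_region_vol) cbind(X0, volume = cohort$volumes[, j]) else X0
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
      stop("rank-deficient confound design at region ",
           cohort$atlas$regions$abbreviation[j], "; collinear column(s): ",
           paste(aliased, collapse = ", "))
    }
    res[, j] <- qr.resid(qrx, cohort$cmrgl[, j])
  }
  structure(list(values = res, regressors = regressors,
                 groups = cohort$subjects$group, atlas = cohort$atlas),
            class = "residual_matrix")
}

#' Regional group-difference t-tests
#'
#' Per region, fits a linear model of uptake on group plus confounds and
#' contrasts the confound-adjusted group means for each requested pair with
#' the model-based (pooled-variance) t statistic. Two-sided p-values are
#' Bonferroni-corrected over the N regions within each contrast.
#'
#' @param cohort A `cohort_table` (normalize first if desired).
#' @param contrasts List of length-2 character vectors of group labels; the
#'   reported direction is `first minus second`.
#' @param alpha Family-wise significance level after Bonferroni correction.
#' @param regressors Confounds entered alongside group (defaults follow the
#'   standard design: age, sex, age x sex, regional volume; total uptake is
#'   itself group-dependent and is not adjusted for here).
#' @return A `regional_ttest_report`: data.frame with one row per region and
#'   contrast (`region`, `contrast`, `t`, `p`, `p_bonferroni`, `significant`,
#'   `direction`), plus attributes `alpha` and `n_tests`.
#' @export
regional_group_ttests <- function(cohort,
                                  contrasts = list(c("NC", "AD"),
                                                   c("NC", "MCI"),
                                                   c("MCI", "AD")),
                                  alpha = 0.05,
                                  regressors = c("age", "sex", "age_sex",
                                                 "volume")) {
  groups <- cohort$subjects$group
  wanted <- unique(unlist(contrasts))
  absent <- setdiff(wanted, groups)
  if (length(absent) > 0)
    stop("group(s) absent from cohort: ", paste(absent, collapse = ", "))
  if (any(table(factor(groups, levels = wanted)) < 2))
    stop("need >= 2 subjects in every contrasted group")

  gf <- factor(groups)
  G <- stats::model.matrix(~ gf)  # intercept + treatment-coded groups
  X0 <- .confound_design(cohort, setdiff(regressors, "volume"))[, -1, drop = FALSE]
  per_region_vol <- "volume" %in% regressors
  nreg <- cohort$atlas$n_regions
  abbr <- cohort$atlas$regions$abbreviation

  # contrast vector on the coefficient scale: mean(g1) - mean(g2)
  coef_contrast <- function(g1, g2, cn) {
    L <- stats::setNames(rep(0, length(cn)), cn)
    for (g in list(c(g1, 1), c(g2, -1))) {
      nm <- paste0("gf", g[1])
      if (nm %in% cn) L[nm] <- as.numeric(g[2])
    }
    L
  }

  rows <- vector("list", nreg * length(contrasts))
  k <- 0L
  for (j in seq_len(nreg)) {
    X <- cbind(G, X0)
    if (per_region_vol) X <- cbind(X, volume = cohort$volumes[, j])
    fit <- stats::lm.fit(X, cohort$cmrgl[, j])
    df <- nrow(X) - fit$rank
    rss <- sum(fit$residuals^2)
    XtXinv <- chol2inv(chol(crossprod(X)))
    cn <- colnames(X)
    for (ct in contrasts) {
      L <- coef_contrast(ct[1], ct[2], cn)
      est <- sum(L * fit$coefficients)
      se <- sqrt((rss / df) * drop(t(L) %*% XtXinv %*% L))
      tval <- if (se > 0) est / se else 0
      p <- 2 * stats::pt(-abs(tval), df = df)
      k <- k + 1L
      rows[[k]] <- data.frame(region = abbr[j],
                              contrast = paste(ct, collapse = "-"),
                              t = tval, p = p)
    }
  }
  rep_df <- do.call(rbind, rows)
  rep_df$p_bonferroni <- pmin(1, rep_df$p * nreg)
  rep_df$significant <- rep_df$p_bonferroni <= alpha
  rep_df$direction <- ifelse(rep_df$t > 0, "first_higher",
                             ifelse(rep_df$t < 0, "second_higher", "none"))
  attr(rep_df, "alpha") <- alpha
  attr(rep_df, "n_tests") <- nreg
  class(rep_df) <- c("regional_ttest_report", "data.frame")
  rep_df
}

#' Regions flagged hypometabolic in a contrast
#'
#' Convenience accessor: regions significantly *lower* in the second group of
#' a contrast (e.g. `"NC-AD"` returns regions where AD is reduced).
#'
#' @param report A `regional_ttest_report`.
#' @param contrast Contrast label such as `"NC-AD"`.
#' @return Character vector of region abbreviations.
#' @export
hypometabolic_regions <- function(report, contrast = "NC-AD") {
  sel <- report$contrast == contrast & report$significant &
    report$direction == "first_higher"
  report$region[sel]
}
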