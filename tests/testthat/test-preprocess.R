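make_cohort <- function(atlas, cmrgl, reference = NULL, group = NULL,
                        age = NULL, sex = NULL, education = NULL,
                        volumes = NULL) {
  n <- nrow(cmrgl)
  cohort_table(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = group %||% rep("NC", n),
    age = age %||% seq(60, 80, length.out = n),
    sex = sex %||% rep(c("M", "F"), length.out = n),
    education = education %||% rep(12:16, length.out = n),
    cmrgl = cmrgl,
    volumes = volumes %||% matrix(8000, n, atlas$n_regions),
    reference = reference %||% rep(1, n),
    atlas = atlas)
}

test_that("reference normalization divides by the subject reference", {
  atlas <- toy_atlas(stems = "A", lobes = "Frontal")
  co <- make_cohort(atlas, matrix(c(2, 4, 6, 8), 2, 2), reference = c(2, 4))
  out <- normalize_reference(co)
  expect_equal(unname(out$cmrgl), matrix(c(1, 1, 3, 2), 2, 2))

  # reference = 1 is the identity
  co1 <- make_cohort(atlas, matrix(rnorm(8), 4, 2))
  expect_equal(normalize_reference(co1)$cmrgl, co1$cmrgl)

  # scale equivariance under any per-subject rescaling
  s <- c(0.5, 2, 3, 10)
  co2 <- make_cohort(atlas, co1$cmrgl * s, reference = s)
  expect_equal(normalize_reference(co2)$cmrgl, co1$cmrgl, tolerance = 1e-12)

  co_bad <- co1
  co_bad$reference[2] <- 0
  expect_error(normalize_reference(co_bad), "s02")
})

test_that("confound regression matches the normal-equations oracle", {
  set.seed(10)
  atlas <- toy_atlas10()
  spec <- toy_spec(atlas, n = c(NC = 60L), seed = 10,
                   covariate_effects = list(age = 0.01, sex = 0.05,
                                            age_sex = 0.002, volume = 1e-5,
                                            education = 0))
  co <- normalize_reference(generate_cohort(spec, atlas))
  rm <- remove_confounds(co)
  expect_equal(dim(rm$values), dim(co$cmrgl))
  expect_equal(colMeans(rm$values), rep(0, 10), tolerance = 1e-10,
               ignore_attr = TRUE)

  # oracle: residuals via explicit (X'X)^-1 X'y per region
  sexn <- ifelse(co$subjects$sex == "M", 1, 0)
  agec <- co$subjects$age - mean(co$subjects$age)
  for (j in c(1, 5, 10)) {
    X <- cbind(1, co$subjects$age, sexn, agec * sexn, rowSums(co$cmrgl),
               co$volumes[, j])
    beta <- solve(t(X) %*% X, t(X) %*% co$cmrgl[, j])
    expect_equal(rm$values[, j], drop(co$cmrgl[, j] - X %*% beta),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # orthogonality to every standardized design column
    Xs <- scale(X[, -1])
    expect_lt(max(abs(crossprod(Xs, rm$values[, j] / sd(rm$values[, j])))) /
                nrow(X), 1e-8)
  }
})

test_that("planted linear age effect is removed from residuals", {
  atlas <- toy_atlas10()
  spec <- toy_spec(atlas, n = c(NC = 500L), seed = 77,
                   covariate_effects = list(age = 0.05, sex = 0, age_sex = 0,
                                            volume = 0, education = 0))
  co <- normalize_reference(generate_cohort(spec, atlas))
  rm <- remove_confounds(co)
  r_age <- cor(co$subjects$age, rm$values)
  expect_true(all(abs(r_age) < 0.05))
})

test_that("degenerate confound designs are rejected", {
  atlas <- toy_atlas(stems = "A", lobes = "Frontal")
  co <- make_cohort(atlas, matrix(rnorm(6), 3, 2))
  expect_error(remove_confounds(co), "more subjects")

  # education identical to age -> collinear design
  n <- 30
  co2 <- make_cohort(atlas, matrix(rnorm(2 * n), n, 2),
                     age = seq(60, 80, length.out = n),
                     education = seq(60, 80, length.out = n))
  expect_error(remove_confounds(co2, regressors = c("age", "education")),
               "collinear")
})

test_that("null education covariate is screened out, real effects kept", {
  atlas <- toy_atlas10()
  # calibration: with a zero education coefficient the screen should drop
  # the covariate in about 1 - alpha of cohorts
  dropped <- vapply(1:60, function(s) {
    co <- normalize_reference(generate_cohort(toy_spec(atlas, n = c(NC = 200L),
                                                       seed = s), atlas))
    !screen_covariate(co, "education")$keep
  }, logical(1))
  expect_gte(mean(dropped), 0.85)

  # strong planted effect in every region -> kept (power >> 99%)
  spec <- toy_spec(atlas, n = c(NC = 200L), seed = 1,
                   covariate_effects = list(age = 0, sex = 0, age_sex = 0,
                                            volume = 0, education = 0.05))
  co <- normalize_reference(generate_cohort(spec, atlas))
  expect_true(screen_covariate(co, "education")$keep)

  co$subjects$education <- rep(14, n_subjects(co))
  expect_error(screen_covariate(co, "education"), "constant")
})

test_that("group t-tests: identical groups give t = 0, planted reductions recover", {
  atlas <- toy_atlas10()
  # two groups with literally identical data matrices
  cm <- matrix(rnorm(40 * 10), 40, 10)
  co <- make_cohort(atlas, rbind(cm, cm),
                    group = rep(c("NC", "AD"), each = 40),
                    age = rep(seq(60, 80, length.out = 40), 2),
                    sex = rep(rep(c("M", "F"), 20), 2),
                    education = rep(14, 80),
                    volumes = matrix(rnorm(800, 8000, 100), 80, 10)[
                      rep(1:40, 2), ])
  tt <- regional_group_ttests(co, contrasts = list(c("NC", "AD")))
  expect_true(all(abs(tt$t) < 1e-8))
  expect_false(any(tt$significant))

  expect_error(regional_group_ttests(co, contrasts = list(c("NC", "MCI"))),
               "absent")

  # planted 20% reduction in 5 regions at n = 150/group
  hypo <- c("R1.L", "R1.R", "R2.L", "R2.R", "R3.L")
  spec <- toy_spec(atlas, n = c(NC = 150L, AD = 150L), seed = 4,
                   hypometabolic_regions = list(
                     AD = list(regions = hypo, reduction = 0.2)))
  co2 <- normalize_reference(generate_cohort(spec, atlas))
  tt2 <- regional_group_ttests(co2, contrasts = list(c("NC", "AD")))
  expect_setequal(hypometabolic_regions(tt2, "NC-AD"), hypo)
})

test_that("family-wise false-positive rate is controlled at the null", {
  atlas <- toy_atlas10()
  any_fp <- vapply(1:100, function(s) {
    spec <- toy_spec(atlas, n = c(NC = 60L, AD = 60L), seed = 1000 + s)
    co <- normalize_reference(generate_cohort(spec, atlas))
    tt <- regional_group_ttests(co, contrasts = list(c("NC", "AD")))
    any(tt$significant)
  }, logical(1))
  # Bonferroni FWER <= 0.05; allow two-sigma binomial slack on 100 draws
  expect_lte(mean(any_fp), 0.05 + 2 * sqrt(0.05 * 0.95 / 100))
})
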