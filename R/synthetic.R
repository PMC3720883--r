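#' Synthetic cohort generation
#'
#' The restricted clinical data behind multi-group CMRgl covariance studies
#' cannot be redistributed, so the package ships a generator that emulates the
#' second-order structure those analyses assume: strong homologous (left/right)
#' pair correlations, within-lobe covariance blocks, group-specific mean
#' reductions (hypometabolism), group-specific covariance alterations, and
#' linear covariate effects that the preprocessing stage is expected to remove.
#'
#' @name synthetic_cohort
NULL

#' Default hypometabolic region sets
#'
#' Region sets with planted group mean reductions, chosen to mirror the
#' topography reported for Alzheimer-spectrum FDG-PET studies: widespread
#' temporo-parietal/limbic/occipital involvement (23 regions, left-lateralized
#' occipital) for AD and a smaller bilateral limbic/temporal set (10 regions)
#' for MCI.
#'
#' @return Named list of character vectors of region abbreviations.
#' @export
default_hypometabolic_sets <- function() {
  list(
    AD = c("MTG.L", "MTG.R", "ITG.L", "ITG.R", "PHG.L", "PHG.R",
           "PCG.L", "PCG.R", "ANG.L", "ANG.R", "MOG.L", "IOG.L",
           "SOG.L", "CUN.L", "FFG.L", "IPL.L", "IPL.R", "PCUN.L",
           "PCUN.R", "TPOmid.R", "HIP.L", "SMG.L", "CAL.L"),
    MCI = c("PCG.L", "PCG.R", "PHG.L", "PHG.R", "ITG.L", "ITG.R",
            "ANG.R", "MTG.R", "FFG.R", "TPOmid.R")
  )
}

#' Specify a synthetic cohort
#'
#' Collects every tunable of the generator. Correlation targets are plain
#' Pearson correlations of the latent (confound-free, normalized) regional
#' uptake; the implied correlation matrix is repaired to positive
#' semi-definiteness by eigenvalue clipping when block construction makes it
#' indefinite.
#'
#' @param n_subjects Named integer vector of per-group sizes. Defaults to the
#'   69/62/68 (AD/MCI/NC) sizes typical of the ADNI baseline FDG-PET cohort.
#' @param seed RNG seed; per-group streams are derived from `(seed, group)` so
#'   adding a group never perturbs the others.
#' @param base_mean Baseline normalized regional uptake (scalar or length-N).
#' @param homologous_r Target correlation for homologous L/R pairs.
#' @param lobe_block_r Default within-lobe correlation.
#' @param background_r Off-block correlation.
#' @param noise_sd Residual standard deviation of regional uptake (the
#'   covariance is `noise_sd^2` times the target correlation matrix).
#' @param hypometabolic_regions Named list `group -> list(regions, reduction)`
#'   with `reduction` the fractional mean decrease in `[0, 1)`. Entries may
#'   also be bare character vectors (then `reduction` defaults per group:
#'   0.2 for AD, 0.1 otherwise).
#' @param covariate_effects Named list of linear coefficients applied on the
#'   normalized uptake scale: `age` (per year, age centered at 72.5), `sex`
#'   (M = 1), `age_sex` (centered age x sex), `volume` (per mm^3, volume
#'   centered at its regional mean), `education` (per year, centered at 14;
#'   default 0 so the education screen behaves as a null test).
#' @param extra_edges Optional data.frame (`region_a`, `region_b`, `r`)
#'   overriding specific pairwise correlations.
#' @param group_overrides Named list `group -> list(...)` overriding
#'   `lobe_r` (named per-lobe correlations), `core_r` (within the ten-region
#'   central "Core" set), `homologous_r`, `background_r`, or `extra_edges`
#'   for that group's covariance, so that groups can differ in connectivity
#'   and not only in means.
#' @param core_r Baseline correlation among the Core regions (see
#'   [core_regions()]).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = c(NC = 68L, MCI = 62L, AD = 69L),
                        seed = 1L,
                        base_mean = 1.0,
                        homologous_r = 0.7,
                        lobe_block_r = 0.4,
                        background_r = 0.1,
                        noise_sd = 0.1,
                        hypometabolic_regions = list(
                          AD = list(regions = default_hypometabolic_sets()$AD,
                                    reduction = 0.2),
                          MCI = list(regions = default_hypometabolic_sets()$MCI,
                                     reduction = 0.1)),
                        covariate_effects = list(age = -0.002, sex = 0.02,
                                                 age_sex = 0.001,
                                                 volume = 2e-6,
                                                 education = 0),
                        extra_edges = NULL,
                        group_overrides = default_group_overrides(),
                        core_r = 0.6) {
  n_subjects <- unlist(n_subjects)  # accept YAML-style lists
  rs <- c(homologous_r = homologous_r, lobe_block_r = lobe_block_r,
          background_r = background_r, core_r = core_r)
  if (any(abs(rs) >= 1)) stop("all target |r| must be < 1")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  hypo <- lapply(names(hypometabolic_regions), function(g) {
    h <- hypometabolic_regions[[g]]
    if (is.character(h)) h <- list(regions = h,
                                   reduction = if (g == "AD") 0.2 else 0.1)
    if (h$reduction < 0 || h$reduction >= 1)
      stop("hypometabolic reduction must lie in [0, 1)")
    h
  })
  names(hypo) <- names(hypometabolic_regions)
  structure(list(n_subjects = n_subjects, seed = seed, base_mean = base_mean,
                 homologous_r = homologous_r, lobe_block_r = lobe_block_r,
                 background_r = background_r, noise_sd = noise_sd,
                 hypometabolic_regions = hypo,
                 covariate_effects = covariate_effects,
                 extra_edges = extra_edges,
                 group_overrides = group_overrides,
                 core_r = core_r),
            class = "cohort_spec")
}

#' Default group-specific covariance alterations
#'
#' Emulates the qualitative group findings of CMRgl covariance studies of the
#' Alzheimer spectrum: raised frontal and occipital within-lobe covariation
#' and weakened temporal/limbic and Core covariation in AD, with MCI
#' intermediate. Magnitudes are the package's own calibration (the source
#' cohorts do not print effect sizes); they are chosen so planted effects are
#' recoverable at realistic group sizes.
#'
#' @return Named list of per-group override lists (see [cohort_spec()]).
#' @export
default_group_overrides <- function() {
  list(
    MCI = list(lobe_r = c(Frontal = 0.48, Occipital = 0.50,
                          Temporal = 0.33, Limbic = 0.33),
               core_r = 0.45),
    AD = list(lobe_r = c(Frontal = 0.55, Occipital = 0.60,
                         Temporal = 0.25, Limbic = 0.25),
              core_r = 0.30)
  )
}

#' Build the target covariance matrix implied by a cohort spec
#'
#' Constructs the block correlation matrix (background, within-lobe,
#' homologous-pair, Core, and explicit edge overrides, in that precedence
#' order), then repairs it to positive semi-definiteness by clipping negative
#' eigenvalues at zero and rescaling to unit diagonal, and finally scales by
#' `noise_sd^2`.
#'
#' @param spec A `cohort_spec`.
#' @param atlas A `region_atlas`.
#' @param group Optional group label; applies that group's
#'   `group_overrides` entry.
#' @param tol Eigenvalue tolerance: construction fails if clipping has to
#'   remove eigenvalue mass below `-tol * N`.
#' @return Covariance matrix with attributes `target` (pre-repair correlation
#'   matrix), `repaired` (logical), and `min_eigenvalue` (pre-clip minimum).
#' @export
build_covariance <- function(spec, atlas, group = NULL, tol = 0.5) {
  n <- atlas$n_regions
  ov <- if (!is.null(group)) spec$group_overrides[[group]] else NULL
  pick <- function(field, default) if (!is.null(ov[[field]])) ov[[field]] else default

  background_r <- pick("background_r", spec$background_r)
  homologous_r <- pick("homologous_r", spec$homologous_r)
  core_r <- pick("core_r", spec$core_r)
  lobe_r_default <- pick("lobe_block_r", spec$lobe_block_r)
  lobe_r <- stats::setNames(rep(lobe_r_default, length(.lobe_levels)), .lobe_levels)
  if (!is.null(ov$lobe_r)) lobe_r[names(ov$lobe_r)] <- ov$lobe_r

  R <- matrix(background_r, n, n)
  lobes <- atlas$regions$lobe
  for (lb in unique(lobes)) {
    i <- which(lobes == lb)
    R[i, i] <- lobe_r[[lb]]
  }
  core <- intersect(core_regions(), atlas$regions$abbreviation)
  if (length(core) >= 2) {
    i <- region_index(atlas, core)
    R[i, i] <- core_r
  }
  for (p in seq_len(nrow(atlas$pairs))) {
    i <- atlas$pairs$left[p] + 1L; j <- atlas$pairs$right[p] + 1L
    R[i, j] <- R[j, i] <- homologous_r
  }
  extra <- rbind(spec$extra_edges, ov$extra_edges)
  if (!is.null(extra) && nrow(extra) > 0) {
    ia <- region_index(atlas, extra$region_a)
    ib <- region_index(atlas, extra$region_b)
    for (k in seq_along(ia)) {
      R[ia[k], ib[k]] <- R[ib[k], ia[k]] <- extra$r[k]
    }
  }
  diag(R) <- 1

  e <- eigen(R, symmetric = TRUE)
  min_ev <- min(e$values)
  repaired <- min_ev < 0
  if (min_ev < -tol * n)
    stop("implied correlation matrix is far from positive semi-definite ",
         "(min eigenvalue ", signif(min_ev, 3), "); check target correlations")
  if (repaired) {
    ev <- pmax(e$values, 0)
    R2 <- e$vectors %*% (ev * t(e$vectors))
    d <- sqrt(diag(R2))
    R2 <- R2 / tcrossprod(d)
    R2 <- (R2 + t(R2)) / 2
    diag(R2) <- 1
  } else R2 <- R
  sigma <- spec$noise_sd^2 * R2
  attr(sigma, "target") <- R
  attr(sigma, "repaired") <- repaired
  attr(sigma, "min_eigenvalue") <- min_ev
  sigma
}

# deterministic per-(seed, group) stream so adding a group never perturbs others
.group_seed <- function(seed, group) {
  h <- sum(utf8ToInt(group) * seq_along(utf8ToInt(group)))
  as.integer((as.numeric(seed) * 1009 + h * 7919) %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' Draws each group's normalized regional uptake from a multivariate normal
#' with the group's mean vector (baseline minus planted hypometabolic
#' reductions) and the group's repaired covariance, adds linear covariate
#' effects (age ~ U(55, 90), sex ~ Bernoulli(1/2), education ~ U(8, 20),
#' region volumes ~ lognormal), then multiplies by a per-subject reference
#' uptake so that the emitted table is on the raw tracer scale and
#' [normalize_reference()] recovers the latent profiles exactly.
#'
#' @param spec A `cohort_spec`.
#' @param atlas A `region_atlas`.
#' @return A `cohort_table`.
#' @export
generate_cohort <- function(spec, atlas) {
  n_all <- spec$n_subjects
  if (any(n_all < 4))
    stop("n_subjects must be >= 4 per group (correlation undefined below that)")
  base <- rep_len(spec$base_mean, atlas$n_regions)
  eff <- spec$covariate_effects
  vol_meanlog <- log(8000)

  parts <- lapply(names(n_all), function(g) {
    n <- n_all[[g]]
    set.seed(.group_seed(spec$seed, g))
    mu <- base
    hy <- spec$hypometabolic_regions[[g]]
    if (!is.null(hy)) {
      i <- region_index(atlas, hy$regions)
      mu[i] <- mu[i] * (1 - hy$reduction)
    }
    sigma <- build_covariance(spec, atlas, group = g)
    profile <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)

    age <- stats::runif(n, 55, 90)
    sex <- stats::rbinom(n, 1, 0.5)
    education <- round(stats::runif(n, 8, 20))
    volumes <- matrix(exp(stats::rnorm(n * atlas$n_regions, vol_meanlog, 0.15)),
                      n, atlas$n_regions)
    age_c <- age - 72.5
    lin <- eff$age * age_c + eff$sex * sex + eff$age_sex * age_c * sex +
      eff$education * (education - 14)
    vol_c <- volumes - exp(vol_meanlog + 0.15^2 / 2)
    norm_uptake <- profile + lin + eff$volume * vol_c

    reference <- pmax(stats::rnorm(n, 6.5, 0.4), 0.5)
    cmrgl_raw <- norm_uptake * reference  # row-wise scale by subject reference

    list(subject_id = sprintf("%s_%03d", g, seq_len(n)),
         group = rep(g, n), age = age,
         sex = ifelse(sex == 1, "M", "F"), education = education,
         cmrgl = cmrgl_raw, volumes = volumes, reference = reference)
  })

  cohort_table(
    subject_id = unlist(lapply(parts, `[[`, "subject_id")),
    group = unlist(lapply(parts, `[[`, "group")),
    age = unlist(lapply(parts, `[[`, "age")),
    sex = unlist(lapply(parts, `[[`, "sex")),
    education = unlist(lapply(parts, `[[`, "education")),
    cmrgl = do.call(rbind, lapply(parts, `[[`, "cmrgl")),
    volumes = do.call(rbind, lapply(parts, `[[`, "volumes")),
    reference = unlist(lapply(parts, `[[`, "reference")),
    atlas = atlas)
}
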