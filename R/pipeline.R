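#' End-to-end pipeline orchestration
#'
#' Runs the full study in the standard order: cohort (loaded or synthesized)
#' -> reference normalization -> covariate screen -> confound regression per
#' group -> connectivity matrices and bootstraps -> edge-wise group
#' comparisons -> attribute curves with AUC contrasts -> NBC profile and
#' hubs -> lobe and Core covariation analyses. Every stochastic stage is
#' seeded from the single run seed, so `(config, seed)` fully determines all
#' outputs.
#'
#' @name pipeline_run
NULL

#' Default run configuration
#'
#' @param seed Root seed; per-stage seeds are derived deterministically.
#' @param n_boot,fraction Bootstrap draws per group and subset fraction.
#' @param sparsity_start,sparsity_stop,sparsity_step Sparsity grid.
#' @param metrics Global attributes for the AUC analysis.
#' @param q Edge-wise false discovery rate.
#' @param alpha Significance level for regional tests and post-hocs.
#' @param hub_threshold Mean-NBC hub cut.
#' @param top_k Edge count for the lobe distribution analysis.
#' @param sigma_null Null draws per sigma evaluation inside curves.
#' @param spec A `cohort_spec` for synthetic input (ignored when
#'   `cohort_path` is given).
#' @param cohort_path Optional path to a cohort CSV/TSV.
#' @param atlas_path Atlas source (default builtin `"aal90"`).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_boot = 300, fraction = 0.8,
                       sparsity_start = 0.5, sparsity_stop = 0.9,
                       sparsity_step = 0.02,
                       metrics = c("C", "L", "Eglob", "Eloc", "sigma"),
                       q = 0.05, alpha = 0.05, hub_threshold = 1.5,
                       top_k = 1000, sigma_null = 20,
                       spec = NULL, cohort_path = NULL,
                       atlas_path = "aal90") {
  bad <- setdiff(metrics, c("C", "L", "Eglob", "Eloc", "sigma"))
  if (length(bad) > 0)
    stop("unknown metric name(s): ", paste(bad, collapse = ", "))
  if (!is.null(cohort_path) && !file.exists(cohort_path))
    stop("cohort file not found: ", cohort_path)
  structure(list(seed = as.integer(seed), n_boot = n_boot,
                 fraction = fraction, sparsity_start = sparsity_start,
                 sparsity_stop = sparsity_stop, sparsity_step = sparsity_step,
                 metrics = metrics, q = q, alpha = alpha,
                 hub_threshold = hub_threshold, top_k = top_k,
                 sigma_null = sigma_null, spec = spec,
                 cohort_path = cohort_path, atlas_path = atlas_path),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; a `spec` block
#' is passed to [cohort_spec()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$spec)) y$spec <- do.call(cohort_spec, y$spec)
  do.call(run_config, y)
}

.stage_seed <- function(config, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(config$seed) * 2654435761 + h) %% 2147483647)
}

.provenance <- function(config, stage) {
  sprintf("# metabnet stage=%s seed=%d config_hash=%s", stage, config$seed,
          substr(paste(format(unlist(config[c("seed", "n_boot", "fraction",
                                              "sparsity_start",
                                              "sparsity_stop",
                                              "sparsity_step")])),
                       collapse = "|"), 1, 64))
}

.write_stage_csv <- function(df, path, config, stage) {
  con <- file(path, "w")
  writeLines(.provenance(config, stage), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
}

#' Run the full pipeline
#'
#' @param config A `run_config` (or YAML path).
#' @param out_dir Output directory for stage artifacts (created); `NULL`
#'   skips file output.
#' @return Invisibly, a summary list: per-contrast significant-edge counts,
#'   hypometabolic region sets, per-metric AUC comparisons, hubs, lobe
#'   counts, Core and hypometabolic-set covariation tests, and the seeds
#'   used.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  atlas <- load_atlas(config$atlas_path)

  # --- cohort ---------------------------------------------------------------
  cohort <- if (!is.null(config$cohort_path)) {
    load_cohort(config$cohort_path, atlas)
  } else {
    spec <- if (is.null(config$spec)) cohort_spec(seed = .stage_seed(config, "synth"))
            else config$spec
    generate_cohort(spec, atlas)
  }
  cohort <- normalize_reference(cohort)
  groups <- intersect(.group_levels, unique(cohort$subjects$group))

  # --- covariate screen + regional group differences ------------------------
  screen <- screen_covariate(cohort, "education", alpha = config$alpha)
  confounds <- c("age", "sex", "age_sex", "total_cmrgl", "volume")
  if (screen$keep) confounds <- c(confounds, "education")
  ttest_confounds <- c("age", "sex", "age_sex", "volume",
                       if (screen$keep) "education")
  contrasts <- list(c("NC", "AD"), c("NC", "MCI"), c("MCI", "AD"))
  contrasts <- Filter(function(ct) all(ct %in% groups), contrasts)
  regional <- regional_group_ttests(cohort, contrasts = contrasts,
                                    alpha = config$alpha,
                                    regressors = ttest_confounds)
  hypo_sets <- lapply(stats::setNames(nm = vapply(contrasts, paste,
                                                  character(1),
                                                  collapse = "-")),
                      function(ct) hypometabolic_regions(regional, ct))

  # --- connectivity ---------------------------------------------------------
  residuals <- lapply(stats::setNames(nm = groups), function(g) {
    remove_confounds(subset_group(cohort, g), regressors = confounds)
  })
  full_mats <- lapply(residuals, pearson_matrix)
  boots <- lapply(stats::setNames(nm = groups), function(g) {
    bootstrap_matrices(residuals[[g]], n_boot = config$n_boot,
                       fraction = config$fraction,
                       seed = .stage_seed(config, paste0("boot_", g)))
  })
  grid <- sparsity_grid(config$sparsity_start, config$sparsity_stop,
                        config$sparsity_step)

  edge_comparisons <- list()
  for (ct in contrasts) {
    key <- paste(ct, collapse = "-")
    edge_comparisons[[key]] <- compare_matrices(
      full_mats[[ct[1]]], full_mats[[ct[2]]], q = config$q, atlas = atlas)
  }

  # --- global attributes ----------------------------------------------------
  curves <- lapply(stats::setNames(nm = config$metrics), function(m) {
    lapply(stats::setNames(nm = groups), function(g) {
      attribute_curves(boots[[g]], grid, m, n_null = config$sigma_null,
                       seed = .stage_seed(config, paste0("sigma_", g)))
    })
  })
  auc_tests <- lapply(curves, function(by_group) {
    compare_auc(lapply(by_group, `[[`, "auc"), alpha = config$alpha)
  })

  # --- NBC and hubs ---------------------------------------------------------
  nbc <- nbc_profile(boots, grid, atlas, alpha = config$alpha)
  hubs <- select_hubs(nbc, threshold = config$hub_threshold)

  # --- lobe / Core ----------------------------------------------------------
  lobe_counts <- lapply(stats::setNames(nm = groups), function(g) {
    counts <- vapply(boots[[g]], function(C) {
      lobe_edge_counts(top_k_edges(C, config$top_k, atlas = atlas), atlas)
    }, numeric(6))
    rowMeans(counts)
  })
  core <- core_analysis(boots, atlas, alpha = config$alpha)
  hypo_ad <- hypo_sets[["NC-AD"]]
  hypo_cov <- if (!is.null(hypo_ad) && length(hypo_ad) >= 2) {
    hypometabolic_set_covariation(boots, hypo_ad, atlas = atlas,
                                  alpha = config$alpha)
  } else NULL

  summary <- list(
    seed = config$seed,
    groups = groups,
    n_subjects = as.list(table(cohort$subjects$group)),
    education_kept = screen$keep,
    significant_edges = vapply(edge_comparisons,
                               function(e) sum(e$significant), numeric(1)),
    hypometabolic_regions = hypo_sets,
    auc = lapply(auc_tests, function(a)
      list(kw_p = a$kw$p, group_means = as.list(a$group_means))),
    nbc_flagged = names(which(nbc$flags)),
    nbc_upper_bound = nbc$upper_bound,
    hubs = lapply(stats::setNames(nm = groups),
                  function(g) hubs$region[hubs$group == g]),
    lobe_counts = lobe_counts,
    core_means = core$group_means,
    hypometabolic_covariation_means =
      if (!is.null(hypo_cov)) as.list(hypo_cov$group_means) else NULL)

  if (!is.null(out_dir)) {
    .write_stage_csv(regional, file.path(out_dir, "regional_ttests.csv"),
                     config, "regional")
    for (key in names(edge_comparisons))
      .write_stage_csv(edge_comparisons[[key]],
                       file.path(out_dir, paste0("edges_", key, ".csv")),
                       config, "edges")
    .write_stage_csv(hubs, file.path(out_dir, "hubs.csv"), config, "hubs")
    for (g in groups)
      write_conn_matrix(full_mats[[g]], atlas,
                        file.path(out_dir, paste0("connectivity_", g, ".csv")))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(summary = summary, cohort = cohort, regional = regional,
                 edge_comparisons = edge_comparisons, curves = curves,
                 auc_tests = auc_tests, nbc = nbc, hubs = hubs,
                 core = core, hypometabolic_covariation = hypo_cov,
                 full_matrices = full_mats, bootstraps = boots,
                 grid = grid, atlas = atlas, config = config))
}
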