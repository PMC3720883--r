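# Shared settings for the numbered analysis scripts. Each script is a thin
# driver over the metabnet package; all computation lives in R/.
library(metabnet)

settings <- list(
  seed = 1L,
  n_boot = 50L,          # bootstrap draws per group
  fraction = 0.8,
  grid = sparsity_grid(),  # 21 sparsity degrees, 0.5 .. 0.9
  q = 0.05,
  alpha = 0.05,
  top_k = 1000L,
  results_dir = "results"
)
dir.create(settings$results_dir, showWarnings = FALSE)

atlas <- load_atlas()
cohort_file <- file.path(settings$results_dir, "synthetic_cohort.csv")

# cohort + per-group residuals + bootstrap ensembles, reproducible from seed
study_inputs <- function() {
  cohort <- if (file.exists(cohort_file)) load_cohort(cohort_file, atlas)
            else generate_cohort(cohort_spec(seed = settings$seed), atlas)
  cohort <- normalize_reference(cohort)
  groups <- intersect(c("NC", "MCI", "AD"), unique(cohort$subjects$group))
  residuals <- lapply(stats::setNames(nm = groups), function(g)
    remove_confounds(subset_group(cohort, g)))
  list(cohort = cohort, groups = groups, residuals = residuals)
}

study_bootstraps <- function(residuals) {
  lapply(stats::setNames(nm = names(residuals)), function(g)
    bootstrap_matrices(residuals[[g]], n_boot = settings$n_boot,
                       fraction = settings$fraction,
                       seed = settings$seed + match(g, names(residuals))))
}
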