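# Programmatic fixtures: toy atlases and small cohort specs built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_atlas_csv <- function(stems = c("A", "B"),
                          lobes = c("Frontal", "Temporal"),
                          path = tempfile(fileext = ".csv")) {
  rows <- do.call(rbind, lapply(seq_along(stems), function(i) {
    rbind(c(paste0(stems[i], ".L"), paste(stems[i], "left"), "L", lobes[i]),
          c(paste0(stems[i], ".R"), paste(stems[i], "right"), "R", lobes[i]))
  }))
  df <- data.frame(abbreviation = rows[, 1], name = rows[, 2],
                   hemisphere = rows[, 3], lobe = rows[, 4])
  utils::write.csv(df, path, row.names = FALSE)
  path
}

toy_atlas <- function(stems = c("A", "B"),
                      lobes = c("Frontal", "Temporal")) {
  load_atlas(toy_atlas_csv(stems, lobes))
}

# a 10-region (5-pair) atlas across two lobes for planted-effect tests
toy_atlas10 <- function() {
  toy_atlas(stems = paste0("R", 1:5),
            lobes = c("Frontal", "Frontal", "Frontal", "Temporal", "Temporal"))
}

# a spec safe for non-AAL atlases: no AAL-specific hypometabolic sets or
# group overrides unless supplied
toy_spec <- function(atlas, n = c(NC = 30L, AD = 30L), seed = 1L, ...) {
  args <- list(...)
  defaults <- list(n_subjects = n, seed = seed,
                   hypometabolic_regions = list(),
                   group_overrides = list(),
                   covariate_effects = list(age = 0, sex = 0, age_sex = 0,
                                            volume = 0, education = 0))
  do.call(cohort_spec, utils::modifyList(defaults, args))
}

# group-labelled residual matrices from iid noise (null connectivity data)
null_residuals <- function(n, n_regions) {
  matrix(stats::rnorm(n * n_regions), n, n_regions)
}
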