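#!/usr/bin/env Rscript
# Group connectivity matrices and edge-wise comparison: Pearson matrices on
# confound-adjusted uptake, Fisher r-to-z, Z statistic, FDR at q = 0.05
# over the 4005 region pairs.
source("analysis/common.R")

inp <- study_inputs()
mats <- lapply(inp$residuals, pearson_matrix)
for (g in inp$groups)
  write_conn_matrix(mats[[g]], atlas,
                    file.path(settings$results_dir,
                              paste0("connectivity_", g, ".csv")))

contrasts <- list(c("NC", "AD"), c("NC", "MCI"), c("MCI", "AD"))
for (ct in contrasts) {
  key <- paste(ct, collapse = "-")
  cmp <- compare_matrices(mats[[ct[1]]], mats[[ct[2]]], q = settings$q,
                          atlas = atlas)
  write.csv(cmp, file.path(settings$results_dir,
                           paste0("edge_comparison_", key, ".csv")),
            row.names = FALSE)
  inv <- sort(edge_involvement_counts(cmp), decreasing = TRUE)
  cat(sprintf("%-8s %3d significant edge differences; most involved: %s\n",
              key, sum(cmp$significant),
              paste(names(inv)[seq_len(min(3, sum(inv > 0)))],
                    collapse = " ")))
}
cat("Wrote connectivity matrices and edge comparisons to results/\n")
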