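#!/usr/bin/env Rscript
# Spatial distribution of the strongest covariations: top-1000 edge counts
# per lobe, the ten-region Core analysis (Core-Core, Core-Frontal,
# Core-Limbic), and covariation among the AD-hypometabolic set.
source("analysis/common.R")

inp <- study_inputs()
boots <- study_bootstraps(inp$residuals)

# top-1000 intra-lobe counts, averaged over bootstraps
count_rows <- lapply(inp$groups, function(g) {
  counts <- vapply(boots[[g]], function(C)
    lobe_edge_counts(top_k_edges(C, settings$top_k, atlas = atlas), atlas),
    numeric(6))
  data.frame(group = g, t(rowMeans(counts)))
})
counts_df <- do.call(rbind, count_rows)
print(counts_df, row.names = FALSE)
write.csv(counts_df, file.path(settings$results_dir, "lobe_edge_counts.csv"),
          row.names = FALSE)

core <- core_analysis(boots, atlas, alpha = settings$alpha)
cat("\nCore covariation (mean |r|):\n")
print(round(core$group_means, 3))
for (panel in rownames(core$group_means))
  cat(sprintf("%-12s KW p = %.3g\n", panel, core$tests[[panel]]$kw$p))

tt <- regional_group_ttests(inp$cohort, alpha = settings$alpha)
hypo <- hypometabolic_regions(tt, "NC-AD")
if (length(hypo) >= 2) {
  hc <- hypometabolic_set_covariation(boots, hypo, atlas = atlas,
                                      alpha = settings$alpha)
  cat("\nCovariation among the", length(hypo), "AD-hypometabolic regions:\n")
  print(round(hc$group_means, 3))
  cat("KW p =", signif(hc$tests$kw$p, 3), "\n")
}
cat("Wrote results/lobe_edge_counts.csv\n")
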