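#!/usr/bin/env Rscript

# Stage 5 — clone-size versus plaque-volume regression.
#
# Each (clone, contacted plaque) pair is one observation: x = plaque volume
# (um^3), y = clone cell count. Fits are reported for all plaques and
# stratified at the 1,000-um^3 cutoff (small: <= 1,000; large: > 1,000),
# per group. The scrambled control group shows what the regression looks
# like without clonal structure.
#
# Inputs:  results/clones/   Outputs: results/regression/

suppressPackageStartupMessages(library(microclonality))

out <- "results/regression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pairs <- utils::read.csv("results/clones/clone_plaque_pairs.csv")
clones <- utils::read.csv("results/clones/clones.csv")
pairs$group <- clones$group[match(pairs$clone_id, clones$clone_id)]

fits <- NULL
for (g in unique(pairs$group)) {
  s <- regress_strata(pairs[pairs$group == g, ], cutoff_um3 = 1000)
  s$group <- g
  fits <- rbind(fits, s)
  for (r in seq_len(nrow(s))) {
    message(sprintf(
      "%-8s %-5s: n = %4d, R = %6.3f, p = %9.3g, slope = %.3g cells/um^3",
      g, s$stratum[r], s$n_pairs[r], s$pearson_r[r], s$p_value[r],
      s$slope[r]))
  }
}
write_results(fits[, c("group", setdiff(names(fits), "group"))],
              file.path(out, "regressions.csv"))
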