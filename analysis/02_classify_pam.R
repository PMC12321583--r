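#!/usr/bin/env Rscript

# Stage 2 — plaque-proximity classification.
#
# Assigns every microglia a PAM / non-PAM state (cell body within 30 um of
# the nearest plaque surface, sphere-from-volume geometry) and tabulates
# the group-level summaries: PAM / non-PAM counts, Confetti+ cells within
# 30 um per animal, and the fraction of plaques decorated by PAM.
#
# Inputs:  results/tissue/        Outputs: results/classify/

suppressPackageStartupMessages(library(microclonality))

tissue <- "results/tissue"
out <- "results/classify"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meta <- utils::read.csv(file.path(tissue, "image_meta.csv"))
cells <- read_cells(file.path(tissue, "cells.csv"), meta)
plaques <- read_plaques(file.path(tissue, "plaques.csv"), meta)

cells <- classify_cells(cells, plaques, state_rule(contact_radius_um = 30))
write_cells(cells, file.path(out, "cells_classified.csv"))

state_counts <- as.data.frame(table(group = cells$group, state = cells$state))
write_results(state_counts, file.path(out, "state_counts.csv"))

ring30 <- cells_within_30um(cells, plaques)
write_results(ring30, file.path(out, "confetti_within_30um.csv"))

pam_frac <- plaques_with_pam_fraction(cells, plaques)
write_results(pam_frac, file.path(out, "plaques_with_pam.csv"))

for (g in unique(cells$group)) {
  sub <- cells$group == g
  message(sprintf(
    "%-8s %5d PAM / %5d non-PAM; Confetti+ within 30 um per animal: %s",
    g, sum(cells$state[sub] == "PAM"), sum(cells$state[sub] == "nonPAM"),
    paste(ring30$n_cells[ring30$group == g], collapse = ", ")))
}
message(sprintf("plaques decorated by PAM: %.1f%% (fad), %.1f%% (control)",
                100 * mean(pam_frac$fraction[pam_frac$group == "fad"]),
                100 * mean(pam_frac$fraction[pam_frac$group == "control"])))
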