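#!/usr/bin/env Rscript

# Stage 4 — Voronoi clone calling and clone-to-plaque contacts.
#
# Per image: z-project all microglia and plaques into the xy plane, build
# the box-clipped Voronoi tessellation, call clones as connected components
# of same-color adjacency, and record clone sizes, territories, plaque
# contacts and the fraction of PAM clones with an adjacent same-colored
# non-PAM cell.
#
# Inputs:  results/tissue/, results/classify/   Outputs: results/clones/

suppressPackageStartupMessages(library(microclonality))

out <- "results/clones"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meta <- utils::read.csv("results/tissue/image_meta.csv")
cells <- read_cells("results/classify/cells_classified.csv", meta)
plaques <- read_plaques("results/tissue/plaques.csv", meta)

clone_tabs <- list(); pair_tabs <- list(); assoc <- NULL
for (img in unique(cells$image_id)) {
  ci <- cells[cells$image_id == img, ]
  pi_ <- plaques[plaques$image_id == img, ]
  tess <- build_tessellation(ci, pi_, meta)
  cs <- call_clones(tess, ci)
  contacts <- clone_plaque_contacts(cs)
  sm <- clone_summaries(cs, contacts, ci)
  clone_tabs[[img]] <- sm$clone_table
  if (nrow(contacts$pairs)) {
    pair_tabs[[img]] <- contact_pairs(contacts, cs$clones, pi_)
  }
  assoc <- rbind(assoc, data.frame(
    group = ci$group[1], image_id = img,
    nonpam_assoc_fraction = sm$nonpam_assoc_fraction,
    frac_plaques_multiclone = contacts$frac_plaques_multiclone))
}
clones <- do.call(rbind, clone_tabs); rownames(clones) <- NULL
pairs <- do.call(rbind, pair_tabs); rownames(pairs) <- NULL

write_results(clones, file.path(out, "clones.csv"))
write_results(pairs, file.path(out, "clone_plaque_pairs.csv"))
write_results(assoc, file.path(out, "image_summaries.csv"))

for (g in unique(clones$group)) {
  cl <- clones[clones$group == g, ]
  message(sprintf(
    "%-8s %4d clones; cells/clone median %g (max %d); multi-cell clones %d; plaque contacts %d",
    g, nrow(cl), stats::median(cl$n_cells), max(cl$n_cells),
    sum(cl$n_cells > 1), sum(pairs$clone_id %in% cl$clone_id)))
}
message(sprintf(
  "PAM clones with same-colored non-PAM neighbor: %.0f%% (fad), %.0f%% (control)",
  100 * mean(assoc$nonpam_assoc_fraction[assoc$group == "fad"], na.rm = TRUE),
  100 * mean(assoc$nonpam_assoc_fraction[assoc$group == "control"],
             na.rm = TRUE)))
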