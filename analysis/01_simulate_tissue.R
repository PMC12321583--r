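#!/usr/bin/env Rscript

# Stage 1 — simulate the synthetic study.
#
# Two experimental groups of 3 animals x 3 tile-scan images each:
#   "fad"      amyloid-bearing cortex: plaques seed clonal PAM clusters
#              whose expected size scales with plaque volume
#   "control"  identical tissue with clone seeding off and Confetti colors
#              scrambled independently per cell — the no-clonality control
#
# Outputs: results/tissue/{cells,plaques}.csv, image_meta.csv, config.json

suppressPackageStartupMessages(library(microclonality))

out <- "results/tissue"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 101)
write_sim_config(cfg, file.path(out, "config.json"))

per_group <- cfg$n_replicates_per_group * cfg$n_images_per_replicate
fad <- simulate_group(cfg, group = "fad")
ctl_cfg <- sim_config(clone_cells_per_um3_plaque = 0, seed = 101)
control <- simulate_group(ctl_cfg, group = "control", scramble = TRUE,
                          image_offset = per_group)

cells <- rbind(fad$cells, control$cells)
plaques <- rbind(fad$plaques, control$plaques)
meta <- rbind(fad$meta, control$meta)

write_cells(cells, file.path(out, "cells.csv"))
write_plaques(plaques, file.path(out, "plaques.csv"))
write_results(meta, file.path(out, "image_meta.csv"))

n_lab <- tapply(cells$confetti_color != "none", cells$group, sum)
message(sprintf("simulated %d cells (%d plaques) over %d images",
                nrow(cells), nrow(plaques), nrow(meta)))
message(sprintf("Confetti+ cells: fad %d, control %d",
                n_lab[["fad"]], n_lab[["control"]]))
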