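# End-to-end pipeline: simulate -> classify -> ringtest -> clones -> regress.
#
# Every stage hands off via files in the run directory; the manifest records
# the config, seed, package version, per-stage outputs with md5 digests and
# any warnings, so a run is fully reproducible from its directory.

#' Run the full analysis pipeline on synthetic tissue
#'
#' Executes, for each requested group: tissue simulation, PAM/non-PAM
#' classification, the Monte Carlo ring clonality test, Voronoi clone
#' calling with plaque contacts, and the stratified clone-size regression.
#' Stage outputs are written to `out_dir` and listed (with digests) in
#' `manifest.json`. Identical config + seed reproduce byte-identical
#' outputs.
#'
#' @param cfg A [sim_config()]; `cfg$seed` is the run seed.
#' @param out_dir Output directory (created if needed).
#' @param groups Character vector of group labels to simulate; each group
#'   uses a disjoint RNG substream.
#' @param scramble Logical per group (recycled): assign colors per cell
#'   (null model) instead of clonally.
#' @param n_shuffles Shuffles for the null envelope (default 1,000 for a
#'   pipeline run; raise to 10,000 for final inference).
#' @param ci Confidence/envelope level.
#' @param subset Cell subset for the ring test.
#' @param r_max Outer ring radius (um).
#' @return The manifest, invisibly (also written as JSON).
#' @examples
#' \donttest{
#' cfg <- sim_config(image_extent = c(400, 400, 40), plaque_intensity = 400,
#'                   background_cell_intensity = 4000, seed = 1)
#' mf <- run_pipeline(cfg, tempfile("run"), n_shuffles = 200, r_max = 90)
#' names(mf$stages)
#' }
#' @export
run_pipeline <- function(cfg, out_dir, groups = "group1", scramble = FALSE,
                         n_shuffles = 1000, ci = 0.98, subset = "all",
                         r_max = 290) {
  validate_sim_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scramble <- rep_len(scramble, length(groups))
  warn_log <- character()
  note <- function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stages <- list()
  t0 <- format(Sys.time(), tz = "UTC", usetz = TRUE)

  per_image <- cfg$n_replicates_per_group * cfg$n_images_per_replicate
  sims <- lapply(seq_along(groups), function(g) {
    simulate_group(cfg, groups[g], scramble = scramble[g],
                   image_offset = (g - 1L) * per_image)
  })
  cells <- do.call(rbind, lapply(sims, `[[`, "cells"))
  plaques <- do.call(rbind, lapply(sims, `[[`, "plaques"))
  meta <- do.call(rbind, lapply(sims, `[[`, "meta"))
  f_cells <- file.path(out_dir, "cells.csv")
  f_plaques <- file.path(out_dir, "plaques.csv")
  write_cells(cells, f_cells)
  write_plaques(plaques, f_plaques)
  stages$simulate <- c(f_cells, f_plaques)

  cells <- classify_cells(cells, plaques)
  f_class <- file.path(out_dir, "cells_classified.csv")
  write_cells(cells, f_class)
  stages$classify <- f_class

  bins <- make_ring_bins(r_max)
  ring <- list()
  withCallingHandlers({
    for (g in groups) {
      gc_ <- cells[cells$group == g, , drop = FALSE]
      rt <- ring_clonality_test(gc_, bins, meta, subset = subset,
                                n_shuffles = n_shuffles, ci = ci,
                                seed = cfg$seed)
      ring[[g]] <- list(observed = rt$observed,
                        envelope = rt$envelope$envelope,
                        n_shuffles = rt$envelope$n_shuffles,
                        ci = rt$envelope$ci,
                        estimators = rt$envelope$estimators,
                        calls = rt$calls)
    }
  }, warning = note)
  f_ring <- file.path(out_dir, "ringtest.json")
  f_calls <- file.path(out_dir, "ring_calls.csv")
  write_results(ring, f_ring)
  write_results(do.call(rbind, lapply(ring, `[[`, "calls")), f_calls)
  stages$ringtest <- c(f_ring, f_calls)

  all_clones <- list(); all_pairs <- list(); summaries <- list()
  for (img in unique(cells$image_id)) {
    ci_ <- cells[cells$image_id == img, , drop = FALSE]
    pi_ <- plaques[plaques$image_id == img, , drop = FALSE]
    if (nrow(ci_) + nrow(pi_) < 3) next
    tess <- build_tessellation(ci_, pi_, meta)
    cs <- call_clones(tess, ci_)
    contacts <- clone_plaque_contacts(cs)
    sm <- clone_summaries(cs, contacts, ci_)
    all_clones[[img]] <- sm$clone_table
    if (nrow(cs$clones)) {
      all_pairs[[img]] <- contact_pairs(contacts, cs$clones, pi_)
    }
    summaries[[img]] <- list(nonpam_assoc_fraction = sm$nonpam_assoc_fraction,
                             frac_plaques_multiclone =
                               contacts$frac_plaques_multiclone)
  }
  clone_tab <- do.call(rbind, all_clones) %||%
    data.frame(group = character(), clone_id = character())
  pair_tab <- do.call(rbind, all_pairs) %||%
    data.frame(clone_id = character(), plaque_id = character(),
               image_id = character(), plaque_volume_um3 = numeric(),
               clone_n_cells = integer(), clone_territory_um2 = numeric())
  rownames(clone_tab) <- rownames(pair_tab) <- NULL
  f_clones <- file.path(out_dir, "clones.csv")
  f_pairs <- file.path(out_dir, "clone_plaque_pairs.csv")
  write_results(clone_tab, f_clones)
  write_results(pair_tab, f_pairs)
  stages$clones <- c(f_clones, f_pairs)

  reg <- regress_strata(pair_tab)
  f_reg <- file.path(out_dir, "regression.json")
  write_results(list(pairs_pooled_across_images = TRUE,
                     cutoff_um3 = 1000, regressions = reg), f_reg)
  stages$regress <- f_reg

  files <- unlist(stages, use.names = FALSE)
  manifest <- list(
    package = "microclonality",
    version = as.character(utils::packageVersion("microclonality")),
    seed = cfg$seed,
    config = unclass(cfg),
    groups = groups,
    scramble = scramble,
    started_utc = t0,
    finished_utc = format(Sys.time(), tz = "UTC", usetz = TRUE),
    stages = lapply(stages, function(f) {
      lapply(f, function(p) list(file = basename(p),
                                 md5 = unname(tools::md5sum(p))))
    }),
    warnings = warn_log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
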