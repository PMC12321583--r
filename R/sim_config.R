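#' Configuration for the synthetic-tissue generator
#'
#' Bundles every parameter of the synthetic point-process model of Confetti
#' fate-mapped cortex: a homogeneous Poisson background of microglia, amyloid
#' plaques with lognormal volumes, plaque-seeded clonal clusters whose
#' expected cell count scales linearly with plaque volume, and sparse
#' stochastic four-color labeling inherited clonally from founder lineages.
#'
#' Defaults emulate a tile-scanned confocal field of aged amyloid-model
#' (5xFAD-like) frontal cortex: roughly 10,000 microglia and 3,000
#' Methoxy-X04-positive deposits per mm^3, plaque volumes lognormal around a
#' median of 700 um^3, plaque-associated clones of ~8 cells per 1,000 um^3 of
#' plaque confined within 25 um of the plaque surface, and ~10% of founder
#' lineages carrying a Confetti color.
#'
#' @param image_extent Numeric length-3, image dimensions (Lx, Ly, Lz) in um.
#' @param n_images_per_replicate Images acquired per biological replicate.
#' @param n_replicates_per_group Biological replicates (animals) per group.
#' @param plaque_intensity Expected plaques per mm^3.
#' @param plaque_volume_log_mean,plaque_volume_log_sd Meanlog / sdlog of the
#'   lognormal plaque-volume distribution (um^3 scale).
#' @param background_cell_intensity Expected background microglia per mm^3.
#' @param clone_cells_per_um3_plaque Slope linking plaque volume (um^3) to the
#'   expected number of cells in its plaque-associated clone.
#' @param clone_radius Maximal spread (um) of clone members around the plaque
#'   surface.
#' @param label_prob Probability that a founder lineage carries a Confetti
#'   color.
#' @param color_weights Length-4 probability vector over
#'   `confetti_colors()`; must sum to 1.
#' @param noise_sd Gaussian positional jitter (um) applied to every cell.
#' @param seed Base RNG seed; per-image substreams are derived
#'   deterministically from it so that adding images never reshuffles
#'   earlier ones.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(plaque_intensity = 500, seed = 7)
#' cfg$plaque_intensity
#' @export
sim_config <- function(image_extent = c(1500, 1500, 50),
                       n_images_per_replicate = 3L,
                       n_replicates_per_group = 3L,
                       plaque_intensity = 3000,
                       plaque_volume_log_mean = log(700),
                       plaque_volume_log_sd = 0.5,
                       background_cell_intensity = 10000,
                       clone_cells_per_um3_plaque = 0.01,
                       clone_radius = 25,
                       label_prob = 0.1,
                       color_weights = c(nGFP = 0.10, YFP = 0.35,
                                         RFP = 0.40, mCFP = 0.15),
                       noise_sd = 0.5,
                       seed = 1L) {
  cfg <- list(
    image_extent = as.numeric(image_extent),
    n_images_per_replicate = as.integer(n_images_per_replicate),
    n_replicates_per_group = as.integer(n_replicates_per_group),
    plaque_intensity = plaque_intensity,
    plaque_volume_log_mean = plaque_volume_log_mean,
    plaque_volume_log_sd = plaque_volume_log_sd,
    background_cell_intensity = background_cell_intensity,
    clone_cells_per_um3_plaque = clone_cells_per_um3_plaque,
    clone_radius = clone_radius,
    label_prob = label_prob,
    color_weights = as.numeric(color_weights),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a sim_config
#'
#' Checks positivity of extents and counts, non-negativity of intensities and
#' probabilities, and that the color weights form a probability vector.
#'
#' @param cfg A `sim_config`.
#' @return `cfg`, invisibly unchanged, or an error describing the violation.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$image_extent) != 3 || any(!is.finite(cfg$image_extent)) ||
      any(cfg$image_extent <= 0)) {
    stop("image_extent must be three positive lengths (um)", call. = FALSE)
  }
  if (cfg$n_images_per_replicate < 1 || cfg$n_replicates_per_group < 1) {
    stop("counts of images and replicates must be >= 1", call. = FALSE)
  }
  rates <- c(plaque_intensity = cfg$plaque_intensity,
             background_cell_intensity = cfg$background_cell_intensity,
             clone_cells_per_um3_plaque = cfg$clone_cells_per_um3_plaque,
             clone_radius = cfg$clone_radius,
             plaque_volume_log_sd = cfg$plaque_volume_log_sd,
             noise_sd = cfg$noise_sd)
  bad <- names(rates)[!is.finite(rates) | rates < 0]
  if (length(bad)) {
    stop("negative or non-finite parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.finite(cfg$label_prob) || cfg$label_prob < 0 || cfg$label_prob > 1) {
    stop("label_prob must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$color_weights) != 4 || any(cfg$color_weights < 0) ||
      abs(sum(cfg$color_weights) - 1) > 1e-9) {
    stop("color_weights must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  cfg
}

#' Read a generator configuration from JSON or YAML
#'
#' Fields not present in the file keep their `sim_config()` defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file whose top-level keys
#'   are `sim_config()` argument names.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml, got: ", ext, call. = FALSE)
  )
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, raw)
}

#' Write a generator configuration as JSON
#'
#' @param cfg A `sim_config`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-tissue configuration\n")
  cat(sprintf("  image extent      : %g x %g x %g um\n",
              x$image_extent[1], x$image_extent[2], x$image_extent[3]))
  cat(sprintf("  hierarchy         : %d replicate(s) x %d image(s)\n",
              x$n_replicates_per_group, x$n_images_per_replicate))
  cat(sprintf("  plaques           : %g / mm^3, volume ~ lognormal(%.3f, %.3f)\n",
              x$plaque_intensity, x$plaque_volume_log_mean,
              x$plaque_volume_log_sd))
  cat(sprintf("  background cells  : %g / mm^3\n", x$background_cell_intensity))
  cat(sprintf("  clones            : %g cells per um^3 plaque, radius %g um\n",
              x$clone_cells_per_um3_plaque, x$clone_radius))
  cat(sprintf("  labeling          : P = %g over {%s}\n", x$label_prob,
              paste(confetti_colors(), collapse = ", ")))
  cat(sprintf("  seed              : %d\n", x$seed))
  invisible(x)
}
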