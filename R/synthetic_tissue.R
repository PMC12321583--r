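# Synthetic tissue generator
#
# The generator is organised around per-image RNG substreams: image k of a
# run draws its plaques, its cells and its labels from three deterministic
# substreams of cfg$seed, so that (a) regenerating with the same seed is
# bit-identical and (b) changing the number of images never reshuffles
# earlier images.

.with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  expr
}

.image_grid <- function(cfg, group, image_offset) {
  reps <- seq_len(cfg$n_replicates_per_group)
  imgs <- seq_len(cfg$n_images_per_replicate)
  g <- expand.grid(image = imgs, replicate = reps)
  data.frame(
    group = group,
    replicate_id = sprintf("%s_r%d", group, g$replicate),
    image_id = sprintf("%s_r%d_i%d", group, g$replicate, g$image),
    idx = image_offset + (g$replicate - 1L) * cfg$n_images_per_replicate +
      g$image,
    stringsAsFactors = FALSE
  )
}

#' Generate amyloid plaques for one experimental group
#'
#' Plaque counts per image are Poisson with mean
#' `plaque_intensity * image volume`, centroids are uniform in the image,
#' and volumes are lognormal.
#'
#' @param cfg A [sim_config()].
#' @param group Group label carried into the table.
#' @param image_offset Integer offset added to the global image index, used
#'   to give different groups of one run disjoint RNG substreams.
#' @return A plaque table: `group`, `replicate_id`, `image_id`, `plaque_id`,
#'   `x_um`, `y_um`, `z_um`, `volume_um3`.
#' @examples
#' pl <- generate_plaques(sim_config(plaque_intensity = 200, seed = 1))
#' head(pl)
#' @export
generate_plaques <- function(cfg, group = "group1", image_offset = 0L) {
  validate_sim_config(cfg)
  grid <- .image_grid(cfg, group, image_offset)
  ext <- cfg$image_extent
  lambda <- cfg$plaque_intensity * prod(ext) / 1e9
  .with_preserved_rng({
    out <- lapply(seq_len(nrow(grid)), function(r) {
      set.seed(.substream(cfg$seed, grid$idx[r], 1L))
      n <- rpois(1L, lambda)
      if (n == 0L) {
        return(NULL)
      }
      data.frame(
        group = group,
        replicate_id = grid$replicate_id[r],
        image_id = grid$image_id[r],
        plaque_id = sprintf("p%03d", seq_len(n)),
        x_um = runif(n, 0, ext[1]),
        y_um = runif(n, 0, ext[2]),
        z_um = runif(n, 0, ext[3]),
        volume_um3 = rlnorm(n, cfg$plaque_volume_log_mean,
                            cfg$plaque_volume_log_sd),
        stringsAsFactors = FALSE
      )
    })
    res <- do.call(rbind, out)
    if (is.null(res)) {
      res <- data.frame(group = character(), replicate_id = character(),
                        image_id = character(), plaque_id = character(),
                        x_um = numeric(), y_um = numeric(), z_um = numeric(),
                        volume_um3 = numeric(), stringsAsFactors = FALSE)
    }
    rownames(res) <- NULL
    res
  })
}

# draw k clone-member positions around one plaque: uniform directions, radial
# offset from the plaque surface folded-normal(sd = clone_radius / 2)
# truncated at clone_radius. Members falling outside the image are redrawn a
# bounded number of times, then clamped (sections truncate clones too).
.place_clone <- function(k, centre, r_plaque, clone_radius, ext) {
  draw <- function(m) {
    u <- runif(m, -1, 1)
    th <- runif(m, 0, 2 * pi)
    d <- abs(rnorm(m, 0, clone_radius / 2))
    d <- pmin(d, clone_radius)
    rad <- r_plaque + d
    s <- sqrt(1 - u^2)
    cbind(centre[1] + rad * s * cos(th),
          centre[2] + rad * s * sin(th),
          centre[3] + rad * u)
  }
  pos <- draw(k)
  for (i in 1:25) {
    bad <- pos[, 1] < 0 | pos[, 1] > ext[1] | pos[, 2] < 0 |
      pos[, 2] > ext[2] | pos[, 3] < 0 | pos[, 3] > ext[3]
    if (!any(bad)) break
    pos[bad, ] <- draw(sum(bad))
  }
  pos[, 1] <- pmin(pmax(pos[, 1], 0), ext[1])
  pos[, 2] <- pmin(pmax(pos[, 2], 0), ext[2])
  pos[, 3] <- pmin(pmax(pos[, 3], 0), ext[3])
  pos
}

#' Generate microglia positions for one experimental group
#'
#' Background cells follow a homogeneous Poisson process over the image
#' volume. Each plaque additionally seeds a clone of
#' `Poisson(clone_cells_per_um3_plaque * volume)` cells placed isotropically
#' within `clone_radius` of the plaque surface. Every cell records its
#' founder lineage (`founder_id`); background cells are their own founders.
#' Colors are not assigned here (see [assign_confetti()]).
#'
#' @param cfg A [sim_config()].
#' @param plaques Plaque table from [generate_plaques()] under the same
#'   config, group and offset.
#' @inheritParams generate_plaques
#' @return An unlabeled cell table: hierarchy keys, `cell_id`, coordinates,
#'   `confetti_color` (all `"none"`), `pu1` (all `TRUE`), `founder_id`.
#' @export
generate_cells <- function(cfg, plaques, group = "group1", image_offset = 0L) {
  validate_sim_config(cfg)
  grid <- .image_grid(cfg, group, image_offset)
  ext <- cfg$image_extent
  lambda_bg <- cfg$background_cell_intensity * prod(ext) / 1e9
  .with_preserved_rng({
    out <- lapply(seq_len(nrow(grid)), function(r) {
      set.seed(.substream(cfg$seed, grid$idx[r], 2L))
      n_bg <- rpois(1L, lambda_bg)
      parts <- list(cbind(runif(n_bg, 0, ext[1]), runif(n_bg, 0, ext[2]),
                          runif(n_bg, 0, ext[3])))
      fparts <- list(sprintf("bg%05d", seq_len(n_bg)))
      pl <- plaques[plaques$image_id == grid$image_id[r], , drop = FALSE]
      for (p in seq_len(nrow(pl))) {
        k <- rpois(1L, cfg$clone_cells_per_um3_plaque * pl$volume_um3[p])
        if (k == 0L) next
        rp <- plaque_radius(pl$volume_um3[p])
        parts[[length(parts) + 1L]] <-
          .place_clone(k, c(pl$x_um[p], pl$y_um[p], pl$z_um[p]),
                       rp, cfg$clone_radius, ext)
        fparts[[length(fparts) + 1L]] <- rep(pl$plaque_id[p], k)
      }
      xyz <- do.call(rbind, parts)
      founder <- unlist(fparts)
      n <- nrow(xyz)
      if (n > 0L && cfg$noise_sd > 0) {
        xyz <- xyz + matrix(rnorm(3L * n, 0, cfg$noise_sd), ncol = 3)
        xyz[, 1] <- pmin(pmax(xyz[, 1], 0), ext[1])
        xyz[, 2] <- pmin(pmax(xyz[, 2], 0), ext[2])
        xyz[, 3] <- pmin(pmax(xyz[, 3], 0), ext[3])
      }
      data.frame(
        group = rep_len(group, n),
        replicate_id = rep_len(grid$replicate_id[r], n),
        image_id = rep_len(grid$image_id[r], n),
        cell_id = sprintf("c%05d", seq_len(n)),
        x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
        confetti_color = rep_len("none", n),
        pu1 = rep_len(TRUE, n),
        founder_id = founder,
        stringsAsFactors = FALSE
      )
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Assign Confetti colors to cells
#'
#' In clonal mode (default), each founder lineage is independently labeled
#' with probability `label_prob` and, if labeled, draws one of the four
#' Confetti colors from `color_weights`; all members of a lineage inherit the
#' same color. In scramble mode, every cell is labeled and colored
#' independently of its lineage — the generator of the no-clonality null.
#'
#' @param cells Cell table from [generate_cells()].
#' @param cfg The [sim_config()] used to generate `cells`.
#' @param scramble Logical; assign colors per cell instead of per founder.
#' @param image_offset Offset used when `cells` were generated.
#' @return `cells` with `confetti_color` filled in.
#' @export
assign_confetti <- function(cells, cfg, scramble = FALSE, image_offset = 0L) {
  validate_sim_config(cfg)
  stopifnot(all(c("image_id", "founder_id") %in% names(cells)))
  if (nrow(cells) == 0L) {
    return(cells)
  }
  grid <- .image_grid(cfg, cells$group[1], image_offset)
  vocab <- confetti_colors()
  .with_preserved_rng({
    for (r in seq_len(nrow(grid))) {
      rows <- which(cells$image_id == grid$image_id[r])
      if (!length(rows)) next
      set.seed(.substream(cfg$seed, grid$idx[r], 3L))
      if (scramble) {
        lab <- runif(length(rows)) < cfg$label_prob
        col <- rep("none", length(rows))
        if (any(lab)) {
          col[lab] <- sample(vocab, sum(lab), replace = TRUE,
                             prob = cfg$color_weights)
        }
        cells$confetti_color[rows] <- col
      } else {
        founders <- sort(unique(cells$founder_id[rows]))
        lab <- runif(length(founders)) < cfg$label_prob
        fcol <- rep("none", length(founders))
        if (any(lab)) {
          fcol[lab] <- sample(vocab, sum(lab), replace = TRUE,
                              prob = cfg$color_weights)
        }
        cells$confetti_color[rows] <-
          fcol[match(cells$founder_id[rows], founders)]
      }
    }
    cells
  })
}

#' Simulate one experimental group end to end
#'
#' Convenience wrapper chaining [generate_plaques()], [generate_cells()] and
#' [assign_confetti()].
#'
#' @inheritParams generate_plaques
#' @inheritParams assign_confetti
#' @return List with `cells`, `plaques` and `meta` (an [image_meta()] table).
#' @examples
#' g <- simulate_group(sim_config(plaque_intensity = 100,
#'                                background_cell_intensity = 2000))
#' table(g$cells$confetti_color)
#' @export
simulate_group <- function(cfg, group = "group1", scramble = FALSE,
                           image_offset = 0L) {
  plaques <- generate_plaques(cfg, group, image_offset)
  cells <- generate_cells(cfg, plaques, group, image_offset)
  cells <- assign_confetti(cells, cfg, scramble, image_offset)
  grid <- .image_grid(cfg, group, image_offset)
  meta <- image_meta(grid$image_id, cfg$image_extent)
  list(cells = cells, plaques = plaques, meta = meta)
}
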