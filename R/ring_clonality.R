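# Monte Carlo ring-density clonality test.
#
# Starting from every Confetti-positive cell, same-colored neighbors are
# counted in concentric xy-annuli spanning the full image depth (the
# measured volume of a ring is 2D-ring area x Lz; z offsets are ignored).
# The per-annulus density, averaged image -> replicate -> group, is compared
# with the same statistic recomputed after shuffling Confetti labels over
# the positions of all Pu.1+ cells of the chosen subset: non-overlap of the
# experimental confidence interval and the shuffled-null envelope at level
# ci rejects random recombination with P < 1 - ci.

.subset_rows <- function(cells, subset) {
  if (subset == "all") return(seq_len(nrow(cells)))
  if (!("state" %in% names(cells))) {
    stop("subset '", subset, "' needs a state column; run classify_cells()",
         call. = FALSE)
  }
  which(cells$state == subset)
}

.color_codes <- function(color) {
  match(color, confetti_colors(), nomatch = 0L)
}

#' Per-origin-cell same-color neighbor counts in ring bins
#'
#' For every Confetti-positive cell of one image (after subset filtering),
#' counts the same-colored Confetti-positive neighbors whose xy-distance
#' falls in each annulus. z is ignored: annuli are cylindrical shells
#' spanning the full image depth. The origin cell itself is excluded, and
#' colors are never compared across (a neighbor must match its origin's
#' color exactly).
#'
#' @param cells Cell table of a single image.
#' @param bins A [make_ring_bins()] object.
#' @param subset `"all"`, `"PAM"` or `"nonPAM"` (the latter two require a
#'   `state` column); the filter applies to origins and neighbors alike.
#' @return Integer matrix, one row per origin cell (rownames = cell ids),
#'   one column per bin. Zero Confetti-positive cells give a 0-row matrix.
#' @export
same_color_counts <- function(cells, bins, subset = "all") {
  stopifnot(inherits(bins, "ring_bins"))
  if (length(unique(cells$image_id)) > 1) {
    stop("same_color_counts operates on a single image", call. = FALSE)
  }
  sub <- cells[.subset_rows(cells, subset), , drop = FALSE]
  sub <- sub[sub$pu1, , drop = FALSE]
  lab <- sub[sub$confetti_color != "none", , drop = FALSE]
  counts <- matrix(0L, nrow = nrow(lab), ncol = bins$n_bins,
                   dimnames = list(lab$cell_id, .bin_labels(bins)))
  if (nrow(lab) < 2) return(counts)
  for (col in unique(lab$confetti_color)) {
    idx <- which(lab$confetti_color == col)
    if (length(idx) < 2) next
    d <- as.matrix(stats::dist(cbind(lab$x_um[idx], lab$y_um[idx])))
    b <- matrix(findInterval(d, bins$edges, left.open = TRUE),
                nrow = length(idx))
    diag(b) <- 0L  # self is excluded; coincident pairs (d = 0) fall nowhere
    for (k in seq_len(bins$n_bins)) {
      counts[idx, k] <- as.integer(rowSums(b == k))
    }
  }
  counts
}

#' Ring density profile of one image
#'
#' Densities are the mean over origin cells of the same-color neighbor count
#' divided by the cylindrical annulus volume `pi * (r2^2 - r1^2) * Lz`
#' (um^-3). No correction is applied for annuli truncated by the image
#' border: the shuffled null is computed in the identical geometry, so
#' border effects cancel in the comparison.
#'
#' @inheritParams same_color_counts
#' @param meta [image_meta()] covering the image.
#' @return Data.frame with one row per bin: hierarchy keys, `subset`,
#'   `bin`, `r_lo`, `r_hi`, `mean_count`, `density_um3`, `n_origin_cells`.
#'   With zero origin cells the densities are `NA`.
#' @export
ring_density_profile <- function(cells, bins, meta, subset = "all") {
  img <- unique(cells$image_id)
  stopifnot(length(img) == 1)
  ext <- .meta_for_image(meta, img)
  counts <- same_color_counts(cells, bins, subset)
  n_origin <- nrow(counts)
  vol <- .bin_volumes(bins, ext[3])
  mean_count <- if (n_origin > 0) colMeans(counts) else rep(NA_real_, bins$n_bins)
  data.frame(
    group = cells$group[1], replicate_id = cells$replicate_id[1],
    image_id = img, subset = subset,
    bin = seq_len(bins$n_bins),
    r_lo = bins$edges[-length(bins$edges)], r_hi = bins$edges[-1],
    mean_count = as.numeric(mean_count),
    density_um3 = as.numeric(mean_count) / vol,
    n_origin_cells = n_origin,
    stringsAsFactors = FALSE
  )
}

#' Two-stage averaged group profile with experimental confidence interval
#'
#' Image profiles are averaged within each replicate, then replicate means
#' are averaged into the group profile (so unbalanced image counts do not
#' weight replicates unequally). The per-bin experimental confidence
#' interval at level `ci` is a Student-t interval across replicate means.
#' Images without origin cells (NA densities) are dropped from their
#' replicate's mean.
#'
#' @param profiles Row-bound [ring_density_profile()] outputs of one group
#'   and subset.
#' @param ci Two-sided confidence level (default 0.98).
#' @return Data.frame per bin: `density_mean`, `ci_lo`, `ci_hi`,
#'   `n_replicates`, `single_replicate` flag (CI undefined when only one
#'   replicate is present).
#' @export
average_profiles <- function(profiles, ci = 0.98) {
  stopifnot(length(unique(profiles$group)) == 1,
            length(unique(profiles$subset)) == 1,
            ci > 0, ci < 1)
  bins <- sort(unique(profiles$bin))
  rep_means <- vapply(bins, function(b) {
    sub <- profiles[profiles$bin == b, , drop = FALSE]
    tapply(sub$density_um3, sub$replicate_id, mean, na.rm = TRUE)
  }, numeric(length(unique(profiles$replicate_id))))
  if (is.null(dim(rep_means))) rep_means <- matrix(rep_means, nrow = 1)
  rep_means[!is.finite(rep_means)] <- NA_real_
  n_rep <- colSums(!is.na(rep_means))
  gmean <- colMeans(rep_means, na.rm = TRUE)
  gsd <- apply(rep_means, 2, stats::sd, na.rm = TRUE)
  tcrit <- ifelse(n_rep > 1, stats::qt(1 - (1 - ci) / 2, pmax(n_rep - 1, 1)),
                  NA_real_)
  se <- gsd / sqrt(n_rep)
  first <- profiles[!duplicated(profiles$bin), , drop = FALSE]
  first <- first[order(first$bin), , drop = FALSE]
  data.frame(
    group = profiles$group[1], subset = profiles$subset[1],
    bin = bins, r_lo = first$r_lo, r_hi = first$r_hi,
    density_mean = gmean,
    ci_lo = gmean - tcrit * se, ci_hi = gmean + tcrit * se,
    n_replicates = n_rep,
    single_replicate = n_rep < 2,
    stringsAsFactors = FALSE
  )
}

#' Shuffle Confetti labels over Pu.1+ positions of one image
#'
#' Implements the randomization move of the Monte Carlo null: the positions
#' of the subset's Pu.1+ cells are permuted uniformly at random while the
#' Confetti labels stay attached to the cell records — equivalently (and as
#' implemented) the color labels are reassigned to a uniform random
#' permutation of the positions. The multiset of positions and the count of
#' every color are invariant.
#'
#' @inheritParams same_color_counts
#' @return `cells` with permuted `confetti_color` within the subset.
#' @export
shuffle_labels <- function(cells, subset = "all") {
  rows <- .subset_rows(cells, subset)
  rows <- rows[cells$pu1[rows]]
  if (length(rows) > 1) {
    cells$confetti_color[rows] <-
      cells$confetti_color[rows][sample.int(length(rows))]
  }
  cells
}

# internal: per-image shuffled ring statistics.
# Returns an n_shuffles x n_bins matrix of per-origin mean counts (NA if the
# image has no labeled cell in the subset).
.image_shuffle_stats <- function(cells, bins, subset, n_shuffles, seed, idx) {
  sub <- cells[.subset_rows(cells, subset), , drop = FALSE]
  sub <- sub[sub$pu1, , drop = FALSE]
  n <- nrow(sub)
  codes <- .color_codes(sub$confetti_color)
  L <- sum(codes > 0)
  if (L == 0 || n < 2) {
    return(matrix(NA_real_, n_shuffles, bins$n_bins))
  }
  counts <- .with_preserved_rng({
    set.seed(.substream(seed, idx, 4L))
    ring_shuffle_pair_counts(sub$x_um, sub$y_um, codes, bins$edges,
                             n_shuffles)
  })
  counts[-1, , drop = FALSE] / L  # row 1 is the observed assignment
}

#' Monte Carlo null envelope of the group ring-density profile
#'
#' For every shuffle, Confetti labels are permuted independently within each
#' image (over the subset's Pu.1+ positions), the full two-stage averaged
#' group profile is recomputed, and the per-bin empirical
#' `(1-ci)/2` and `1-(1-ci)/2` quantiles (type 7) across shuffles form the
#' envelope. With the default `ci = 0.98` and 10,000 shuffles the bounds are
#' the interpolated 1st and 99th percentiles of the shuffled group
#' statistic.
#'
#' @param cells Cell table of one group (one or more images).
#' @param bins A [make_ring_bins()].
#' @param meta [image_meta()] covering every image.
#' @param subset `"all"`, `"PAM"` or `"nonPAM"`.
#' @param n_shuffles Number of label shufflings (default 10,000; fewer than
#'   100 triggers a quantile-resolution warning).
#' @param ci Envelope level (default 0.98).
#' @param seed RNG seed; shuffles for image k draw from a deterministic
#'   substream of (seed, k), so results are reproducible and independent of
#'   image order.
#' @param keep_shuffles Keep the full shuffles x bins matrix of group
#'   statistics in the result (for diagnostics).
#' @return An object of class `null_envelope`: data.frame `envelope`
#'   (per-bin `lo`, `hi`), plus `n_shuffles`, `ci`, `seed`, `subset` and
#'   metadata on the estimators used.
#' @export
mc_null_envelope <- function(cells, bins, meta, subset = "all",
                             n_shuffles = 10000, ci = 0.98, seed = 1L,
                             keep_shuffles = FALSE) {
  stopifnot(inherits(bins, "ring_bins"), ci > 0, ci < 1, n_shuffles >= 2)
  if (n_shuffles < 100) {
    warning("n_shuffles = ", n_shuffles,
            " gives poor quantile resolution for a ", ci,
            " envelope; use >= 100", call. = FALSE)
  }
  imgs <- unique(cells[, c("replicate_id", "image_id")])
  stats_by_img <- vector("list", nrow(imgs))
  for (r in seq_len(nrow(imgs))) {
    sub <- cells[cells$image_id == imgs$image_id[r], , drop = FALSE]
    ext <- .meta_for_image(meta, imgs$image_id[r])
    m <- .image_shuffle_stats(sub, bins, subset, n_shuffles, seed, r)
    stats_by_img[[r]] <- sweep(m, 2, .bin_volumes(bins, ext[3]), "/")
  }
  # two-stage average per shuffle: image -> replicate -> group
  na_mean <- function(mats) {  # elementwise NA-aware mean over a list
    num <- Reduce(`+`, lapply(mats, function(m) ifelse(is.na(m), 0, m)))
    den <- Reduce(`+`, lapply(mats, function(m) !is.na(m)))
    out <- num / den
    out[den == 0] <- NA_real_
    out
  }
  reps <- unique(imgs$replicate_id)
  rep_stats <- lapply(reps, function(rp) {
    na_mean(stats_by_img[imgs$replicate_id == rp])
  })
  group_stats <- na_mean(rep_stats)
  alpha <- (1 - ci) / 2
  q_safe <- function(v, p) {
    if (all(is.na(v))) return(NA_real_)
    stats::quantile(v, probs = p, type = 7, na.rm = TRUE, names = FALSE)
  }
  lo <- apply(group_stats, 2, q_safe, p = alpha)
  hi <- apply(group_stats, 2, q_safe, p = 1 - alpha)
  structure(list(
    envelope = data.frame(bin = seq_len(bins$n_bins),
                          r_lo = bins$edges[-length(bins$edges)],
                          r_hi = bins$edges[-1], lo = lo, hi = hi,
                          stringsAsFactors = FALSE),
    n_shuffles = n_shuffles, ci = ci, seed = seed, subset = subset,
    estimators = list(null = "empirical quantiles across shuffles (type 7)",
                      experimental = "Student-t across replicate means"),
    shuffle_stats = if (keep_shuffles) group_stats else NULL
  ), class = "null_envelope")
}

#' @export
print.null_envelope <- function(x, ...) {
  cat(sprintf("Shuffled-label null envelope: %d shuffles, %.0f%% level, subset %s\n",
              x$n_shuffles, 100 * x$ci, x$subset))
  print(x$envelope)
  invisible(x)
}

#' Per-bin clonality decision
#'
#' A bin shows clonal excess when the experimental confidence interval lies
#' entirely above the null envelope (`obs_lo > null_hi`), a deficit when it
#' lies entirely below, and no call otherwise (any overlap, including
#' touching bounds). Non-overlap at envelope level ci rejects the
#' random-recombination null with P < 1 - ci (P < 0.02 at the default).
#'
#' @param observed Output of [average_profiles()].
#' @param envelope A [mc_null_envelope()].
#' @return Data.frame per bin with both intervals and
#'   `call` in `{"none", "excess", "deficit"}`.
#' @export
clonality_decision <- function(observed, envelope) {
  stopifnot(inherits(envelope, "null_envelope"))
  env <- envelope$envelope
  if (!identical(observed$bin, env$bin) ||
      !isTRUE(all.equal(observed$r_lo, env$r_lo)) ||
      !isTRUE(all.equal(observed$r_hi, env$r_hi))) {
    stop("observed profile and envelope bins do not match", call. = FALSE)
  }
  call <- rep("none", nrow(env))
  excess <- observed$ci_lo > env$hi
  deficit <- observed$ci_hi < env$lo
  call[!is.na(excess) & excess] <- "excess"
  call[!is.na(deficit) & deficit] <- "deficit"
  data.frame(
    group = observed$group, subset = observed$subset, bin = observed$bin,
    r_lo = observed$r_lo, r_hi = observed$r_hi,
    density_mean = observed$density_mean,
    obs_lo = observed$ci_lo, obs_hi = observed$ci_hi,
    null_lo = env$lo, null_hi = env$hi,
    call = call,
    stringsAsFactors = FALSE
  )
}

#' Run the full ring clonality test on one group
#'
#' Computes per-image ring density profiles, the two-stage averaged group
#' profile with its experimental confidence interval, the shuffled-label
#' null envelope, and the per-bin clonality calls.
#'
#' @inheritParams mc_null_envelope
#' @return List of class `ring_clonality`: `profiles` (per image),
#'   `observed` (group profile + CI), `envelope`, `calls`.
#' @examples
#' \donttest{
#' g <- simulate_group(sim_config(seed = 3))
#' rt <- ring_clonality_test(g$cells, make_ring_bins(290), g$meta,
#'                           n_shuffles = 200, seed = 3)
#' subset(rt$calls, call != "none")
#' }
#' @export
ring_clonality_test <- function(cells, bins, meta, subset = "all",
                                n_shuffles = 10000, ci = 0.98, seed = 1L) {
  profiles <- do.call(rbind, lapply(unique(cells$image_id), function(img) {
    ring_density_profile(cells[cells$image_id == img, , drop = FALSE],
                         bins, meta, subset)
  }))
  observed <- average_profiles(profiles, ci = ci)
  envelope <- mc_null_envelope(cells, bins, meta, subset = subset,
                               n_shuffles = n_shuffles, ci = ci, seed = seed)
  calls <- clonality_decision(observed, envelope)
  structure(list(profiles = profiles, observed = observed,
                 envelope = envelope, calls = calls),
            class = "ring_clonality")
}

#' @export
print.ring_clonality <- function(x, ...) {
  cat(sprintf("Ring clonality test (subset %s, %d shuffles, %.0f%% level)\n",
              x$envelope$subset, x$envelope$n_shuffles, 100 * x$envelope$ci))
  hits <- x$calls[x$calls$call != "none", , drop = FALSE]
  if (nrow(hits) == 0) {
    cat("No bin departs from the shuffled-label null.\n")
  } else {
    for (r in seq_len(nrow(hits))) {
      cat(sprintf("  (%g,%g] um: %s (obs mean %.3g, null [%.3g, %.3g])\n",
                  hits$r_lo[r], hits$r_hi[r], hits$call[r],
                  hits$density_mean[r], hits$null_lo[r], hits$null_hi[r]))
    }
  }
  invisible(x)
}

#' Confetti-positive cells within 30 um of a plaque, per animal
#'
#' Counts, per replicate, the Confetti-positive cells whose body lies within
#' `radius_um` (surface distance) of the nearest plaque.
#'
#' @param cells_classified Cells with a `dist_to_plaque_um` column (from
#'   [classify_cells()]); it is computed on the fly when absent.
#' @param plaques Plaque table (used only when distances must be computed).
#' @param radius_um Ring distance (default 30 um).
#' @return Data.frame `group`, `replicate_id`, `n_cells`.
#' @export
cells_within_30um <- function(cells_classified, plaques, radius_um = 30) {
  cc <- cells_classified
  if (!("dist_to_plaque_um" %in% names(cc))) {
    cc$dist_to_plaque_um <- distance_to_nearest_plaque(cc, plaques)
  }
  hit <- cc$confetti_color != "none" & cc$dist_to_plaque_um <= radius_um
  keys <- unique(cc[, c("group", "replicate_id")])
  keys$n_cells <- vapply(seq_len(nrow(keys)), function(r) {
    sum(hit & cc$replicate_id == keys$replicate_id[r] &
          cc$group == keys$group[r])
  }, integer(1))
  rownames(keys) <- NULL
  keys
}
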