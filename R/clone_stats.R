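# Clone-size versus plaque-volume regressions and clone summary statistics.
#
# The regression unit is the clone-to-plaque contact pair: a clone touching
# k plaques contributes k points and a plaque touched by m clones
# contributes m points (no within-clone averaging). The volume cutoff
# stratifies plaques into small (<= 1,000 um^3) and large (> 1,000 um^3);
# ties at exactly the cutoff go to the small stratum.

#' Build the (clone, contacted plaque) regression pairs
#'
#' @param contacts A [clone_plaque_contacts()] result (or row-bound `pairs`
#'   data.frames from several images).
#' @param clones Clone table(s) from [call_clones()].
#' @param plaques Plaque table.
#' @return Data.frame, one row per contact pair: `clone_id`, `plaque_id`,
#'   `image_id`, `plaque_volume_um3` (x), `clone_n_cells` (y),
#'   `clone_territory_um2`.
#' @export
contact_pairs <- function(contacts, clones, plaques) {
  pairs <- if (is.data.frame(contacts)) contacts else contacts$pairs
  ci <- match(pairs$clone_id, clones$clone_id)
  pi_ <- match(paste(pairs$image_id %||% NA, pairs$plaque_id),
               paste(plaques$image_id, plaques$plaque_id))
  if (anyNA(ci)) stop("contact pairs reference unknown clones", call. = FALSE)
  if (anyNA(pi_)) {
    # fall back to plaque_id alone (single-image use)
    pi_ <- match(pairs$plaque_id, plaques$plaque_id)
    if (anyNA(pi_)) stop("contact pairs reference unknown plaques",
                         call. = FALSE)
  }
  data.frame(
    clone_id = pairs$clone_id,
    plaque_id = pairs$plaque_id,
    image_id = plaques$image_id[pi_],
    plaque_volume_um3 = plaques$volume_um3[pi_],
    clone_n_cells = clones$n_cells[ci],
    clone_territory_um2 = clones$territory_um2[ci],
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear regression of clone size on plaque volume
#'
#' Ordinary least squares of clone cell count (y) on contacted plaque volume
#' (x, um^3) over contact pairs, with Pearson correlation and its two-sided
#' t-test on n - 2 degrees of freedom. Strata: `"all"`, `"small"` (volume
#' <= cutoff) or `"large"` (> cutoff).
#'
#' @param pairs Output of [contact_pairs()] (pairs may be pooled across
#'   images; `image_id` is retained for per-image inspection).
#' @param stratum `"all"`, `"small"` or `"large"`.
#' @param cutoff_um3 Stratum boundary (default 1,000 um^3).
#' @param response `"n_cells"` (clone size, default) or `"territory"`.
#' @return One-row data.frame: `stratum`, `n_pairs`, `pearson_r`,
#'   `p_value`, `slope`, `intercept`, `insufficient_n` flag (p and the fit
#'   are `NA` when fewer than 3 pairs survive the stratum filter).
#' @examples
#' pairs <- data.frame(clone_id = letters[1:4], plaque_id = LETTERS[1:4],
#'                     image_id = "i", plaque_volume_um3 = c(100, 400, 900, 1600),
#'                     clone_n_cells = c(1, 4, 9, 16) * 2,
#'                     clone_territory_um2 = 1)
#' regress_clone_vs_plaque(pairs)
#' @export
regress_clone_vs_plaque <- function(pairs,
                                    stratum = c("all", "small", "large"),
                                    cutoff_um3 = 1000,
                                    response = c("n_cells", "territory")) {
  stratum <- match.arg(stratum)
  response <- match.arg(response)
  keep <- switch(stratum,
    all = rep(TRUE, nrow(pairs)),
    small = pairs$plaque_volume_um3 <= cutoff_um3,
    large = pairs$plaque_volume_um3 > cutoff_um3
  )
  sub <- pairs[keep, , drop = FALSE]
  x <- sub$plaque_volume_um3
  y <- if (response == "n_cells") sub$clone_n_cells else sub$clone_territory_um2
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(stratum = stratum, n_pairs = n, pearson_r = NA_real_,
                      p_value = NA_real_, slope = NA_real_,
                      intercept = NA_real_, insufficient_n = TRUE,
                      stringsAsFactors = FALSE))
  }
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  data.frame(stratum = stratum, n_pairs = n, pearson_r = r, p_value = p,
             slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
             insufficient_n = FALSE, stringsAsFactors = FALSE)
}

#' Stratified regression summary
#'
#' Runs [regress_clone_vs_plaque()] for the all / small / large strata;
#' the small and large pair sets are disjoint and partition the full set.
#'
#' @inheritParams regress_clone_vs_plaque
#' @return Three-row data.frame, one per stratum.
#' @export
regress_strata <- function(pairs, cutoff_um3 = 1000,
                           response = c("n_cells", "territory")) {
  response <- match.arg(response)
  do.call(rbind, lapply(c("all", "small", "large"), function(s) {
    regress_clone_vs_plaque(pairs, s, cutoff_um3, response)
  }))
}

#' Per-clone summary table and group distributions
#'
#' Emits cells-per-clone, contacted-plaques-per-clone and territory-per-
#' clone for every called clone, grouped by experimental group, plus the
#' fraction of clones with at least one same-colored Confetti-positive
#' non-PAM cell adjacent to the clone (tessellation adjacency; requires a
#' `state` column from [classify_cells()], otherwise that fraction is `NA`).
#'
#' @param clone_set A [call_clones()] result.
#' @param contacts The matching [clone_plaque_contacts()] result.
#' @param cells_classified The image's cells, ideally with `state`.
#' @param group Group label attached to the rows (defaults to the cells'
#'   group).
#' @return List: `clone_table` (one row per clone), `nonpam_assoc_fraction`.
#' @export
clone_summaries <- function(clone_set, contacts, cells_classified,
                            group = NULL) {
  stopifnot(inherits(clone_set, "clone_set"))
  clones <- clone_set$clones
  ppc <- contacts$plaques_per_clone
  tab <- merge(clones, ppc, by = "clone_id", all.x = TRUE, sort = TRUE)
  tab$n_plaques[is.na(tab$n_plaques)] <- 0L
  tab$group <- group %||% cells_classified$group[1]
  tab <- tab[, c("group", "clone_id", "color", "n_cells", "n_plaques",
                 "territory_um2", "touches_border")]
  frac <- NA_real_
  if ("state" %in% names(cells_classified)) {
    frac <- pam_clone_nonpam_association(clone_set$tess, cells_classified)
  }
  list(clone_table = tab, nonpam_assoc_fraction = frac)
}

#' Fraction of PAM clones with an adjacent same-colored non-PAM cell
#'
#' PAM clones are connected components of same-color tessellation adjacency
#' restricted to Confetti-positive PAM cells; a clone is "associated" when
#' any member's polygon touches a same-colored Confetti-positive non-PAM
#' cell.
#'
#' @param tess A [build_tessellation()] of the image.
#' @param cells_classified The image's cells with `state` and
#'   `confetti_color`.
#' @return Fraction in \[0, 1\], or `NA` when the image has no PAM clone.
#' @export
pam_clone_nonpam_association <- function(tess, cells_classified) {
  seeds <- tess$seeds
  rows <- match(seeds$ref_id, cells_classified$cell_id)
  col <- ifelse(seeds$kind == "cell",
                cells_classified$confetti_color[rows], "none")
  st <- ifelse(seeds$kind == "cell", cells_classified$state[rows],
               NA_character_)
  pam_lab <- seeds$seed[col != "none" & !is.na(st) & st == "PAM"]
  if (!length(pam_lab)) return(NA_real_)
  adj <- tess$adjacency
  keep <- adj[, 1] %in% pam_lab & adj[, 2] %in% pam_lab &
    col[adj[, 1]] == col[adj[, 2]]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(adj[keep, 1]),
                   to = as.character(adj[keep, 2])),
    directed = FALSE, vertices = data.frame(name = as.character(pam_lab))
  )
  memb <- igraph::components(g)$membership[as.character(pam_lab)]
  nb <- split(c(adj[, 2], adj[, 1]), c(adj[, 1], adj[, 2]))
  assoc <- vapply(split(pam_lab, memb), function(m) {
    cl_col <- col[m[1]]
    neigh <- setdiff(unique(unlist(nb[as.character(m)], use.names = FALSE)),
                     m)
    any(col[neigh] == cl_col & !is.na(st[neigh]) & st[neigh] == "nonPAM")
  }, logical(1))
  mean(assoc)
}
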