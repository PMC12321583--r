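# Voronoi tessellation of z-projected centroids; clone calling as
# same-color adjacency components.
#
# All microglia (labeled and unlabeled) and all plaques enter the
# tessellation as point seeds: unlabeled cells and plaques shape the
# polygons and can break contact between labeled cells, but are never clone
# members. Clipping to the image xy-bounding box makes every polygon finite;
# two seeds are adjacent when their polygons share an edge longer than a
# small threshold (degenerate point contacts do not count).

#' Build the clipped 2D Voronoi tessellation of an image
#'
#' Cell and plaque centroids are orthographically z-projected into the xy
#' plane and tessellated; outer cells are clipped to the image bounding box
#' `[0, Lx] x [0, Ly]`. Exactly coincident seed positions are perturbed by a
#' deterministic 1e-6 um jitter before tessellating.
#'
#' @param cells Cell table of one image.
#' @param plaques Plaque table of the same image (may be empty).
#' @param meta [image_meta()] covering the image.
#' @param edge_eps Minimal shared-edge length (um) for two polygons to count
#'   as adjacent. Default 1e-9.
#' @return An object of class `voronoi_tessellation`: `seeds` (data.frame
#'   with `seed`, `kind` = cell/plaque, `ref_id`, `x`, `y`), `polygons`
#'   (list of CCW vertex matrices), `areas` (um^2), `adjacency` (two-column
#'   matrix of seed index pairs, i < j), `touches_border` (logical per
#'   seed), `bbox`.
#' @export
build_tessellation <- function(cells, plaques, meta, edge_eps = 1e-9) {
  img <- unique(c(cells$image_id, plaques$image_id))
  stopifnot(length(img) == 1)
  ext <- .meta_for_image(meta, img)
  seeds <- data.frame(
    seed = seq_len(nrow(cells) + nrow(plaques)),
    kind = c(rep("cell", nrow(cells)), rep("plaque", nrow(plaques))),
    ref_id = c(cells$cell_id, plaques$plaque_id),
    x = c(cells$x_um, plaques$x_um),
    y = c(cells$y_um, plaques$y_um),
    stringsAsFactors = FALSE
  )
  if (nrow(seeds) < 3) {
    stop("tessellation needs at least 3 seeds", call. = FALSE)
  }
  # deterministic de-duplication of coincident seeds: successive duplicates
  # step around a 1e-6-um spiral so they never stay collinear
  key <- paste(seeds$x, seeds$y)
  if (anyDuplicated(key)) {
    occ <- stats::ave(seq_along(key), key, FUN = seq_along) - 1L
    seeds$x <- seeds$x + 1e-6 * occ * cos(2.399963 * occ)
    seeds$y <- seeds$y + 1e-6 * occ * sin(2.399963 * occ)
  }
  cx <- seeds$x - mean(seeds$x)
  cy <- seeds$y - mean(seeds$y)
  sv <- svd(cbind(cx, cy), nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    stop("all seeds are collinear; tessellation is degenerate", call. = FALSE)
  }
  vc <- voronoi_cells_cpp(seeds$x, seeds$y, 0, 0, ext[1], ext[2])
  polys <- vc$vertices
  srcs <- vc$edge_source
  n <- nrow(seeds)
  # adjacency: shared edge longer than edge_eps, required from both sides
  edges_of <- function(i) {
    v <- polys[[i]]
    s <- srcs[[i]]
    if (is.null(v) || nrow(v) < 3) return(integer(0))
    v2 <- v[c(seq_len(nrow(v))[-1], 1L), , drop = FALSE]
    len <- sqrt(rowSums((v2 - v)^2))
    unique(s[s > 0 & len > edge_eps])
  }
  nb <- lapply(seq_len(n), edges_of)
  pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- nb[[i]]
    j <- j[j > i]
    if (!length(j)) return(NULL)
    cbind(i, j)
  }))
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2)
  mutual <- vapply(seq_len(nrow(pairs)), function(r) {
    pairs[r, 1] %in% nb[[pairs[r, 2]]]
  }, logical(1))
  pairs <- pairs[mutual, , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  touches <- vapply(seq_len(n), function(i) {
    s <- srcs[[i]]
    any(s < 0)
  }, logical(1))
  structure(list(seeds = seeds, polygons = polys, areas = vc$area,
                 adjacency = pairs, touches_border = touches,
                 bbox = c(0, 0, ext[1], ext[2]), edge_eps = edge_eps,
                 image_id = img),
            class = "voronoi_tessellation")
}

#' @export
print.voronoi_tessellation <- function(x, ...) {
  cat(sprintf("Voronoi tessellation of image %s: %d seeds (%d cells, %d plaques), %d adjacencies\n",
              x$image_id, nrow(x$seeds), sum(x$seeds$kind == "cell"),
              sum(x$seeds$kind == "plaque"), nrow(x$adjacency)))
  invisible(x)
}

#' Call Confetti clones from tessellation adjacency
#'
#' A clone is a connected component of the graph whose vertices are the
#' Confetti-positive microglia of the image and whose edges are tessellation
#' adjacencies between same-colored cells. Singleton clones are allowed;
#' unlabeled cells and plaques are never members.
#'
#' @param tess A [build_tessellation()] built with all microglia as seeds.
#' @param cells The cell table used to build `tess`.
#' @return An object of class `clone_set`: `clones` (data.frame `clone_id`,
#'   `color`, `n_cells`, `territory_um2`, `touches_border`), `members`
#'   (data.frame `clone_id`, `cell_id`, `seed`), `unassigned` (Confetti-
#'   negative cell ids).
#' @export
call_clones <- function(tess, cells) {
  stopifnot(inherits(tess, "voronoi_tessellation"))
  seeds <- tess$seeds
  cell_seed <- seeds[seeds$kind == "cell", , drop = FALSE]
  col <- cells$confetti_color[match(cell_seed$ref_id, cells$cell_id)]
  lab_seed <- cell_seed$seed[col != "none"]
  lab_col <- col[col != "none"]
  if (length(lab_seed) == 0) {
    clones <- data.frame(clone_id = character(), color = character(),
                         n_cells = integer(), territory_um2 = numeric(),
                         touches_border = logical(), stringsAsFactors = FALSE)
    members <- data.frame(clone_id = character(), cell_id = character(),
                          seed = integer(), stringsAsFactors = FALSE)
    return(structure(list(clones = clones, members = members,
                          unassigned = cell_seed$ref_id, tess = tess),
                     class = "clone_set"))
  }
  colof <- stats::setNames(lab_col, lab_seed)
  adj <- tess$adjacency
  both_lab <- adj[, 1] %in% lab_seed & adj[, 2] %in% lab_seed
  same <- both_lab & colof[as.character(adj[, 1])] ==
    colof[as.character(adj[, 2])]
  edges <- adj[which(same), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges[, 1]),
                   to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(lab_seed))
  )
  comp <- igraph::components(g)
  memb <- comp$membership[as.character(lab_seed)]
  clone_id <- sprintf("%s_cl%03d", tess$image_id, memb)
  members <- data.frame(
    clone_id = clone_id,
    cell_id = cell_seed$ref_id[match(lab_seed, cell_seed$seed)],
    seed = lab_seed,
    stringsAsFactors = FALSE
  )
  members <- members[order(members$clone_id, members$seed), , drop = FALSE]
  rownames(members) <- NULL
  sp <- split(members, members$clone_id)
  clones <- do.call(rbind, lapply(sp, function(m) {
    data.frame(clone_id = m$clone_id[1],
               color = unname(colof[as.character(m$seed[1])]),
               n_cells = nrow(m),
               territory_um2 = sum(tess$areas[m$seed]),
               touches_border = any(tess$touches_border[m$seed]),
               stringsAsFactors = FALSE)
  }))
  rownames(clones) <- NULL
  structure(list(clones = clones, members = members,
                 unassigned = cell_seed$ref_id[col == "none"], tess = tess),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("%d Confetti clone(s) over %d labeled cells (%d unlabeled cells)\n",
              nrow(x$clones), nrow(x$members), length(x$unassigned)))
  if (nrow(x$clones)) print(table(size = x$clones$n_cells))
  invisible(x)
}

#' Territory of one clone
#'
#' Sum of the Voronoi polygon areas of the clone's member cells, in um^2; as
#' the tessellation is a z-projection, multiplying by the image depth
#' (`report_volume = TRUE`) converts the territory to an occupied volume in
#' um^3.
#'
#' @param clone_set A [call_clones()] result.
#' @param clone_id Clone identifier(s); default all clones.
#' @param report_volume Multiply areas by the image depth.
#' @param meta [image_meta()]; required when `report_volume = TRUE`.
#' @return Named numeric vector of territories.
#' @export
clone_territory <- function(clone_set, clone_id = NULL,
                            report_volume = FALSE, meta = NULL) {
  stopifnot(inherits(clone_set, "clone_set"))
  cl <- clone_set$clones
  if (!is.null(clone_id)) cl <- cl[cl$clone_id %in% clone_id, , drop = FALSE]
  out <- stats::setNames(cl$territory_um2, cl$clone_id)
  if (report_volume) {
    stopifnot(!is.null(meta))
    out <- out * .meta_for_image(meta, clone_set$tess$image_id)[3]
  }
  out
}

#' Clone-to-plaque contacts
#'
#' A clone contacts a plaque when any member polygon shares a tessellation
#' edge with the plaque's polygon.
#'
#' @param clone_set A [call_clones()] result whose tessellation includes the
#'   plaques as seeds.
#' @return List: `pairs` (data.frame `clone_id`, `plaque_id`),
#'   `plaques_per_clone` (per clone, including zero-contact clones),
#'   `clones_per_plaque` (per plaque), `frac_plaques_multiclone` (fraction
#'   of plaques contacted by >= 2 clones; `NA` without plaques).
#' @export
clone_plaque_contacts <- function(clone_set) {
  stopifnot(inherits(clone_set, "clone_set"))
  tess <- clone_set$tess
  seeds <- tess$seeds
  plq <- seeds[seeds$kind == "plaque", , drop = FALSE]
  members <- clone_set$members
  adj <- tess$adjacency
  if (nrow(plq) == 0 || nrow(members) == 0 || nrow(adj) == 0) {
    pairs <- data.frame(clone_id = character(), plaque_id = character(),
                        image_id = character(), stringsAsFactors = FALSE)
  } else {
    clone_of <- stats::setNames(members$clone_id, members$seed)
    is_plq <- seeds$kind[adj[, 1]] == "plaque" |
      seeds$kind[adj[, 2]] == "plaque"
    touch <- adj[is_plq, , drop = FALSE]
    rows <- lapply(seq_len(nrow(touch)), function(r) {
      a <- touch[r, 1]; b <- touch[r, 2]
      if (seeds$kind[a] == "plaque" && !is.na(clone_of[as.character(b)])) {
        c(clone_of[as.character(b)], seeds$ref_id[a])
      } else if (seeds$kind[b] == "plaque" &&
                 !is.na(clone_of[as.character(a)])) {
        c(clone_of[as.character(a)], seeds$ref_id[b])
      } else {
        NULL
      }
    })
    rows <- do.call(rbind, rows)
    pairs <- if (is.null(rows)) {
      data.frame(clone_id = character(), plaque_id = character(),
                 image_id = character(), stringsAsFactors = FALSE)
    } else {
      unique(data.frame(clone_id = rows[, 1], plaque_id = rows[, 2],
                        image_id = tess$image_id, stringsAsFactors = FALSE))
    }
  }
  pairs <- pairs[order(pairs$clone_id, pairs$plaque_id), , drop = FALSE]
  rownames(pairs) <- NULL
  ppc <- table(factor(pairs$clone_id, levels = clone_set$clones$clone_id))
  cpp <- table(factor(pairs$plaque_id, levels = plq$ref_id))
  list(
    pairs = pairs,
    plaques_per_clone = data.frame(clone_id = clone_set$clones$clone_id,
                                   n_plaques = as.integer(ppc),
                                   stringsAsFactors = FALSE),
    clones_per_plaque = data.frame(plaque_id = plq$ref_id,
                                   n_clones = as.integer(cpp),
                                   stringsAsFactors = FALSE),
    frac_plaques_multiclone = if (nrow(plq)) mean(cpp >= 2) else NA_real_
  )
}
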