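# Plaque-proximity classification of microglia.
#
# Only centroids and volumes survive tabulation of the segmented images, so
# a plaque is modeled as a sphere of equivalent volume; the distance from a
# cell body to the nearest plaque is measured to that sphere's surface
# (floored at zero for cells inside it). When the input already carries
# mask-derived `plaque_contact` or `dist_to_plaque_um` columns, those take
# precedence over the sphere model.

#' Equivalent-sphere radius of a plaque
#'
#' @param volume_um3 Plaque volume(s) in um^3.
#' @return Radius r such that a sphere of radius r has the given volume.
#' @export
plaque_radius <- function(volume_um3) (3 * volume_um3 / (4 * pi))^(1 / 3)

#' Classification rule for PAM / non-PAM states
#'
#' @param contact_radius_um Cells with their body within this distance of a
#'   plaque are plaque-associated; the boundary is inclusive. Default 30 um.
#' @param plaque_geometry `"sphere-from-volume"` derives distances from
#'   plaque centroids and volumes; `"explicit-contact-column"` trusts
#'   per-cell `plaque_contact` / `dist_to_plaque_um` columns computed
#'   upstream on the image masks.
#' @param distance_to Measure to the plaque `"surface"` (default) or
#'   `"centroid"`.
#' @return An object of class `state_rule`.
#' @export
state_rule <- function(contact_radius_um = 30,
                       plaque_geometry = c("sphere-from-volume",
                                           "explicit-contact-column"),
                       distance_to = c("surface", "centroid")) {
  if (!is.finite(contact_radius_um) || contact_radius_um <= 0) {
    stop("contact_radius_um must be positive", call. = FALSE)
  }
  structure(list(contact_radius_um = contact_radius_um,
                 plaque_geometry = match.arg(plaque_geometry),
                 distance_to = match.arg(distance_to)),
            class = "state_rule")
}

#' Distance from each cell to its nearest plaque
#'
#' Euclidean 3D distance from the cell body to the nearest plaque, measured
#' to the equivalent-sphere surface (centroid distance minus the equivalent
#' radius, floored at 0) or to the centroid, per `rule$distance_to`. Images
#' without plaques yield `Inf`.
#'
#' @param cells Cell table.
#' @param plaques Plaque table sharing image keys with `cells`.
#' @param rule A [state_rule()].
#' @return Numeric vector, one distance (um) per row of `cells`.
#' @export
distance_to_nearest_plaque <- function(cells, plaques, rule = state_rule()) {
  d <- rep(Inf, nrow(cells))
  for (img in unique(cells$image_id)) {
    rows <- which(cells$image_id == img)
    pl <- plaques[plaques$image_id == img, , drop = FALSE]
    if (nrow(pl) == 0L) next
    dx <- outer(cells$x_um[rows], pl$x_um, "-")
    dy <- outer(cells$y_um[rows], pl$y_um, "-")
    dz <- outer(cells$z_um[rows], pl$z_um, "-")
    dc <- sqrt(dx^2 + dy^2 + dz^2)
    if (rule$distance_to == "surface") {
      dc <- pmax(sweep(dc, 2, plaque_radius(pl$volume_um3), "-"), 0)
    }
    d[rows] <- do.call(pmin, as.data.frame(dc))
  }
  d
}

#' Classify cells as PAM or non-PAM
#'
#' A cell is plaque-associated (PAM) iff it is in recorded physical contact
#' with a plaque (`plaque_contact` column, when present) or its body lies
#' within `contact_radius_um` of the nearest plaque (inclusive). All other
#' cells, including every cell of a plaque-free image, are non-PAM.
#'
#' @inheritParams distance_to_nearest_plaque
#' @return `cells` with columns `dist_to_plaque_um` (filled if absent) and
#'   `state` (`"PAM"` / `"nonPAM"`).
#' @examples
#' cells <- data.frame(group = "g", replicate_id = "r", image_id = "i",
#'                     cell_id = c("a", "b"), x_um = c(10, 80), y_um = 0,
#'                     z_um = 0, confetti_color = "none", pu1 = TRUE)
#' plaques <- data.frame(group = "g", replicate_id = "r", image_id = "i",
#'                       plaque_id = "p", x_um = 0, y_um = 0, z_um = 0,
#'                       volume_um3 = 4 * pi / 3)
#' classify_cells(cells, plaques)$state
#' @export
classify_cells <- function(cells, plaques, rule = state_rule()) {
  use_cols <- rule$plaque_geometry == "explicit-contact-column"
  if (use_cols && !("plaque_contact" %in% names(cells)) &&
      !("dist_to_plaque_um" %in% names(cells))) {
    stop("explicit-contact-column geometry needs a plaque_contact or ",
         "dist_to_plaque_um column", call. = FALSE)
  }
  if (!use_cols || !("dist_to_plaque_um" %in% names(cells))) {
    cells$dist_to_plaque_um <- distance_to_nearest_plaque(cells, plaques, rule)
  }
  pam <- cells$dist_to_plaque_um <= rule$contact_radius_um
  pam[is.na(pam)] <- FALSE
  if ("plaque_contact" %in% names(cells)) {
    pam <- pam | (!is.na(cells$plaque_contact) & cells$plaque_contact)
  }
  cells$state <- ifelse(pam, "PAM", "nonPAM")
  cells
}

#' Fraction of plaques decorated by at least one PAM
#'
#' For each image, the fraction of plaques with at least one PAM cell
#' (optionally restricted to cells positive for a marker column) whose body
#' lies within the contact radius of that specific plaque. Images without
#' plaques yield `NA` rather than 0.
#'
#' @param cells_classified Output of [classify_cells()].
#' @param plaques Plaque table.
#' @param marker Optional name of a logical column of `cells_classified`
#'   (e.g. `"cd11c"`); only marker-positive cells count as decoration.
#' @param rule The [state_rule()] used for classification.
#' @return Data.frame with `group`, `replicate_id`, `image_id`, `n_plaques`,
#'   `n_with_pam`, `fraction`.
#' @export
plaques_with_pam_fraction <- function(cells_classified, plaques,
                                      marker = NULL, rule = state_rule()) {
  cc <- cells_classified[cells_classified$state == "PAM", , drop = FALSE]
  if (!is.null(marker)) {
    stopifnot(marker %in% names(cc))
    cc <- cc[!is.na(cc[[marker]]) & cc[[marker]], , drop = FALSE]
  }
  imgs <- unique(cells_classified[, c("group", "replicate_id", "image_id")])
  res <- lapply(seq_len(nrow(imgs)), function(r) {
    img <- imgs$image_id[r]
    pl <- plaques[plaques$image_id == img, , drop = FALSE]
    cells <- cc[cc$image_id == img, , drop = FALSE]
    n_with <- 0L
    if (nrow(pl) > 0L && nrow(cells) > 0L) {
      dx <- outer(pl$x_um, cells$x_um, "-")
      dy <- outer(pl$y_um, cells$y_um, "-")
      dz <- outer(pl$z_um, cells$z_um, "-")
      dc <- sqrt(dx^2 + dy^2 + dz^2)
      if (rule$distance_to == "surface") {
        dc <- pmax(dc - plaque_radius(pl$volume_um3), 0)
      }
      n_with <- sum(apply(dc <= rule$contact_radius_um, 1, any))
    }
    data.frame(group = imgs$group[r], replicate_id = imgs$replicate_id[r],
               image_id = img, n_plaques = nrow(pl), n_with_pam = n_with,
               fraction = if (nrow(pl)) n_with / nrow(pl) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
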