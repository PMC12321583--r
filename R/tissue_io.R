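# Tabular data model: validated CSV/TSV input and deterministic output.
#
# Coordinates are micrometres, continuous, 0-based, image-local (analyses
# operate per image; there is no global registration). CSV with comma
# delimiter is canonical; TSV is accepted. Data tables are written at full
# double precision so that write -> read round-trips exactly; derived
# results are written with 6 significant digits for cross-platform
# byte-stable outputs.

.cell_cols <- c("group", "replicate_id", "image_id", "cell_id",
                "x_um", "y_um", "z_um", "confetti_color", "pu1")
.plaque_cols <- c("group", "replicate_id", "image_id", "plaque_id",
                  "x_um", "y_um", "z_um", "volume_um3")

#' Image metadata table
#'
#' Records the acquisition extent of each image; the z-extent enters the
#' ring-density normalisation and the xy-extent bounds the Voronoi
#' tessellation.
#'
#' @param image_id Character vector of image identifiers.
#' @param extent Either a length-3 numeric (shared by all images) or a
#'   matrix/data.frame with one row per image and columns Lx, Ly, Lz (um).
#' @return A data.frame with columns `image_id`, `lx_um`, `ly_um`, `lz_um`.
#' @export
image_meta <- function(image_id, extent) {
  if (is.null(dim(extent))) {
    stopifnot(length(extent) == 3)
    extent <- matrix(rep(as.numeric(extent), each = length(image_id)),
                     ncol = 3)
  }
  extent <- as.matrix(extent)
  stopifnot(nrow(extent) == length(image_id), ncol(extent) == 3)
  if (any(extent <= 0)) stop("image extents must be positive", call. = FALSE)
  data.frame(image_id = as.character(image_id),
             lx_um = extent[, 1], ly_um = extent[, 2], lz_um = extent[, 3],
             stringsAsFactors = FALSE)
}

.meta_for_image <- function(meta, image_id) {
  i <- match(image_id, meta$image_id)
  if (is.na(i)) {
    stop("no extent metadata for image '", image_id, "'", call. = FALSE)
  }
  c(meta$lx_um[i], meta$ly_um[i], meta$lz_um[i])
}

.check_required <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

.check_coords <- function(df, meta, what, allow_outside) {
  i <- match(df$image_id, meta$image_id)
  if (anyNA(i)) {
    stop(what, ": image(s) without extent metadata: ",
         paste(unique(df$image_id[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  out <- df$x_um < 0 | df$x_um > meta$lx_um[i] |
    df$y_um < 0 | df$y_um > meta$ly_um[i] |
    df$z_um < 0 | df$z_um > meta$lz_um[i]
  if (any(out)) {
    if (!allow_outside) {
      stop(what, ": coordinates outside the image extent at row(s) ",
           paste(utils::head(which(out), 10), collapse = ", "),
           if (sum(out) > 10) " ..." else "", call. = FALSE)
    }
    df$outside_extent <- out
  }
  df
}

.check_unique <- function(df, id_col, what) {
  key <- paste(df$image_id, df[[id_col]])
  if (anyDuplicated(key)) {
    stop(what, ": duplicated ", id_col, " within an image at row(s) ",
         paste(utils::head(which(duplicated(key)), 10), collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Read and validate a cell table
#'
#' @param path Delimited text file with a header; must provide the columns
#'   `group`, `replicate_id`, `image_id`, `cell_id`, `x_um`, `y_um`, `z_um`,
#'   `confetti_color`, `pu1`. Extra columns are preserved.
#' @param meta [image_meta()] table covering every image in the file.
#' @param sep Field delimiter; `","` (default) or `"\t"`.
#' @param allow_outside Keep rows whose coordinates fall outside the declared
#'   extent, flagging them in an `outside_extent` column, instead of
#'   erroring.
#' @return A validated cell data.frame.
#' @export
read_cells <- function(path, meta, sep = ",", allow_outside = FALSE) {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  validate_cells(df, meta, allow_outside = allow_outside)
}

#' Validate an in-memory cell table
#'
#' @param cells Data.frame with the cell-table columns.
#' @inheritParams read_cells
#' @return The validated (possibly flagged) cell table.
#' @export
validate_cells <- function(cells, meta, allow_outside = FALSE) {
  .check_required(cells, .cell_cols, "cell table")
  bad <- !(cells$confetti_color %in% .color_vocab())
  if (any(bad)) {
    stop("cell table: confetti_color must be one of {",
         paste(.color_vocab(), collapse = ", "), "}; offending row(s): ",
         paste(utils::head(which(bad), 10), collapse = ", "),
         if (sum(bad) > 10) " ..." else "", call. = FALSE)
  }
  cells$pu1 <- as.logical(cells$pu1)
  for (col in c("x_um", "y_um", "z_um")) cells[[col]] <- as.numeric(cells[[col]])
  .check_unique(cells, "cell_id", "cell table")
  .check_coords(cells, meta, "cell table", allow_outside)
}

#' Read and validate a plaque table
#'
#' @param path Delimited text file with columns `group`, `replicate_id`,
#'   `image_id`, `plaque_id`, `x_um`, `y_um`, `z_um`, `volume_um3`.
#' @inheritParams read_cells
#' @return A validated plaque data.frame.
#' @export
read_plaques <- function(path, meta, sep = ",", allow_outside = FALSE) {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  validate_plaques(df, meta, allow_outside = allow_outside)
}

#' Validate an in-memory plaque table
#'
#' @param plaques Data.frame with the plaque-table columns.
#' @inheritParams read_cells
#' @return The validated plaque table.
#' @export
validate_plaques <- function(plaques, meta, allow_outside = FALSE) {
  .check_required(plaques, .plaque_cols, "plaque table")
  plaques$volume_um3 <- as.numeric(plaques$volume_um3)
  if (any(!is.finite(plaques$volume_um3) | plaques$volume_um3 <= 0)) {
    stop("plaque table: volume_um3 must be positive at row(s) ",
         paste(utils::head(which(!is.finite(plaques$volume_um3) |
                                   plaques$volume_um3 <= 0), 10),
               collapse = ", "), call. = FALSE)
  }
  .check_unique(plaques, "plaque_id", "plaque table")
  .check_coords(plaques, meta, "plaque table", allow_outside)
}

.format_table <- function(df, digits) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      df[[col]] <- sprintf(paste0("%.", digits, "g"), df[[col]])
    }
  }
  df
}

.write_table <- function(df, path, lead_cols, digits = 15) {
  ord <- c(intersect(lead_cols, names(df)), setdiff(names(df), lead_cols))
  df <- .format_table(df[, ord, drop = FALSE], digits)
  con <- file(path, open = "wb")  # binary mode pins Unix newlines
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Write a cell table as CSV
#'
#' Columns are emitted in a deterministic order (canonical columns first) and
#' doubles at full precision, so `read_cells(write_cells(x))` returns the
#' same values and identical inputs produce byte-identical files.
#'
#' @param cells Cell table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cells <- function(cells, path) {
  .write_table(cells, path, .cell_cols)
}

#' Write a plaque table as CSV
#'
#' @param plaques Plaque table.
#' @inheritParams write_cells
#' @return `path`, invisibly.
#' @export
write_plaques <- function(plaques, path) {
  .write_table(plaques, path, .plaque_cols)
}

.signif_rec <- function(x, digits) {
  if (is.data.frame(x)) {
    x[] <- lapply(x, function(col) if (is.double(col)) signif(col, digits)
                  else col)
    return(x)
  }
  if (is.double(x)) return(signif(x, digits))
  if (is.list(x)) return(lapply(x, .signif_rec, digits = digits))
  x
}

#' Write a per-stage results object
#'
#' Data.frames become CSV, anything else JSON; numbers are rounded to six
#' significant digits so reruns are byte-stable across platforms.
#'
#' @param x Data.frame or list of results.
#' @param path Output path (`.csv` for data.frames, `.json` otherwise).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (is.data.frame(x)) {
    .write_table(x, path, names(x), digits = 6)
  } else {
    jsonlite::write_json(.signif_rec(x, 6), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    invisible(path)
  }
}
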