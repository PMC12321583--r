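#' Concentric ring (annulus) bins around an origin cell
#'
#' The first annulus spans (0, 10] um of xy-distance; each subsequent
#' annulus is 20 um wide, up to `r_max`. Bins are half-open on the left so
#' the annuli partition (0, r_max] with no double counting.
#'
#' @param r_max Outer radius (um); must be >= 10 and of the form
#'   10 + 20k. Default 290 (15 bins ending at (270, 290]).
#' @return An object of class `ring_bins`: list with `edges` (length
#'   n_bins + 1) and `n_bins`.
#' @examples
#' make_ring_bins(290)$n_bins   # 15
#' make_ring_bins(190)$n_bins   # 10
#' @export
make_ring_bins <- function(r_max = 290) {
  if (!is.finite(r_max) || r_max < 10 || (r_max - 10) %% 20 != 0) {
    stop("r_max must be 10 + 20k um for integer k >= 0, got ", r_max,
         call. = FALSE)
  }
  edges <- c(0, seq(10, r_max, by = 20))
  structure(list(edges = edges, n_bins = length(edges) - 1L),
            class = "ring_bins")
}

#' @export
print.ring_bins <- function(x, ...) {
  cat(sprintf("%d ring bins: (%g, %g], then 20-um annuli up to (%g, %g] um\n",
              x$n_bins, x$edges[1], x$edges[2],
              x$edges[x$n_bins], x$edges[x$n_bins + 1]))
  invisible(x)
}

# labels like "(10,30]" for result tables
.bin_labels <- function(bins) {
  sprintf("(%g,%g]", bins$edges[-length(bins$edges)], bins$edges[-1])
}

# cylindrical annulus volumes (um^3) for an image of depth lz
.bin_volumes <- function(bins, lz) {
  pi * diff(bins$edges^2) * lz
}
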