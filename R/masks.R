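#' Circular nucleus mask
#'
#' Binary disk mask used as the default nuclear region for simulations.
#' A HeLa-like nucleus (~10 um diameter) fills roughly the central 70%
#' of a 256 px field at 0.096 um/px, hence the default relative radius.
#'
#' @param size image side length in pixels.
#' @param radius disk radius in pixels (default `0.35 * size`).
#' @param center numeric length-2 center `(row, col)` in pixel-center
#'   coordinates; defaults to the image center.
#' @return logical `size x size` matrix, `TRUE` inside the disk.
#' @export
disk_mask <- function(size, radius = 0.35 * size, center = NULL) {
  stopifnot(size >= 1, radius > 0)
  if (is.null(center)) center <- c((size - 1) / 2, (size - 1) / 2)
  rc <- expand.grid(row = 0:(size - 1), col = 0:(size - 1))
  m <- (rc$row - center[1])^2 + (rc$col - center[2])^2 <= radius^2
  matrix(m, size, size)
}

#' Horizontal band (stripe) mask
#'
#' Binary mask of a horizontal band of rows, clipped to an optional
#' enclosing mask. Emulates a hand-drawn laser-microirradiation stripe
#' crossing the nucleus.
#'
#' @param size image side length in pixels.
#' @param half_width half-height of the band in pixels.
#' @param row_center center row (0-based); defaults to the middle row.
#' @param within optional logical matrix; the band is intersected with it.
#' @return logical `size x size` matrix.
#' @export
band_mask <- function(size, half_width = 5, row_center = NULL, within = NULL) {
  stopifnot(size >= 1, half_width >= 0)
  if (is.null(row_center)) row_center <- (size - 1) / 2
  rows <- abs(0:(size - 1) - row_center) <= half_width
  m <- matrix(rows, size, size)
  if (!is.null(within)) m <- m & within
  m
}

#' Corner background mask
#'
#' Square region in the top-left image corner, excluded from an optional
#' nucleus mask, used as the default background region.
#'
#' @param size image side length in pixels.
#' @param side side length of the corner square in pixels.
#' @param exclude optional logical matrix of pixels to exclude.
#' @return logical `size x size` matrix.
#' @export
corner_mask <- function(size, side = max(8L, size %/% 8L), exclude = NULL) {
  stopifnot(size >= 1, side >= 1)
  m <- matrix(FALSE, size, size)
  m[seq_len(min(side, size)), seq_len(min(side, size))] <- TRUE
  if (!is.null(exclude)) m <- m & !exclude
  m
}

# Validate a logical mask; returns it invisibly or errors with `name`.
check_mask <- function(mask, name, n_required = 1L) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("'%s' must be a logical matrix", name))
  if (sum(mask) < n_required)
    stop(sprintf("mask '%s' is empty", name))
  invisible(mask)
}
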