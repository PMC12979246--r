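#' Band-pass filter a frame (difference of Gaussians)
#'
#' Standard band-pass for diffraction-limited spots: the difference of
#' a narrow and a wide Gaussian blur. With a flat input the output is
#' zero everywhere; a spot of scale ~`sigma_small` is passed, slowly
#' varying background is suppressed.
#'
#' @param frame numeric matrix of photon counts.
#' @param sigma_small sd (px) of the narrow Gaussian; default 1.
#' @param sigma_large sd (px) of the wide Gaussian; default 3.
#' @return numeric matrix, same shape as `frame`.
#' @export
bandpass_filter <- function(frame, sigma_small = 1, sigma_large = 3) {
  stopifnot(is.matrix(frame))
  if (!(sigma_small > 0 && sigma_small < sigma_large))
    stop("require 0 < sigma_small < sigma_large")
  if (any(!is.finite(frame))) stop("frame contains non-finite pixels")
  f <- matrix(as.numeric(frame), nrow(frame), ncol(frame))
  small <- EBImage::gblur(f, sigma = sigma_small)
  large <- EBImage::gblur(f, sigma = sigma_large)
  as.matrix(small - large)
}

# shift a matrix by (dr, dc), padding with -Inf (for maxima tests)
shift_pad <- function(m, dr, dc, pad = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(pad, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Detect candidate spots in a filtered frame
#'
#' Local maxima (8-neighborhood, strictly greater than all neighbors
#' with ties broken toward the top-left) whose filtered value exceeds
#' `mean + k_threshold * sd` of the filtered frame. Maxima within
#' `roi_size` pixels (Euclidean) of a stronger maximum are suppressed.
#'
#' @param filtered band-pass filtered frame from [bandpass_filter()].
#' @param k_threshold threshold multiplier on the frame sd; default 5.
#' @param roi_size ROI side length K (odd); also the suppression
#'   distance. Default 7.
#' @param frame_index frame number recorded with each candidate.
#' @return `data.frame` with columns `frame`, `row`, `col` (0-based
#'   peak pixel) and `value` (peak filtered value), ordered by
#'   `(frame, row, col)`. Zero rows if nothing passes the threshold.
#' @export
detect_spots <- function(filtered, k_threshold = 5, roi_size = 7L,
                         frame_index = 1L) {
  stopifnot(is.matrix(filtered), roi_size %% 2 == 1)
  thr <- mean(filtered) + k_threshold * stats::sd(filtered)
  is_max <- filtered > thr
  if (any(is_max)) {
    for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))) {
      is_max <- is_max & (filtered > shift_pad(filtered, d[1], d[2]))
      }
    for (d in list(c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
      is_max <- is_max & (filtered >= shift_pad(filtered, d[1], d[2]))
    }
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(frame = integer(), row = integer(),
                      col = integer(), value = numeric()))
  val <- filtered[idx]
  ord <- order(-val, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]; val <- val[ord]
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      j <- (i + 1):nrow(idx)
      d2 <- (idx[j, 1] - idx[i, 1])^2 + (idx[j, 2] - idx[i, 2])^2
      keep[j][d2 < roi_size^2] <- FALSE
    }
  }
  out <- data.frame(frame = frame_index,
                    row = idx[keep, 1] - 1L, col = idx[keep, 2] - 1L,
                    value = val[keep])
  out <- out[order(out$row, out$col), ]
  rownames(out) <- NULL
  out
}

#' Phasor sub-pixel localization of a spot ROI
#'
#' Estimates the spot center from the phase of the first-harmonic
#' discrete Fourier coefficient of the ROI along each axis:
#' `F_x = sum I(r, c) exp(-2*pi*i*c/K)` (and analogously over rows).
#' The phase is converted to a position and referenced to the ROI
#' center, so a symmetric spot centered in the ROI yields `(0, 0)`.
#' Offsets are wrapped into `(-K/2, K/2]`.
#'
#' @param roi square numeric matrix with odd side K, nonnegative.
#' @return numeric `c(dx, dy)`: sub-pixel offset of the spot from the
#'   ROI center pixel, x along columns, y along rows.
#' @export
phasor_localize <- function(roi) {
  stopifnot(is.matrix(roi), nrow(roi) == ncol(roi), nrow(roi) %% 2 == 1)
  if (any(roi < 0)) stop("ROI must be nonnegative")
  if (all(roi == 0)) stop("no signal in ROI")
  k <- nrow(roi)
  c0 <- (k - 1) / 2
  w <- exp(-2i * pi * (0:(k - 1)) / k)
  fx <- sum(colSums(roi) * w)
  fy <- sum(rowSums(roi) * w)
  # spot at center + d gives phase -2*pi*(c0 + d)/K
  wrap <- function(ph) {
    d <- -ph * k / (2 * pi) - c0
    ((d + k / 2) %% k) - k / 2
  }
  c(dx = wrap(Arg(fx)), dy = wrap(Arg(fy)))
}

#' Detect and localize molecules across a whole movie
#'
#' Runs [bandpass_filter()], [detect_spots()] and [phasor_localize()]
#' on every frame independently. Candidates whose ROI would extend past
#' the image edge are dropped (their count is recorded, not padded).
#' Intensity is the ROI photon sum minus `K^2` times the median of the
#' ROI border pixels (a local background estimate).
#'
#' Coordinates: `x_px`/`y_px` are 0-based pixel-center coordinates
#' (the spot's peak pixel `c` contributes `x_px = c + dx`); `x_um =
#' (x_px + 0.5) * pixel_size` places them in the same corner-origin
#' continuous frame the simulator's ground truth uses.
#'
#' @param movie an `spt_movie` (see [spt_movie()], [read_movie()]).
#' @param sigma_small,sigma_large band-pass scales in px.
#' @param k_threshold detection threshold multiplier.
#' @param roi_size ROI side K (odd px).
#' @return `data.frame` of localizations sorted by `(frame, y_px,
#'   x_px)`: `frame`, `x_px`, `y_px`, `x_um`, `y_um`, `intensity`,
#'   `peak_row`, `peak_col`. Per-frame candidate/dropped counts are
#'   attached as attribute `"counts"`.
#' @export
localize_movie <- function(movie, sigma_small = 1, sigma_large = 3,
                           k_threshold = 5, roi_size = 7L) {
  stopifnot(inherits(movie, "spt_movie"))
  half <- roi_size %/% 2L
  res <- vector("list", length(movie$frames))
  counts <- matrix(0L, length(movie$frames), 2,
                   dimnames = list(NULL, c("candidates", "edge_dropped")))
  for (t in seq_along(movie$frames)) {
    fr <- movie$frames[[t]]
    filt <- bandpass_filter(fr, sigma_small, sigma_large)
    cand <- detect_spots(filt, k_threshold, roi_size, frame_index = t)
    counts[t, 1] <- nrow(cand)
    if (nrow(cand) == 0) next
    in_img <- cand$row >= half & cand$row < nrow(fr) - half &
      cand$col >= half & cand$col < ncol(fr) - half
    counts[t, 2] <- sum(!in_img)
    cand <- cand[in_img, , drop = FALSE]
    if (nrow(cand) == 0) next
    loc <- lapply(seq_len(nrow(cand)), function(i) {
      r <- cand$row[i]; c <- cand$col[i]
      roi <- fr[(r - half):(r + half) + 1L, (c - half):(c + half) + 1L]
      off <- phasor_localize(roi)
      border <- c(roi[1, ], roi[roi_size, ], roi[-c(1, roi_size), 1],
                  roi[-c(1, roi_size), roi_size])
      c(x = c + off[["dx"]], y = r + off[["dy"]],
        intensity = sum(roi) - roi_size^2 * stats::median(border))
    })
    loc <- do.call(rbind, loc)
    res[[t]] <- data.frame(frame = t, x_px = loc[, "x"], y_px = loc[, "y"],
                           x_um = (loc[, "x"] + 0.5) * movie$pixel_size,
                           y_um = (loc[, "y"] + 0.5) * movie$pixel_size,
                           intensity = loc[, "intensity"],
                           peak_row = cand$row, peak_col = cand$col)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(frame = integer(), x_px = numeric(),
                      y_px = numeric(), x_um = numeric(), y_um = numeric(),
                      intensity = numeric(), peak_row = integer(),
                      peak_col = integer())
  out <- out[order(out$frame, out$y_px, out$x_px), ]
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  out
}
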