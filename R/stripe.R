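#' Measure stripe, nucleus-remainder and background brightness
#'
#' Per-timepoint mean pixel brightness of the three hand-drawn
#' regions used for recruitment quantification: the irradiated stripe
#' (Ax), the rest of the nucleus avoiding the stripe (Cx), and the
#' background (B). The stripe mask may be supplied per timepoint
#' (cells migrate during long acquisitions); the nucleus-remainder is
#' always recomputed as nucleus minus stripe.
#'
#' @param frames list of numeric matrices (one per timepoint).
#' @param stripe_mask logical matrix, or a list of one mask per
#'   timepoint.
#' @param nucleus_mask logical matrix (the whole nucleus, including
#'   the stripe); may also be a per-timepoint list.
#' @param background_mask logical matrix or per-timepoint list.
#' @param cell_id label carried into the output.
#' @return `data.frame` with columns `cell_id`, `timepoint`, `Ax`,
#'   `Cx`, `B`.
#' @export
measure_regions <- function(frames, stripe_mask, nucleus_mask,
                            background_mask, cell_id = "cell1") {
  n <- length(frames)
  get_mask <- function(m, t, name) {
    mm <- if (is.list(m)) m[[t]] else m
    check_mask(mm, name)
    mm
  }
  out <- vector("list", n)
  for (t in seq_len(n)) {
    img <- frames[[t]]
    s <- get_mask(stripe_mask, t, "stripe_mask")
    nu <- get_mask(nucleus_mask, t, "nucleus_mask")
    bg <- get_mask(background_mask, t, "background_mask")
    if (any(s & !nu))
      stop(sprintf("stripe_mask extends outside nucleus_mask at timepoint %d", t))
    rem <- nu & !s
    if (!any(rem))
      stop(sprintf("empty region 'nucleus remainder' at timepoint %d", t))
    out[[t]] <- data.frame(cell_id = cell_id, timepoint = t,
                           Ax = mean(img[s]), Cx = mean(img[rem]),
                           B = mean(img[bg]))
  }
  do.call(rbind, out)
}

#' Relative stripe brightness Sx
#'
#' Background-corrected stripe-to-nucleus brightness ratio:
#' `Sx = (Ax - B) / (Cx - B)`, where Ax is the stripe mean, Cx the
#' nucleus-remainder mean and B the background mean. Invariant under
#' affine rescaling of the image (gain and offset cancel).
#'
#' @param Ax stripe mean brightness.
#' @param Cx nucleus-remainder mean brightness.
#' @param B background mean brightness.
#' @return Sx (vectorized over the inputs).
#' @export
compute_sx <- function(Ax, Cx, B) {
  if (any(Cx <= B)) stop("nucleus not above background (Cx <= B)")
  (Ax - B) / (Cx - B)
}

#' Normalize an Sx time series to its first timepoint
#'
#' Subtracts `raw[1] - 1` from every timepoint, so the pre-irradiation
#' value is exactly 1 (e.g. a first-timepoint value of 1.12 leads to
#' 0.12 being subtracted from all timepoints). The additive shift
#' preserves all differences between timepoints.
#'
#' @param sx_raw numeric vector of raw Sx values, time order, the
#'   first element pre-irradiation.
#' @return normalized vector with `[1] == 1`.
#' @export
normalize_series <- function(sx_raw) {
  stopifnot(length(sx_raw) >= 1)
  sx_raw - (sx_raw[1] - 1)
}

#' Per-cell recruitment series
#'
#' Composes [measure_regions()], [compute_sx()] and
#' [normalize_series()] for one cell.
#'
#' @inheritParams measure_regions
#' @param normalize apply first-timepoint normalization per cell
#'   (default TRUE; set FALSE to normalize only the cross-cell
#'   average later, see [aggregate_condition()]).
#' @return `data.frame` (class `cell_series`) with columns `cell_id`,
#'   `timepoint`, `Ax`, `Cx`, `B`, `sx_raw`, `sx_norm`.
#' @export
cell_series <- function(frames, stripe_mask, nucleus_mask,
                        background_mask, cell_id = "cell1",
                        normalize = TRUE) {
  m <- measure_regions(frames, stripe_mask, nucleus_mask,
                       background_mask, cell_id)
  m$sx_raw <- compute_sx(m$Ax, m$Cx, m$B)
  m$sx_norm <- if (normalize) normalize_series(m$sx_raw) else m$sx_raw
  class(m) <- c("cell_series", "data.frame")
  m
}

#' Aggregate per-cell Sx series into a condition curve
#'
#' Per-timepoint mean and standard error over cells of the normalized
#' Sx, SEM defined as the sample standard deviation (n - 1
#' denominator) divided by `sqrt(n cells)`. With a single cell the
#' SEM is reported as 0 with a warning. If the per-cell series are
#' unnormalized (`normalize = FALSE` in [cell_series()]), set
#' `normalize_mean = TRUE` to apply the first-timepoint shift to the
#' averaged curve instead.
#'
#' @param series list of [cell_series()] data frames sharing one
#'   timepoint grid.
#' @param condition condition label.
#' @param normalize_mean shift the averaged curve so its first
#'   timepoint equals 1 (default FALSE; per-cell normalization is the
#'   default upstream).
#' @return object of class `recruitment_curve`: `data.frame` with
#'   `timepoint`, `mean`, `sem`, `n`, and attributes `condition`.
#' @export
aggregate_condition <- function(series, condition = "condition",
                                normalize_mean = FALSE) {
  stopifnot(length(series) >= 1)
  tps <- series[[1]]$timepoint
  for (s in series)
    if (!identical(s$timepoint, tps))
      stop("cells measured on different timepoint grids")
  mat <- vapply(series, function(s) s$sx_norm, numeric(length(tps)))
  mat <- matrix(mat, nrow = length(tps))
  n <- ncol(mat)
  mu <- rowMeans(mat)
  if (n == 1) {
    warning("single cell: SEM reported as 0")
    sem <- rep(0, length(tps))
  } else {
    sem <- apply(mat, 1, stats::sd) / sqrt(n)
  }
  if (normalize_mean) mu <- normalize_series(mu)
  out <- data.frame(timepoint = tps, mean = mu, sem = sem, n = n)
  attr(out, "condition") <- condition
  class(out) <- c("recruitment_curve", "data.frame")
  out
}

#' Closed-form SEM of a simulated normalized Sx curve
#'
#' Standard error of the cross-cell mean normalized Sx implied by a
#' stripe simulation's own noise model, by the delta method: each
#' region mean carries variance `(noise_sd^2 + 1/12)/n_px` (pixel
#' noise plus integer rounding), Sx propagates them as
#' `[var_A + Sx^2 var_C + (1 - Sx)^2 var_B]/(Cx - B)^2`, and
#' first-timepoint normalization adds the anchor timepoint's variance.
#' Useful as a calibrated yardstick for parameter-recovery checks,
#' where the sample SEM over a handful of cells is itself noisy.
#'
#' @param config a [stripe_sim_config()].
#' @param n_cells number of simulated cells averaged.
#' @return numeric vector: per-timepoint SEM of the mean normalized
#'   Sx.
#' @export
stripe_theoretical_sem <- function(config, n_cells) {
  stopifnot(inherits(config, "stripe_sim_config"))
  t_post <- pmax(0, seq_len(config$n_timepoints) -
                   config$pre_irradiation_timepoints)
  sx <- 1 + ifelse(t_post > 0, config$recruitment_amplitude *
                     (1 - exp(-config$recruitment_rate * t_post)), 0) /
    (config$nucleus_baseline - config$background_level)
  v_px <- config$noise_sd^2 + 1 / 12
  v_a <- v_px / sum(config$stripe_region)
  v_c <- v_px / sum(config$nucleus_region & !config$stripe_region)
  v_b <- v_px / sum(config$background_region)
  denom <- (config$nucleus_baseline - config$background_level)^2
  v_sx <- (v_a + sx^2 * v_c + (1 - sx)^2 * v_b) / denom
  sqrt((v_sx + v_sx[1]) / n_cells)
}

#' @export
print.recruitment_curve <- function(x, ...) {
  cat(sprintf("Recruitment curve '%s' (%d cells, %d timepoints)\n",
              attr(x, "condition"), x$n[1], nrow(x)))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Plot a recruitment curve with SEM error bars
#'
#' @param x a `recruitment_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.recruitment_curve <- function(x, ...) {
  graphics::plot(x$timepoint, x$mean, type = "b", pch = 16,
                 xlab = "timepoint", ylab = "normalized Sx",
                 ylim = range(c(x$mean - x$sem, x$mean + x$sem)), ...)
  graphics::arrows(x$timepoint, x$mean - x$sem, x$timepoint,
                   x$mean + x$sem, angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
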