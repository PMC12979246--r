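#' Lag-1 mean squared displacement of one track
#'
#' Mean of squared displacements over single-frame steps, in um^2.
#' Steps spanning a missed frame (a 2-frame jump bridged by the
#' tracker's memory) are excluded rather than rescaled, so the
#' estimate is an unbiased lag-1 MSD.
#'
#' @param x_um,y_um numeric position vectors in um, frame order.
#' @param frame integer frame numbers (strictly increasing).
#' @return msd in um^2.
#' @export
one_step_msd <- function(x_um, y_um, frame) {
  stopifnot(length(x_um) == length(y_um),
            length(x_um) == length(frame), length(x_um) >= 2)
  single <- diff(frame) == 1
  if (!any(single)) stop("no single-frame steps")
  mean((diff(x_um)^2 + diff(y_um)^2)[single])
}

#' Apparent diffusion coefficient from a lag-1 MSD
#'
#' For 2-D Brownian motion, `D = MSD / (4 * dt)`.
#'
#' @param msd lag-1 mean squared displacement in um^2.
#' @param frame_interval frame interval dt in seconds.
#' @return apparent D in um^2/s.
#' @export
apparent_d <- function(msd, frame_interval) {
  stopifnot(frame_interval > 0)
  msd / (4 * frame_interval)
}

#' Classify a track as chromatin-bound or mobile
#'
#' Bound if the apparent diffusion coefficient is at or below the
#' threshold (`D <= d_threshold`, inclusive), mobile otherwise.
#'
#' @param d_app apparent diffusion coefficient(s), um^2/s, >= 0.
#' @param d_threshold classification threshold, um^2/s (default 0.3).
#' @return character vector, `"bound"` or `"mobile"`.
#' @export
classify_track <- function(d_app, d_threshold = 0.3) {
  if (any(d_app < 0)) stop("d_app must be nonnegative")
  ifelse(d_app <= d_threshold, "bound", "mobile")
}

#' Fraction of bound tracks
#'
#' @param labels character vector of `"bound"`/`"mobile"` labels, one
#'   per track.
#' @return fraction of tracks labeled bound, in `[0, 1]`.
#' @export
bound_fraction <- function(labels) {
  if (length(labels) == 0) stop("no tracks")
  mean(labels == "bound")
}

#' Normalized histogram of apparent diffusion coefficients
#'
#' @param d_app apparent diffusion coefficients, um^2/s.
#' @param bin_edges increasing bin edges (default `seq(0, 2, 0.05)`);
#'   values above the last edge are collected in an overflow bin.
#' @return `data.frame` with `lower`, `upper` (Inf for the overflow
#'   bin) and `mass` summing to 1.
#' @export
d_histogram <- function(d_app, bin_edges = seq(0, 2, by = 0.05)) {
  if (length(d_app) == 0) stop("no tracks")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  edges <- c(bin_edges, Inf)
  cnt <- tabulate(findInterval(d_app, edges,
                               rightmost.closed = FALSE, left.open = FALSE),
                  nbins = length(edges) - 1)
  data.frame(lower = edges[-length(edges)], upper = edges[-1],
             mass = cnt / length(d_app))
}

#' Per-track diffusion analysis
#'
#' The quantitative core of the tracking pipeline: computes each
#' track's lag-1 MSD, the apparent diffusion coefficient
#' `D = MSD/(4*dt)`, and the bound/mobile label at `d_threshold`, and
#' summarizes the bound fraction and the D distribution. Returns a
#' classed object with `print`, `summary`, `coef`, `plot` and
#' `as.data.frame` methods.
#'
#' @param tracks track `data.frame` (from [build_tracks()] +
#'   [filter_tracks()], or [truth_to_tracks()]) with columns
#'   `track_id`, `frame`, `x_um`, `y_um`.
#' @param frame_interval frame interval in seconds (default 0.020).
#' @param d_threshold bound/mobile threshold in um^2/s (default 0.3).
#' @param bin_edges histogram bin edges, see [d_histogram()].
#' @param cell_id optional label carried into summaries.
#' @return object of class `spt_diffusion`: list with `per_track`
#'   (`data.frame`: `track_id`, `n_steps` single-frame steps,
#'   `msd_um2`, `d_app`, `label`), `bound_fraction`, `n_tracks`,
#'   `n_dropped_gap_only` (tracks whose every step spans a missed
#'   frame carry no lag-1 information and are excluded), `histogram`,
#'   `frame_interval`, `d_threshold`, `cell_id`.
#' @export
spt_diffusion <- function(tracks, frame_interval = 0.020,
                          d_threshold = 0.3,
                          bin_edges = seq(0, 2, by = 0.05),
                          cell_id = NA_character_) {
  req <- c("track_id", "frame", "x_um", "y_um")
  if (!all(req %in% names(tracks)))
    stop("tracks must have columns track_id, frame, x_um, y_um")
  if (nrow(tracks) == 0) stop("no tracks")
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  ids <- unique(tracks$track_id)
  by_track <- split(tracks, factor(tracks$track_id, levels = ids))
  n_single <- vapply(by_track, function(tr) sum(diff(tr$frame) == 1),
                     integer(1))
  # a track whose every step spans a gap has no lag-1 information
  usable <- n_single >= 1
  if (!any(usable)) stop("no tracks with single-frame steps")
  per <- lapply(by_track[usable], function(tr)
    one_step_msd(tr$x_um, tr$y_um, tr$frame))
  per <- data.frame(track_id = ids[usable],
                    n_steps = n_single[usable],
                    msd_um2 = unlist(per, use.names = FALSE),
                    row.names = NULL)
  per$d_app <- apparent_d(per$msd_um2, frame_interval)
  per$label <- classify_track(per$d_app, d_threshold)
  obj <- list(per_track = per,
              bound_fraction = bound_fraction(per$label),
              n_tracks = nrow(per),
              n_dropped_gap_only = sum(!usable),
              histogram = d_histogram(per$d_app, bin_edges),
              frame_interval = frame_interval,
              d_threshold = d_threshold,
              cell_id = cell_id)
  class(obj) <- "spt_diffusion"
  obj
}

#' @export
print.spt_diffusion <- function(x, ...) {
  cat("Per-track diffusion analysis (lag-1 MSD, D = MSD/(4*dt))\n")
  if (!is.na(x$cell_id)) cat(sprintf("  cell: %s\n", x$cell_id))
  cat(sprintf("  tracks: %d   dt: %g s   bound threshold: D <= %g um^2/s\n",
              x$n_tracks, x$frame_interval, x$d_threshold))
  cat(sprintf("  bound fraction: %.3f   median D: %.3f um^2/s\n",
              x$bound_fraction, stats::median(x$per_track$d_app)))
  invisible(x)
}

#' @export
summary.spt_diffusion <- function(object, ...) {
  d <- object$per_track$d_app
  out <- list(n_tracks = object$n_tracks,
              bound_fraction = object$bound_fraction,
              d_quartiles = stats::quantile(d, c(0.25, 0.5, 0.75)),
              mean_d = mean(d),
              d_threshold = object$d_threshold,
              frame_interval = object$frame_interval,
              cell_id = object$cell_id)
  class(out) <- "summary.spt_diffusion"
  out
}

#' @export
print.summary.spt_diffusion <- function(x, ...) {
  cat(sprintf("tracks: %d\nbound fraction (D <= %g): %.4f\n",
              x$n_tracks, x$d_threshold, x$bound_fraction))
  cat(sprintf("mean D: %.4f um^2/s; quartiles: %.4f / %.4f / %.4f\n",
              x$mean_d, x$d_quartiles[1], x$d_quartiles[2],
              x$d_quartiles[3]))
  invisible(x)
}

#' @export
coef.spt_diffusion <- function(object, ...) {
  c(bound_fraction = object$bound_fraction,
    mean_d = mean(object$per_track$d_app),
    median_d = stats::median(object$per_track$d_app))
}

#' @export
as.data.frame.spt_diffusion <- function(x, ...) x$per_track

#' Plot the distribution of apparent diffusion coefficients
#'
#' Bar plot of the normalized D histogram with the bound/mobile
#' threshold marked.
#'
#' @param x an `spt_diffusion` object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.spt_diffusion <- function(x, ...) {
  h <- x$histogram
  fin <- is.finite(h$upper)
  mids <- (h$lower[fin] + h$upper[fin]) / 2
  graphics::barplot(h$mass[fin], names.arg = sprintf("%.2f", mids),
                    xlab = expression(D ~ (mu * m^2 / s)),
                    ylab = "fraction of tracks",
                    border = NA, space = 0, ...)
  at <- (x$d_threshold - h$lower[1]) / (h$upper[1] - h$lower[1])
  graphics::abline(v = at, lty = 2)
  invisible(x)
}

#' Compare per-cell bound fractions across conditions (one-way ANOVA)
#'
#' Fixed-effects one-way ANOVA on per-cell bound fractions, the
#' cross-condition test used for bound-fraction bar plots (means +/-
#' SD per condition, `*p <= 0.05`).
#'
#' @param fractions named list: one numeric vector of per-cell bound
#'   fractions per condition (>= 2 conditions, >= 2 cells each).
#' @return object of class `spt_anova`: list with `F`, `df`, `p_value`
#'   and `per_condition` (`data.frame`: condition, n, mean, sd).
#' @export
compare_conditions <- function(fractions) {
  if (length(fractions) < 2) stop("need at least 2 conditions")
  n_cells <- vapply(fractions, length, integer(1))
  if (any(n_cells < 2))
    stop(sprintf("condition '%s' has fewer than 2 cells",
                 names(fractions)[which(n_cells < 2)[1]]))
  if (is.null(names(fractions)))
    names(fractions) <- paste0("condition", seq_along(fractions))
  dat <- data.frame(
    fraction = unlist(fractions, use.names = FALSE),
    condition = factor(rep(names(fractions), n_cells),
                       levels = names(fractions)))
  fit <- stats::aov(fraction ~ condition, data = dat)
  tab <- summary(fit)[[1]]
  out <- list(F = tab[1, "F value"],
              df = c(between = tab[1, "Df"], within = tab[2, "Df"]),
              p_value = tab[1, "Pr(>F)"],
              per_condition = data.frame(
                condition = names(fractions), n = as.integer(n_cells),
                mean = vapply(fractions, mean, numeric(1)),
                sd = vapply(fractions, stats::sd, numeric(1)),
                row.names = NULL))
  # all values identical: 0/0 -> NaN; define F = 0, p = 1
  if (is.nan(out$F)) { out$F <- 0; out$p_value <- 1 }
  # perfect separation: positive/0 -> Inf, p = 0
  if (is.infinite(out$F) && is.na(out$p_value)) out$p_value <- 0
  class(out) <- "spt_anova"
  out
}

#' @export
print.spt_anova <- function(x, ...) {
  cat("One-way ANOVA on per-cell bound fractions\n")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n",
              x$df["between"], x$df["within"], x$F, x$p_value))
  df <- x$per_condition
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %s: mean %.3f +/- SD %.3f (n = %d cells)\n",
                df$condition[i], df$mean[i], df$sd[i], df$n[i]))
  invisible(x)
}

#' Expected bound fraction under the chi-square track-D model
#'
#' For a track of `n` independent single-frame steps with true
#' diffusion coefficient `d` and per-axis localization error `sigma`,
#' the lag-1 MSD satisfies `msd * 2n / (4 dt d_eff) ~ chi^2_(2n)` with
#' `d_eff = d + sigma^2/dt`, so the probability the apparent D falls
#' at or below the threshold is
#' `pchisq(threshold * 2n / d_eff, df = 2n)`. The expected classified
#' bound fraction of a two-population mixture follows in closed form.
#'
#' @param f_bound true bound fraction.
#' @param d_bound,d_mobile true diffusion coefficients, um^2/s.
#' @param n_steps number of single-frame steps per track (scalar or
#'   vector, averaged if a vector).
#' @param frame_interval dt in seconds.
#' @param loc_sigma per-axis localization error in um.
#' @param d_threshold classification threshold, um^2/s.
#' @return expected fraction of tracks classified bound.
#' @export
expected_bound_fraction <- function(f_bound, d_bound, d_mobile, n_steps,
                                    frame_interval, loc_sigma = 0,
                                    d_threshold = 0.3) {
  p_le <- function(d, n) {
    d_eff <- d + loc_sigma^2 / frame_interval
    stats::pchisq(d_threshold * 2 * n / d_eff, df = 2 * n)
  }
  mean(f_bound * p_le(d_bound, n_steps) +
         (1 - f_bound) * p_le(d_mobile, n_steps))
}
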