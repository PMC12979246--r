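# Test oracles kept independent of the implementation paths they check.

# Noiseless pixel-integrated Gaussian ROI with the spot at
# (center + ox, center + oy) pixels. Built directly from pnorm edge
# differences (same physics as the renderer but standalone).
make_spot_roi <- function(k = 7, ox = 0, oy = 0, photons = 1000,
                          sigma = 1.3, background = 0) {
  c0 <- (k - 1) / 2
  fx <- diff(pnorm(0:k, mean = c0 + ox + 0.5, sd = sigma))
  fy <- diff(pnorm(0:k, mean = c0 + oy + 0.5, sd = sigma))
  background + photons * outer(fy, fx)
}

# Least-squares Gaussian-fit localizer: fits center, amplitude and
# offset of a pixel-integrated Gaussian to the ROI by Nelder-Mead.
# Used as the independent reference for the phasor localizer.
gaussfit_localize <- function(roi, sigma = 1.3) {
  k <- nrow(roi)
  c0 <- (k - 1) / 2
  model <- function(p) {
    fx <- diff(pnorm(0:k, mean = c0 + p[1] + 0.5, sd = sigma))
    fy <- diff(pnorm(0:k, mean = c0 + p[2] + 0.5, sd = sigma))
    p[4] + p[3] * outer(fy, fx)
  }
  obj <- function(p) sum((roi - model(p))^2)
  fit <- optim(c(0, 0, sum(roi), 0), obj,
               control = list(maxit = 5000, reltol = 1e-14))
  c(dx = fit$par[1], dy = fit$par[2])
}

# Exhaustive one-frame assignment: enumerate every one-to-one matching
# of tracks to localizations within the radius; pick max links, then
# min total squared distance, then the lexicographically smallest
# assignment vector. Pure enumeration, no pruning.
oracle_assign <- function(track_pos, loc_pos, radius) {
  m <- nrow(track_pos); n <- nrow(loc_pos)
  best <- rep(NA_integer_, m)
  if (m == 0 || n == 0) return(best)
  d2 <- outer(track_pos[, 1], loc_pos[, 1], "-")^2 +
    outer(track_pos[, 2], loc_pos[, 2], "-")^2
  best_key <- c(-1, Inf)
  assign <- rep(NA_integer_, m)
  lex_less <- function(a, b) {
    av <- ifelse(is.na(a), n + 1L, a); bv <- ifelse(is.na(b), n + 1L, b)
    d <- which(av != bv)
    length(d) > 0 && av[d[1]] < bv[d[1]]
  }
  rec <- function(i) {
    if (i > m) {
      links <- sum(!is.na(assign))
      cost <- sum(d2[cbind(which(!is.na(assign)),
                           assign[!is.na(assign)])])
      better <- links > best_key[1] ||
        (links == best_key[1] && cost < best_key[2] - 1e-12) ||
        (links == best_key[1] && abs(cost - best_key[2]) <= 1e-12 &&
           lex_less(assign, best))
      if (better) { best_key <<- c(links, cost); best <<- assign }
      return(invisible())
    }
    for (j in c(seq_len(n), NA_integer_)) {
      if (!is.na(j) && (j %in% assign[seq_len(i - 1)] ||
                        d2[i, j] > radius^2)) next
      assign[i] <<- j
      rec(i + 1)
      assign[i] <<- NA_integer_
    }
  }
  rec(1L)
  best
}

# Exhaustive reference tracker over a localization table (frame, x, y):
# same radius/memory semantics as build_tracks but built on
# oracle_assign and plain bookkeeping. Returns a list of integer
# vectors of row indices, one per track, in creation order.
oracle_build_tracks <- function(locs, radius = 8, memory = 1) {
  tracks <- list()       # per track: vector of row indices
  last_pos <- list()     # per track: last (x, y)
  last_frame <- c()      # per track: frame last seen
  open <- c()            # indices of open tracks
  frames <- sort(unique(locs$frame))
  for (f in frames) {
    open <- open[f - last_frame[open] <= memory + 1]
    rows <- which(locs$frame == f)
    tp <- do.call(rbind, last_pos[open])
    if (is.null(tp)) tp <- matrix(numeric(), 0, 2)
    lp <- cbind(locs$x_px[rows], locs$y_px[rows])
    a <- oracle_assign(tp, lp, radius)
    taken <- rep(FALSE, length(rows))
    for (i in seq_along(open)) {
      j <- a[i]
      if (!is.na(j)) {
        ti <- open[i]
        tracks[[ti]] <- c(tracks[[ti]], rows[j])
        last_pos[[ti]] <- lp[j, ]
        last_frame[ti] <- f
        taken[j] <- TRUE
      }
    }
    for (j in which(!taken)) {
      ti <- length(tracks) + 1
      tracks[[ti]] <- rows[j]
      last_pos[[ti]] <- lp[j, ]
      last_frame[ti] <- f
      open <- c(open, ti)
    }
  }
  tracks
}

# Canonical form of a track table for comparison with the oracle:
# sorted list of row-index vectors.
track_partition <- function(tracks_df, locs) {
  key <- paste(locs$frame, locs$x_px, locs$y_px)
  row_of <- match(paste(tracks_df$frame, tracks_df$x_px, tracks_df$y_px),
                  key)
  parts <- split(row_of, tracks_df$track_id)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, min, numeric(1)))])
}

# Random linking scene: n_spots molecules doing a jittered walk with
# occasional disappearance, in a small field.
random_scene <- function(seed, n_spots = 6, n_frames = 10, size = 32) {
  set.seed(seed)
  n <- sample(2:n_spots, 1)
  out <- list()
  for (m in seq_len(n)) {
    x <- runif(1, 4, size - 4); y <- runif(1, 4, size - 4)
    for (f in seq_len(n_frames)) {
      if (runif(1) < 0.15) next  # missed detection
      x <- min(max(x + rnorm(1, 0, 2), 0), size)
      y <- min(max(y + rnorm(1, 0, 2), 0), size)
      out[[length(out) + 1]] <- data.frame(frame = f, x_px = x, y_px = y)
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$frame, df$y_px, df$x_px), ]
  rownames(df) <- NULL
  df
}
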