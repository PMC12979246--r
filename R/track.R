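#' Linking parameters
#'
#' The radius-and-memory linking rule: a localization may extend a
#' track if it lies within `link_radius` pixels of the track's last
#' position; a track may skip at most `memory` consecutive frames
#' (blinking or a missed detection); tracks with fewer than
#' `min_steps` links are discarded from analysis.
#'
#' @param link_radius maximum link distance in pixels (default 8).
#' @param memory frames a track may go undetected, 0 or 1 (default 1).
#' @param min_steps minimum number of linked steps kept (default 4,
#'   i.e. at least 5 localizations per track).
#' @return object of class `link_params`.
#' @export
link_params <- function(link_radius = 8, memory = 1L, min_steps = 4L) {
  stopifnot(link_radius > 0, memory %in% c(0L, 1L), min_steps >= 1)
  structure(list(link_radius = link_radius, memory = as.integer(memory),
                 min_steps = as.integer(min_steps)),
            class = "link_params")
}

#' One-to-one frame linking by minimum total squared distance
#'
#' Matches active tracks to the localizations of one frame. Feasible
#' pairs are those within `link_radius` (Euclidean, pixels); among all
#' one-to-one matchings over feasible pairs the one with the most
#' links is chosen, with total squared distance as tie-breaker and a
#' deterministic lexicographic order (track index, then localization
#' index) breaking exact cost ties. Solved exactly per connected
#' component of the feasibility graph by depth-first search with
#' pruning.
#'
#' @param track_pos numeric matrix (m x 2) of last known track
#'   positions (columns x, y, pixels).
#' @param loc_pos numeric matrix (n x 2) of new localization positions.
#' @param link_radius maximum link distance in pixels.
#' @return integer vector of length m: for each track the index of the
#'   assigned localization, or `NA` if unassigned.
#' @export
link_frame <- function(track_pos, loc_pos, link_radius = 8) {
  m <- nrow(track_pos); n <- nrow(loc_pos)
  match_out <- rep(NA_integer_, m)
  if (m == 0 || n == 0) return(match_out)
  d2 <- outer(track_pos[, 1], loc_pos[, 1], "-")^2 +
    outer(track_pos[, 2], loc_pos[, 2], "-")^2
  feas <- d2 <= link_radius^2
  if (!any(feas)) return(match_out)

  # connected components of the bipartite feasibility graph
  comp_t <- rep(0L, m); comp_l <- rep(0L, n); nc <- 0L
  for (s in seq_len(m)) {
    if (comp_t[s] || !any(feas[s, ])) next
    nc <- nc + 1L
    qt <- s
    while (length(qt)) {
      t0 <- qt[1]; qt <- qt[-1]
      if (comp_t[t0]) next
      comp_t[t0] <- nc
      for (l0 in which(feas[t0, ] & comp_l == 0L)) {
        comp_l[l0] <- nc
        qt <- c(qt, which(feas[, l0] & comp_t == 0L))
      }
    }
  }

  for (k in seq_len(nc)) {
    tr <- which(comp_t == k); lc <- which(comp_l == k)
    sub <- matrix(d2[tr, lc], length(tr), length(lc))
    sub[sub > link_radius^2] <- Inf
    best <- solve_component(sub)
    match_out[tr] <- ifelse(is.na(best), NA_integer_, lc[best])
  }
  match_out
}

# Exact assignment on a small cost matrix (Inf = infeasible):
# maximize number of assignments, then minimize total cost.
# DFS over rows with branch-and-bound; first-found wins exact ties,
# giving lexicographic determinism.
solve_component <- function(cost) {
  m <- nrow(cost); n <- ncol(cost)
  best_assign <- rep(NA_integer_, m)
  best_links <- -1L
  best_cost <- Inf
  used <- rep(FALSE, n)
  assign <- rep(NA_integer_, m)
  recurse <- function(i, links, tot) {
    if (i > m) {
      if (links > best_links ||
          (links == best_links && tot < best_cost - 1e-12)) {
        best_links <<- links; best_cost <<- tot
        best_assign <<- assign
      }
      return(invisible())
    }
    # bound: even linking every remaining row can't beat best
    if (links + (m - i + 1) < best_links) return(invisible())
    for (j in seq_len(n)) {
      if (!used[j] && is.finite(cost[i, j])) {
        if (links + 1L + (m - i) > best_links ||
            tot + cost[i, j] < best_cost) {
          used[j] <<- TRUE; assign[i] <<- j
          recurse(i + 1L, links + 1L, tot + cost[i, j])
          used[j] <<- FALSE; assign[i] <<- NA_integer_
        }
      }
    }
    recurse(i + 1L, links, tot)
  }
  recurse(1L, 0L, 0)
  best_assign
}

#' Link localizations into tracks
#'
#' Applies [link_frame()] frame by frame. A track unmatched in one
#' frame stays active for `memory` further frames (the same
#' `link_radius`, measured from its last seen position, applies to the
#' gap-spanning link); beyond that it is closed. Unassigned
#' localizations start new tracks. Track ids are deterministic:
#' numbered by first frame, then by localization order within it.
#'
#' @param localizations `data.frame` with columns `frame`, `x_px`,
#'   `y_px` (additional columns such as `x_um`, `y_um`, `intensity`
#'   are carried through), sorted by frame.
#' @param params a [link_params()].
#' @return `data.frame` of the input columns plus `track_id` and
#'   `gap_flag` (TRUE where the link to the previous localization
#'   spans 2 frames), sorted by `(track_id, frame)`.
#' @export
build_tracks <- function(localizations, params = link_params()) {
  stopifnot(inherits(params, "link_params"))
  req <- c("frame", "x_px", "y_px")
  if (!all(req %in% names(localizations)))
    stop("localizations must have columns frame, x_px, y_px")
  if (is.unsorted(localizations$frame))
    stop("localizations must be sorted by frame")
  n <- nrow(localizations)
  track_of <- rep(NA_integer_, n)
  if (n > 0) {
    rows_by_frame <- split(seq_len(n), localizations$frame)
    frames <- as.integer(names(rows_by_frame))
    # active track state: parallel vectors
    act_id <- integer(); act_x <- numeric(); act_y <- numeric()
    act_last <- integer()  # frame last seen
    next_id <- 1L
    for (fi in seq_along(frames)) {
      f <- frames[fi]
      rows <- rows_by_frame[[fi]]
      # retire tracks out of memory reach
      keep <- (f - act_last) <= (params$memory + 1L)
      act_id <- act_id[keep]; act_x <- act_x[keep]
      act_y <- act_y[keep]; act_last <- act_last[keep]
      lx <- localizations$x_px[rows]; ly <- localizations$y_px[rows]
      amatch <- link_frame(cbind(act_x, act_y), cbind(lx, ly),
                           params$link_radius)
      linked_loc <- logical(length(rows))
      for (i in seq_along(act_id)) {
        j <- amatch[i]
        if (!is.na(j)) {
          track_of[rows[j]] <- act_id[i]
          act_x[i] <- lx[j]; act_y[i] <- ly[j]; act_last[i] <- f
          linked_loc[j] <- TRUE
        }
      }
      for (j in which(!linked_loc)) {
        track_of[rows[j]] <- next_id
        act_id <- c(act_id, next_id)
        act_x <- c(act_x, lx[j]); act_y <- c(act_y, ly[j])
        act_last <- c(act_last, f)
        next_id <- next_id + 1L
      }
    }
  }
  out <- localizations
  out$track_id <- track_of
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  gap <- c(FALSE, diff(out$frame) == 2 & diff(out$track_id) == 0)
  if (n == 0) gap <- logical(0)
  out$gap_flag <- gap
  rownames(out) <- NULL
  out
}

#' Discard short tracks
#'
#' Keeps tracks with at least `min_steps` linked steps, i.e. at least
#' `min_steps + 1` localizations (default: tracks with fewer than 4
#' steps — fewer than 5 localizations — are discarded).
#'
#' @param tracks track `data.frame` from [build_tracks()].
#' @param params a [link_params()].
#' @return filtered track `data.frame`; the number of removed tracks
#'   is attached as attribute `"n_removed"`.
#' @export
filter_tracks <- function(tracks, params = link_params()) {
  stopifnot(inherits(params, "link_params"))
  if (nrow(tracks) == 0) {
    attr(tracks, "n_removed") <- 0L
    return(tracks)
  }
  len <- table(tracks$track_id)
  keep_ids <- names(len)[len >= params$min_steps + 1L]
  out <- tracks[as.character(tracks$track_id) %in% keep_ids, ,
                drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- length(len) - length(keep_ids)
  out
}
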