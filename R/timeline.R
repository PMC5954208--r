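#' Convert a session into an alternating walk/stop timeline
#'
#' Replays a walker's session as a robot training timeline in field
#' coordinates: each bout becomes a run of walk elements (one waypoint per
#' step, durations following the walker's own inter-step intervals, led by a
#' zero-duration anchor marking the bout's first step), and each inter-bout
#' stationary period becomes a stop element of duration
#' `min(pause, stop_cap)`. Stationary periods are capped (2 s by default)
#' because a robot is fully stabilized after that long: longer pauses add no
#' training value.
#'
#' Room coordinates map to the field by translating the room center to the
#' field center, meters preserved 1:1 (`grid_cell` rescales if a different
#' grid is wanted).
#'
#' @inheritParams segment_bouts
#' @param stop_cap Maximum stop duration in seconds (default 2).
#' @param grid_cell Field meters per room meter (default 1).
#' @return A [walk_course()] whose elements alternate walk runs and stops;
#'   total walk time equals the summed bout durations, total stop time the
#'   summed capped pauses.
#' @export
session_to_timeline <- function(session, stop_cap = 2,
                                stationary_threshold = 0.5, grid_cell = 1) {
  bouts <- segment_bouts(session, stationary_threshold)
  dims <- room_dims(session)
  cx <- dims[["width"]] / 2
  cy <- dims[["length"]] / 2
  rows <- vector("list", max(1L, 2L * nrow(bouts)))
  j <- 0L
  for (b in seq_len(nrow(bouts))) {
    g <- bouts$steps[[b]]
    if (b > 1L) {
      pause <- bouts$onset[b] - bouts$offset[b - 1L]
      j <- j + 1L
      rows[[j]] <- tibble(mode = "stop", x = NA_real_, y = NA_real_,
                          duration = min(pause, stop_cap))
    }
    j <- j + 1L
    rows[[j]] <- tibble(mode = "walk",
                        x = (g$x - cx) * grid_cell,
                        y = (g$y - cy) * grid_cell,
                        duration = c(0, diff(g$t)))
  }
  walk_course(dplyr::bind_rows(rows[seq_len(j)]),
              course_id = paste0(session_id(session), "-timeline"),
              stop_cap = stop_cap)
}

# Extract the contiguous sub-timeline covering [start, start + duration),
# cycling end-to-start when the timeline is shorter than required. Walk
# elements cut by a boundary are split at the position interpolated along
# the segment, so durations are conserved exactly.
timeline_window <- function(tl, start, duration) {
  d <- tl$duration
  total <- sum(d)
  if (total <= 0) abort("empty timeline", class = "varietywalk_validation_error")
  nr <- nrow(tl)
  prev <- prev_positions(tl)
  cum <- cumsum(d)
  pos <- start %% total
  i <- which(cum > pos + 1e-12)[1L]
  if (is.na(i)) { # start at/after last boundary -> wrap
    i <- 1L
    offset <- 0
  } else {
    offset <- pos - (cum[i] - d[i])
  }
  modes <- character(0); xs <- double(0); ys <- double(0); durs <- double(0)
  remaining <- duration
  guard <- 0L
  while (remaining > 1e-9) {
    guard <- guard + 1L
    if (guard > 10L * nr * (2L + ceiling(duration / total))) {
      abort("timeline windowing failed to terminate")  # nocov
    }
    if (i > nr) { i <- 1L; offset <- 0 }
    di <- d[i]
    if (di - offset <= 1e-12) {
      if (di == 0 && offset == 0) { # zero-duration waypoint anchor
        modes <- c(modes, tl$mode[i]); xs <- c(xs, tl$x[i])
        ys <- c(ys, tl$y[i]); durs <- c(durs, 0)
      }
      i <- i + 1L; offset <- 0
      next
    }
    take <- min(di - offset, remaining)
    if (tl$mode[i] == "stop") {
      modes <- c(modes, "stop"); xs <- c(xs, NA_real_); ys <- c(ys, NA_real_)
      durs <- c(durs, take)
    } else {
      if (offset + take >= di - 1e-12) {
        tx <- tl$x[i]; ty <- tl$y[i]
      } else { # boundary bisects the walk segment: interpolate
        f <- (offset + take) / di
        tx <- prev[i, 1L] + f * (tl$x[i] - prev[i, 1L])
        ty <- prev[i, 2L] + f * (tl$y[i] - prev[i, 2L])
      }
      modes <- c(modes, "walk"); xs <- c(xs, tx); ys <- c(ys, ty)
      durs <- c(durs, take)
    }
    remaining <- remaining - take
    offset <- offset + take
    if (offset >= di - 1e-12) { i <- i + 1L; offset <- 0 }
  }
  tibble(mode = modes, x = xs, y = ys, duration = durs)
}

prev_positions <- function(tl) {
  n <- nrow(tl)
  px <- py <- rep(NA_real_, n)
  lastx <- lasty <- NA_real_
  for (i in seq_len(n)) {
    px[i] <- lastx; py[i] <- lasty
    if (tl$mode[i] == "walk") { lastx <- tl$x[i]; lasty <- tl$y[i] }
  }
  cbind(px, py)
}

#' Randomly sample a fixed-duration block from a timeline
#'
#' Draws a contiguous block of exactly `block_duration` seconds (4 min by
#' default) from the timeline, the start uniform over feasible starts. If
#' the timeline is shorter than the block, it is repeated end-to-start until
#' the duration accumulates. Elements cut by a block boundary are trimmed
#' (walk segments split at the interpolated position) so the block duration
#' is exact.
#'
#' @param timeline A timeline from [session_to_timeline()] (any element
#'   tibble with `mode`, `x`, `y`, `duration`).
#' @param block_duration Seconds (default 240).
#' @param seed Optional integer; if supplied, seeds the start draw.
#' @return An element tibble whose durations sum to `block_duration`, with
#'   the chosen start time (seconds into the timeline) in attribute
#'   `"start"`.
#' @export
sample_block <- function(timeline, block_duration = 240, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(timeline) == 0L || sum(timeline$duration) <= 0) {
    abort("empty timeline", class = "varietywalk_validation_error")
  }
  total <- sum(timeline$duration)
  start <- if (total >= block_duration) {
    runif(1, 0, total - block_duration)
  } else {
    runif(1, 0, total)
  }
  out <- timeline_window(timeline, start, block_duration)
  attr(out, "start") <- start
  out
}
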