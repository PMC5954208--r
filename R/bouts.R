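#' Segment a step stream into walking bouts
#'
#' A walking bout is a maximal run of steps in which every inter-step
#' interval is below the stationary threshold; a pause of at least the
#' threshold (500 ms by default, matching the video-coding convention of
#' ending a bout once the walker is stationary for >= 500 ms) ends the bout.
#' Every step belongs to exactly one bout.
#'
#' @param session A [walk_session()] (or any data frame with `t`, `x`, `y`).
#' @param stationary_threshold Seconds; an inter-step gap `>=` this value
#'   starts a new bout. Default 0.5 s.
#' @return A tibble with one row per bout: `bout` (index), `onset`, `offset`
#'   (seconds, first/last step time), `n_steps`, `path_length` (meters
#'   traveled), `displacement` (start-to-end chord, meters) and `steps`, a
#'   list column of the per-bout step tables.
#' @examples
#' s <- walk_session(data.frame(t = c(0, .4, 1.0, 1.4),
#'                              x = c(1, 1.3, 1.6, 1.9), y = 2))
#' segment_bouts(s)
#' @export
segment_bouts <- function(session, stationary_threshold = 0.5) {
  stopifnot(stationary_threshold > 0)
  steps <- as_tibble(session)
  class(steps) <- setdiff(class(steps), "walk_session")
  if (nrow(steps) == 0L) {
    return(tibble(bout = integer(), onset = double(), offset = double(),
                  n_steps = integer(), path_length = double(),
                  displacement = double(), steps = list()))
  }
  n <- nrow(steps)
  bout <- cumsum(c(1L, as.integer(diff(steps$t) >= stationary_threshold)))
  first <- which(!duplicated(bout))
  last <- c(first[-1L] - 1L, n)
  seg <- sqrt(diff(steps$x)^2 + diff(steps$y)^2)
  within <- bout[-1L] == bout[-n]
  path_length <- rep(0, length(first))
  if (any(within)) {
    pl <- rowsum(seg[within], bout[-n][within])
    path_length[as.integer(rownames(pl))] <- pl[, 1L]
  }
  cols <- steps[c("t", "x", "y", intersect("foot", names(steps)))]
  tibble(bout = seq_along(first),
         onset = steps$t[first], offset = steps$t[last],
         n_steps = last - first + 1L,
         path_length = path_length,
         displacement = sqrt((steps$x[last] - steps$x[first])^2 +
                               (steps$y[last] - steps$y[first])^2),
         steps = lapply(seq_along(first), function(b) {
           cols[first[b]:last[b], , drop = FALSE]
         }))
}

chord_over_arc <- function(x, y) {
  arc <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (arc <= 0) return(NA_real_)
  sqrt((x[length(x)] - x[1L])^2 + (y[length(y)] - y[1L])^2) / arc
}

#' Path curvature (straightness index) of a walking bout
#'
#' For bouts of at least `min_steps` (default 4) steps, curvature is the
#' equal-weight mean of two chord/arc ratios: the overall ratio (straight-line
#' distance between the bout's first and last step divided by the total
#' distance traveled) and the mean step-to-step ratio over every consecutive
#' triple of steps (chord from step i to step i+2 divided by the two-step
#' arc through step i+1). The index lies in (0, 1]; 1 means perfectly
#' straight, values near 0 a maximally tortuous path.
#'
#' @param steps A per-bout step table (e.g. from the `steps` list column of
#'   [segment_bouts()]), or a two-column matrix/data frame of `x`, `y`
#'   positions in step order.
#' @param min_steps Minimum bout length in steps for curvature to be defined
#'   (default 4).
#' @return A single number in (0, 1], or `NA` with a `"reason"` attribute
#'   when undefined (too few steps, or all steps coincident).
#' @examples
#' bout_curvature(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
#' @export
bout_curvature <- function(steps, min_steps = 4) {
  xy <- extract_xy(steps)
  n <- nrow(xy)
  if (n < min_steps) {
    return(structure(NA_real_, reason = "fewer steps than min_steps"))
  }
  overall <- chord_over_arc(xy[, 1L], xy[, 2L])
  if (is.na(overall)) {
    return(structure(NA_real_, reason = "zero total distance"))
  }
  x <- xy[, 1L]; y <- xy[, 2L]
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  i <- seq_len(n - 2L)
  arc <- seg[i] + seg[i + 1L]
  chord <- sqrt((x[i + 2L] - x[i])^2 + (y[i + 2L] - y[i])^2)
  triples <- (chord / arc)[arc > 0]  # coincident triples dropped
  if (length(triples) == 0L) {
    return(structure(NA_real_, reason = "all step triples degenerate"))
  }
  (overall + mean(triples)) / 2
}

#' Heading changes between consecutive step displacements
#'
#' For the displacement vectors `v_i` between consecutive steps, returns the
#' plane angle between each pair `(v_i, v_{i+1})` in degrees: the turning
#' angle of the path at every interior step. Zero-length displacements
#' (repeated positions) contribute no angle; the number skipped is attached
#' as the `"n_skipped"` attribute.
#'
#' @inheritParams bout_curvature
#' @param signed If `FALSE` (default) absolute angles in `[0, 180]`; if
#'   `TRUE` signed angles in `(-180, 180]`, positive counter-clockwise.
#' @return Numeric vector of angles in degrees (length `n_steps - 2` minus
#'   skipped pairs; empty if fewer than 3 steps).
#' @examples
#' heading_changes(data.frame(x = c(0, 1, 1, 2), y = c(0, 0, 1, 1)))
#' @export
heading_changes <- function(steps, signed = FALSE) {
  xy <- extract_xy(steps)
  if (nrow(xy) < 3L) {
    return(structure(numeric(0), n_skipped = 0L))
  }
  vx <- diff(xy[, 1L]); vy <- diff(xy[, 2L])
  len <- sqrt(vx^2 + vy^2)
  keep <- len > 0
  vx <- vx[keep]; vy <- vy[keep]
  n_skipped <- 0L
  if (length(vx) < 2L) {
    return(structure(numeric(0), n_skipped = sum(!keep)))
  }
  i <- seq_len(length(vx) - 1L)
  ang <- atan2(vx[i] * vy[i + 1L] - vy[i] * vx[i + 1L],
               vx[i] * vx[i + 1L] + vy[i] * vy[i + 1L]) * 180 / pi
  # zero-length displacements collapse a pair; count pairs lost
  n_skipped <- (nrow(xy) - 2L) - length(ang)
  if (!signed) ang <- abs(ang)
  structure(ang, n_skipped = n_skipped)
}

extract_xy <- function(steps) {
  if (is.matrix(steps)) {
    stopifnot(ncol(steps) >= 2L)
    return(steps[, 1:2, drop = FALSE])
  }
  stopifnot(all(c("x", "y") %in% names(steps)))
  cbind(steps$x, steps$y)
}
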