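#' Recipe for building a walk-training course from sessions
#'
#' Bundles the tunable constants of course construction: the stop cap, the
#' per-walker block duration, the number of contributing walkers, the
#' room-to-field grid scale and the sampling seed. At the defaults
#' (15 walkers x 4-min blocks) the built course lasts exactly one hour.
#'
#' @param stop_cap Seconds; stationary periods are capped here (default 2).
#' @param block_duration Seconds sampled per walker (default 240).
#' @param total_sessions Number of contributing walkers (default 15).
#' @param seed Integer seed for the block sampling (default 1).
#' @param grid_cell Field meters per room meter (default 1).
#' @param nominal_walk_speed Meters/second recorded on the course (default
#'   0.4).
#' @return A list with class `course_recipe`.
#' @export
course_recipe <- function(stop_cap = 2, block_duration = 240,
                          total_sessions = 15, seed = 1, grid_cell = 1,
                          nominal_walk_speed = 0.4) {
  stopifnot(stop_cap > 0, block_duration > 0, total_sessions >= 1)
  structure(list(stop_cap = stop_cap, block_duration = block_duration,
                 total_sessions = total_sessions, seed = seed,
                 grid_cell = grid_cell,
                 nominal_walk_speed = nominal_walk_speed),
            class = "course_recipe")
}

#' Build a training course from walkers' recorded paths
#'
#' Replays each session as a capped walk/stop timeline
#' ([session_to_timeline()]), samples one random block of
#' `recipe$block_duration` seconds per walker ([sample_block()]) and
#' concatenates the blocks in the given session order. Where a block
#' boundary would put two stop elements back to back, they are merged and
#' capped at `recipe$stop_cap`, and the trimmed stop time is replaced by
#' extending that block within its own timeline — so the course duration is
#' exactly `total_sessions * block_duration` (3600 s at the defaults), no
#' stop exceeds the cap, and no two stops are adjacent.
#'
#' @param sessions A list of exactly `recipe$total_sessions`
#'   [walk_session()] objects (or a tibble with a `session` list column).
#' @param recipe A [course_recipe()].
#' @param course_id Identifier for the built course.
#' @return A [walk_course()].
#' @export
build_infant_course <- function(sessions, recipe = course_recipe(),
                                course_id = "infant-course") {
  if (is.data.frame(sessions) && "session" %in% names(sessions)) {
    sessions <- sessions$session
  }
  if (length(sessions) != recipe$total_sessions) {
    abort(paste0("need exactly ", recipe$total_sessions,
                 " sessions (got ", length(sessions), ")"),
          class = "varietywalk_validation_error")
  }
  set.seed(recipe$seed)
  bd <- recipe$block_duration
  acc <- NULL
  for (s in sessions) {
    tl <- session_to_timeline(s, stop_cap = recipe$stop_cap,
                              grid_cell = recipe$grid_cell)
    total <- sum(tl$duration)
    if (total <= 0) {
      abort(paste0("session '", session_id(s), "' has an empty timeline"),
            class = "varietywalk_validation_error")
    }
    pos <- if (total >= bd) runif(1, 0, total - bd) else runif(1, 0, total)
    needed <- bd
    while (needed > 1e-9) {
      rows <- timeline_window(tl, pos, needed)
      pos <- pos + needed
      deficit <- 0
      if (!is.null(acc) && nrow(acc) > 0L && nrow(rows) > 0L &&
          acc$mode[nrow(acc)] == "stop" && rows$mode[1L] == "stop") {
        combined <- acc$duration[nrow(acc)] + rows$duration[1L]
        merged <- min(combined, recipe$stop_cap)
        deficit <- combined - merged
        acc$duration[nrow(acc)] <- merged
        rows <- rows[-1L, , drop = FALSE]
      }
      acc <- if (is.null(acc)) rows else dplyr::bind_rows(acc, rows)
      needed <- deficit
    }
  }
  walk_course(acc, course_id = course_id, stop_cap = recipe$stop_cap,
              nominal_walk_speed = recipe$nominal_walk_speed)
}

#' Geometric baseline training courses
#'
#' Low-variety reference regimens for walk training:
#'
#' * `line_course()`: walk continually forward for `n_segments` segments of
#'   `walk_duration` seconds each, standing still `stop_duration` seconds
#'   after each (defaults 10 x (7 s walk + 2 s stop); constant heading).
#' * `circle_course()`: follow a fixed circle, the target heading updated
#'   every `waypoint_interval` second for `n_waypoints` updates (one full
#'   revolution), then stop; the pattern repeats `n_repeats` times
#'   (defaults 7 x (20 x 1 s + 2 s stop), 154 s total).
#' * `square_course()`: alternate two lap styles around a fixed square —
#'   once around then a single stop, and once around stopping at every
#'   corner — repeating the pair `n_repeats` times. Each side takes
#'   `side_duration` seconds (default 5 s, so 20 s of walking per lap); the
#'   square's size follows from the nominal walk speed.
#'
#' Spatial sizes derive from `nominal_walk_speed * duration`; the circle
#' radius is set directly (default 1.5 m).
#'
#' @param n_segments,walk_duration,stop_duration Line-course structure.
#' @param nominal_walk_speed Meters/second used to size the shapes
#'   (default 0.4).
#' @param radius Circle radius in meters (default 1.5).
#' @param n_waypoints,waypoint_interval Heading updates per revolution and
#'   their spacing in seconds.
#' @param n_repeats Repetitions (circle laps / square lap pairs).
#' @param side_duration Seconds of walking per square side (default 5).
#' @param center Field coordinates of the shape center, `c(x, y)`.
#' @return A [walk_course()].
#' @examples
#' course_duration(line_course())   # 90 s
#' course_duration(circle_course()) # 154 s
#' @export
line_course <- function(n_segments = 10, walk_duration = 7,
                        stop_duration = 2, nominal_walk_speed = 0.4) {
  seg <- nominal_walk_speed * walk_duration
  x0 <- -n_segments * seg / 2
  rows <- purrr::map_dfr(seq_len(n_segments), function(i) {
    tibble(mode = c("walk", "stop"),
           x = c(x0 + i * seg, NA_real_), y = c(0, NA_real_),
           duration = c(walk_duration, stop_duration))
  })
  walk_course(rows, course_id = "line",
              nominal_walk_speed = nominal_walk_speed,
              stop_cap = stop_duration)
}

#' @rdname line_course
#' @export
circle_course <- function(radius = 1.5, n_waypoints = 20,
                          waypoint_interval = 1, stop_duration = 2,
                          n_repeats = 7, center = c(0, 0),
                          nominal_walk_speed = 0.4) {
  theta <- 2 * pi * seq_len(n_waypoints) / n_waypoints
  rev_rows <- tibble(mode = "walk",
                     x = center[1L] + radius * cos(theta),
                     y = center[2L] + radius * sin(theta),
                     duration = waypoint_interval)
  stop_row <- tibble(mode = "stop", x = NA_real_, y = NA_real_,
                     duration = stop_duration)
  rows <- purrr::map_dfr(seq_len(n_repeats),
                         function(i) dplyr::bind_rows(rev_rows, stop_row))
  walk_course(rows, course_id = "circle",
              nominal_walk_speed = nominal_walk_speed,
              stop_cap = stop_duration)
}

#' @rdname line_course
#' @export
square_course <- function(side_duration = 5, stop_duration = 2,
                          n_repeats = 7, center = c(0, 0),
                          nominal_walk_speed = 0.4) {
  half <- nominal_walk_speed * side_duration / 2
  corners <- tibble(x = center[1L] + c(half, -half, -half, half),
                    y = center[2L] + c(half, half, -half, -half))
  # lap order: start at corner 1, visit 2, 3, 4, back to 1 (closed)
  lap <- corners[c(2, 3, 4, 1), ]
  stop_row <- tibble(mode = "stop", x = NA_real_, y = NA_real_,
                     duration = stop_duration)
  end_stop_lap <- dplyr::bind_rows(
    tibble(mode = "walk", x = lap$x, y = lap$y, duration = side_duration),
    stop_row)
  corner_stop_lap <- purrr::map_dfr(seq_len(4), function(i) {
    dplyr::bind_rows(tibble(mode = "walk", x = lap$x[i], y = lap$y[i],
                            duration = side_duration), stop_row)
  })
  rows <- purrr::map_dfr(seq_len(n_repeats), function(i) {
    dplyr::bind_rows(end_stop_lap, corner_stop_lap)
  })
  walk_course(rows, course_id = "square",
              nominal_walk_speed = nominal_walk_speed,
              stop_cap = stop_duration)
}
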