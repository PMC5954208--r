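#' Construct a free-play walking session
#'
#' A session holds the timestamped 2D foot placements of one walker during a
#' free-play observation in a rectangular playroom. The step table is the raw
#' input for bout segmentation ([segment_bouts()]) and the variety metrics
#' ([variety_profile()]).
#'
#' Coordinates are in the room frame: origin at one corner,
#' `x` in `[0, room_width]`, `y` in `[0, room_length]`, meters. Time is in
#' seconds from session start; timestamps must be strictly increasing (two
#' feet never land at the identical digitized instant).
#'
#' @param steps Data frame with numeric columns `t`, `x`, `y` and optionally a
#'   character `foot` column (`"left"`, `"right"` or `"unknown"`).
#' @param session_id Identifier for the walker/session.
#' @param room_width,room_length Playroom dimensions in meters (default
#'   6 x 9 m).
#' @param duration Scheduled session duration in seconds (default 1200 s,
#'   i.e. 20 min).
#' @param age_months,walk_experience_months Optional walker covariates.
#' @param on_out_of_room Policy for steps digitized outside the room:
#'   `"error"` (default) rejects the session, `"clamp"` moves offending
#'   points to the nearest wall.
#' @return A tibble of steps (`t`, `x`, `y`[, `foot`]) with class
#'   `walk_session` and the session metadata stored as attributes.
#' @examples
#' s <- walk_session(data.frame(t = c(0, .3, .6), x = c(1, 1.2, 1.4), y = 2))
#' s
#' @export
walk_session <- function(steps, session_id = "session", room_width = 6,
                         room_length = 9, duration = 1200,
                         age_months = NA_real_,
                         walk_experience_months = NA_real_,
                         on_out_of_room = c("error", "clamp")) {
  on_out_of_room <- match.arg(on_out_of_room)
  steps <- as_tibble(steps)
  required <- c("t", "x", "y")
  missing_cols <- setdiff(required, names(steps))
  if (length(missing_cols) > 0L) {
    abort(paste0("step table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "varietywalk_format_error")
  }
  keep <- intersect(c("t", "x", "y", "foot"), names(steps))
  steps <- steps[keep]
  for (col in required) {
    if (!is.numeric(steps[[col]])) {
      abort(paste0("column '", col, "' must be numeric"),
            class = "varietywalk_format_error")
    }
  }
  if (nrow(steps) > 0L) {
    if (anyNA(steps$t) || any(!is.finite(steps$t)) || any(steps$t < 0)) {
      abort("timestamps must be finite and >= 0",
            class = "varietywalk_validation_error")
    }
    if (any(!is.finite(steps$x)) || any(!is.finite(steps$y))) {
      abort("step coordinates must be finite",
            class = "varietywalk_validation_error")
    }
    bad <- which(diff(steps$t) <= 0) + 1L
    if (length(bad) > 0L) {
      abort(paste0("timestamps must be strictly increasing; offending row(s): ",
                   paste(bad, collapse = ", ")),
            class = "varietywalk_validation_error")
    }
    out <- steps$x < 0 | steps$x > room_width |
      steps$y < 0 | steps$y > room_length
    if (any(out)) {
      if (on_out_of_room == "error") {
        abort(paste0("step(s) outside the ", room_width, " x ", room_length,
                     " m room at row(s): ",
                     paste(which(out), collapse = ", "),
                     " (use on_out_of_room = \"clamp\" for noisy digitizations)"),
              class = "varietywalk_validation_error")
      }
      steps$x <- pmin(pmax(steps$x, 0), room_width)
      steps$y <- pmin(pmax(steps$y, 0), room_length)
    }
  }
  if ("foot" %in% names(steps)) {
    steps$foot <- as.character(steps$foot)
    ok <- steps$foot %in% c("left", "right", "unknown")
    if (!all(ok)) {
      abort("foot must be one of 'left', 'right', 'unknown'",
            class = "varietywalk_validation_error")
    }
  }
  structure(steps,
            class = c("walk_session", class(steps)),
            session_id = as.character(session_id),
            room_width = room_width, room_length = room_length,
            duration = duration, age_months = age_months,
            walk_experience_months = walk_experience_months)
}

#' @export
print.walk_session <- function(x, ...) {
  cat(sprintf("<walk_session '%s'>  %d steps, %g x %g m room, %g s\n",
              session_id(x), nrow(x), attr(x, "room_width"),
              attr(x, "room_length"), attr(x, "duration")))
  NextMethod()
}

#' Session metadata accessors
#'
#' @param session A `walk_session`.
#' @return `session_id()` the identifier; `room_dims()` a named numeric vector
#'   `c(width, length)` in meters.
#' @export
session_id <- function(session) attr(session, "session_id")

#' @rdname session_id
#' @export
room_dims <- function(session) {
  c(width = attr(session, "room_width"),
    length = attr(session, "room_length"))
}

#' Read a step-event session from a CSV table
#'
#' The canonical dialect is comma-separated with columns `t,x,y` (seconds,
#' meters, meters) and an optional `foot` column. Rows must already be sorted
#' by time; non-monotone timestamps are a validation error naming the
#' offending rows.
#'
#' @param path File to read.
#' @param session_id Identifier; defaults to the file name without extension.
#' @inheritParams walk_session
#' @param ... Further arguments passed to [walk_session()].
#' @return A [walk_session()].
#' @export
read_session <- function(path, session_id = NULL,
                         on_out_of_room = c("error", "clamp"), ...) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "varietywalk_io_error")
  }
  if (is.null(session_id)) {
    session_id <- sub("\\.[^.]*$", "", basename(path))
  }
  # base read.csv parses doubles with strtod (exact to the last ulp), so
  # write_session(read_session(f)) reproduces a canonical file byte for byte
  steps <- utils::read.csv(path, stringsAsFactors = FALSE)
  walk_session(steps, session_id = session_id,
               on_out_of_room = match.arg(on_out_of_room), ...)
}

#' Write a session's step table to CSV
#'
#' Writes the canonical comma-separated dialect (`t,x,y[,foot]`). Writing is a
#' deterministic function of the step table, so
#' `write_session(read_session(f))` reproduces a canonically written file
#' byte for byte.
#'
#' @param session A `walk_session`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  readr::write_csv(as_tibble(unclass_session(session)), path, progress = FALSE)
  invisible(path)
}

unclass_session <- function(session) {
  out <- session
  class(out) <- setdiff(class(out), "walk_session")
  out
}
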