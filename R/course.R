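#' Construct a walk-training course
#'
#' A training course is an ordered schedule of elements handed to a walk
#' optimizer: `walk` elements carry a target waypoint in field coordinates
#' (origin at field center, meters) and the time allotted to reach it;
#' `stop` elements carry only a stand-in-place duration. Consecutive stop
#' elements are merged (durations summed) on construction.
#'
#' @param elements Data frame with columns `mode` (`"walk"`/`"stop"`), `x`,
#'   `y` (walk targets; `NA` for stops) and `duration` (seconds; stops must
#'   have `duration > 0`).
#' @param course_id Identifier.
#' @param nominal_walk_speed Meters/second used for the duration accounting of
#'   geometric courses (default 0.4 m/s, a steady humanoid walk).
#' @param stop_cap Maximum allowed stop duration in seconds (default 2 s);
#'   stops longer than this are rejected. Use `Inf` to disable.
#' @param field_half_x,field_half_y Half-extent of the field in meters
#'   (default 15 x 10, a 30 x 20 m pitch); walk targets must fall inside.
#' @return A tibble of elements with class `walk_course`; metadata in
#'   attributes.
#' @export
walk_course <- function(elements, course_id = "course",
                        nominal_walk_speed = 0.4, stop_cap = 2,
                        field_half_x = 15, field_half_y = 10) {
  elements <- as_tibble(elements)
  if (nrow(elements) == 0L) {
    elements <- tibble(mode = character(), x = double(), y = double(),
                       duration = double())
  }
  required <- c("mode", "x", "y", "duration")
  missing_cols <- setdiff(required, names(elements))
  if (length(missing_cols) > 0L) {
    abort(paste0("course elements missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "varietywalk_format_error")
  }
  elements <- elements[required]
  if (nrow(elements) > 0L) {
    if (!all(elements$mode %in% c("walk", "stop"))) {
      abort("element mode must be 'walk' or 'stop'",
            class = "varietywalk_validation_error")
    }
    elements <- merge_consecutive_stops(elements)
    is_stop <- elements$mode == "stop"
    if (any(is_stop & (!is.finite(elements$duration) | elements$duration <= 0))) {
      abort("stop durations must be positive and finite",
            class = "varietywalk_validation_error")
    }
    if (any(is_stop & elements$duration > stop_cap + 1e-9)) {
      abort(paste0("stop duration exceeds the ", stop_cap, " s cap"),
            class = "varietywalk_validation_error")
    }
    walk <- !is_stop
    if (any(walk & (!is.finite(elements$x) | !is.finite(elements$y)))) {
      abort("walk elements need finite target coordinates",
            class = "varietywalk_validation_error")
    }
    if (any(walk & (abs(elements$x) > field_half_x + 1e-9 |
                    abs(elements$y) > field_half_y + 1e-9))) {
      abort("walk targets must lie within the field bounds",
            class = "varietywalk_validation_error")
    }
    if (any(walk & (elements$duration < 0 | !is.finite(elements$duration)))) {
      abort("walk durations must be finite and >= 0",
            class = "varietywalk_validation_error")
    }
    elements$x[is_stop] <- NA_real_
    elements$y[is_stop] <- NA_real_
  }
  structure(elements,
            class = c("walk_course", class(elements)),
            course_id = as.character(course_id),
            nominal_walk_speed = nominal_walk_speed,
            stop_cap = stop_cap,
            field_half_x = field_half_x, field_half_y = field_half_y)
}

merge_consecutive_stops <- function(elements) {
  if (nrow(elements) < 2L) return(elements)
  is_stop <- elements$mode == "stop"
  run <- cumsum(c(TRUE, !(is_stop[-1L] & is_stop[-length(is_stop)])))
  if (max(run) == nrow(elements)) return(elements)
  dur <- as.vector(tapply(elements$duration, run, sum))
  keep <- elements[!duplicated(run), , drop = FALSE]
  keep$duration <- dur
  keep
}

#' @export
print.walk_course <- function(x, ...) {
  cat(sprintf("<walk_course '%s'>  %d elements (%d walk, %d stop), %.1f s\n",
              attr(x, "course_id"), nrow(x), sum(x$mode == "walk"),
              sum(x$mode == "stop"), course_duration(x)))
  NextMethod()
}

#' Total scheduled duration of a course
#'
#' @param course A `walk_course` (or timeline tibble with a `duration`
#'   column).
#' @return Duration in seconds.
#' @export
course_duration <- function(course) sum(course$duration)

#' Write a training course as a JSON schedule
#'
#' Schema version 1.0: a top-level object with `schema_version`, `course_id`,
#' `nominal_walk_speed`, `stop_cap`, `field_half_x`, `field_half_y` and an
#' `elements` array; each element has `mode`, `duration` and (walk only) a
#' two-element `target` array in field coordinates. Numbers are written at
#' full precision so `read_course(write_course(c))` reproduces `c` exactly.
#'
#' @param course A `walk_course`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_course <- function(course, path) {
  els <- purrr::pmap(course[c("mode", "x", "y", "duration")],
                     function(mode, x, y, duration) {
                       if (mode == "walk") {
                         list(mode = mode, target = c(x, y), duration = duration)
                       } else {
                         list(mode = mode, duration = duration)
                       }
                     })
  obj <- list(schema_version = "1.0",
              course_id = attr(course, "course_id"),
              nominal_walk_speed = attr(course, "nominal_walk_speed"),
              stop_cap = attr(course, "stop_cap"),
              field_half_x = attr(course, "field_half_x"),
              field_half_y = attr(course, "field_half_y"),
              elements = els)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON course schedule
#'
#' @param path File written by [write_course()].
#' @return A [walk_course()].
#' @export
read_course <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "varietywalk_io_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema_version)) {
    abort("not a course schedule: missing schema_version",
          class = "varietywalk_format_error")
  }
  els <- purrr::map_dfr(obj$elements, function(e) {
    tibble(mode = e$mode,
           x = if (e$mode == "walk") e$target[[1]] else NA_real_,
           y = if (e$mode == "walk") e$target[[2]] else NA_real_,
           duration = e$duration)
  })
  walk_course(els, course_id = obj$course_id,
              nominal_walk_speed = obj$nominal_walk_speed,
              stop_cap = obj$stop_cap,
              field_half_x = obj$field_half_x,
              field_half_y = obj$field_half_y)
}
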