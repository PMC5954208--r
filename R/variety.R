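#' Four-dimensional variety profile of a walking session
#'
#' Summarizes how *varied* — not how large — a walker's paths are, as the
#' dispersion (standard error) of three per-bout quantities plus the bout
#' count:
#'
#' * `shape_variety`: SE of path curvature over bouts with at least
#'   `min_curvature_steps` steps (see [bout_curvature()]).
#' * `direction_variety`: SE of the absolute heading change, pooled over
#'   every consecutive step pair of every bout (degrees; see
#'   [heading_changes()]).
#' * `length_variety`: SE of the number of steps per bout (all bouts).
#' * `n_bouts`: total number of bouts (starts and stops).
#'
#' Standard errors use the sample standard deviation (n - 1 denominator)
#' divided by the square root of the number of contributing units, and are
#' `NA` (undefined, never silently zero) with fewer than 2 contributing
#' units; the `n_*` columns expose those counts.
#'
#' @inheritParams segment_bouts
#' @param min_curvature_steps Minimum steps per bout for curvature
#'   eligibility (default 4).
#' @param pool_direction If `TRUE` (default) the heading-change SE is taken
#'   over the pooled step pairs of all bouts; if `FALSE`, over per-bout mean
#'   heading changes.
#' @return A one-row tibble: `session_id`, `n_steps`, `n_bouts`,
#'   `shape_variety`, `direction_variety`, `length_variety`,
#'   `n_curvature_bouts`, `n_heading_pairs`.
#' @export
variety_profile <- function(session, stationary_threshold = 0.5,
                            min_curvature_steps = 4,
                            pool_direction = TRUE) {
  bouts <- segment_bouts(session, stationary_threshold)
  id <- attr(session, "session_id") %||% "session"
  if (nrow(bouts) == 0L) {
    return(tibble(session_id = id, n_steps = 0L, n_bouts = 0L,
                  shape_variety = NA_real_, direction_variety = NA_real_,
                  length_variety = NA_real_, n_curvature_bouts = 0L,
                  n_heading_pairs = 0L))
  }
  curv <- purrr::map_dbl(bouts$steps, bout_curvature,
                         min_steps = min_curvature_steps)
  curv <- curv[!is.na(curv)]
  turns <- purrr::map(bouts$steps, heading_changes)
  pooled <- unlist(turns, use.names = FALSE)
  direction <- if (pool_direction) {
    se_mean(pooled)
  } else {
    se_mean(purrr::map_dbl(turns, function(a) {
      if (length(a) == 0L) NA_real_ else mean(a)
    }))
  }
  tibble(session_id = id,
         n_steps = sum(bouts$n_steps),
         n_bouts = nrow(bouts),
         shape_variety = se_mean(curv),
         direction_variety = direction,
         length_variety = se_mean(as.numeric(bouts$n_steps)),
         n_curvature_bouts = length(curv),
         n_heading_pairs = length(pooled))
}

#' Variety profiles for a list of sessions
#'
#' @param sessions A list of [walk_session()] objects (or a tibble with a
#'   `session` list column, as returned by [generate_cohort()]).
#' @param ... Passed to [variety_profile()].
#' @return A tibble with one row per session.
#' @export
variety_profiles <- function(sessions, ...) {
  if (is.data.frame(sessions) && "session" %in% names(sessions)) {
    sessions <- sessions$session
  }
  purrr::map_dfr(sessions, variety_profile, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
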