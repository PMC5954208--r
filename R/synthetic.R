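#' Parameters for the correlated-random-walk session generator
#'
#' The generator emulates the statistical structure of a free-play walking
#' session in a bounded playroom: a sequence of walking bouts (correlated
#' random walks) separated by stationary pauses. Per bout it draws a step
#' count and a persistent turning bias; per step, a heading change around
#' that bias and a step length; steps fall at a fixed cadence. At a wall
#' the heading is deflected by the smallest angle that keeps the step
#' inside the room (walkers graze walls; reversals only in corners), so
#' all steps stay in bounds without rejection sampling.
#'
#' How the knobs map onto the four variety dimensions (see
#' [variety_profile()]): `heading_sd` drives direction variety,
#' `curvature_drift_sd` spreads per-bout tortuosity and hence shape variety,
#' `steps_per_bout_dispersion` (negative-binomial size; smaller = more
#' dispersed) drives length variety, and `n_bouts` is the start/stop count
#' itself.
#'
#' @param n_bouts Number of walking bouts (exact).
#' @param steps_per_bout_mean Mean steps per bout (> 1); counts are drawn as
#'   `1 + NegBinomial(mu = mean - 1, size = dispersion)` so every bout has
#'   at least one step.
#' @param steps_per_bout_dispersion Negative-binomial `size`; large values
#'   approach Poisson-like spread, small values heavy overdispersion.
#' @param step_length_mean,step_length_sd Step length distribution, meters
#'   (normal, truncated at 2 cm).
#' @param heading_sd SD of the per-step heading change, degrees.
#' @param curvature_drift_sd SD across bouts of the per-bout mean turning
#'   bias, degrees per step.
#' @param pause_mean,pause_sd Inter-bout stationary periods, seconds
#'   (normal, truncated at 0.6 s so every pause ends a bout under the 0.5 s
#'   rule).
#' @param step_interval Seconds between steps within a bout (default 0.3 s,
#'   about 3 steps/s — a brisk toddler cadence safely below the 0.5 s
#'   stationary threshold).
#' @param room_width,room_length Room dimensions, meters (default 6 x 9).
#' @param wall_margin Meters of clearance kept from every wall when a step
#'   must be deflected (default 0.3).
#' @return A list with class `path_gen_params`.
#' @export
path_gen_params <- function(n_bouts = 60, steps_per_bout_mean = 8,
                            steps_per_bout_dispersion = 20,
                            step_length_mean = 0.25, step_length_sd = 0.05,
                            heading_sd = 30, curvature_drift_sd = 10,
                            pause_mean = 10, pause_sd = 4,
                            step_interval = 0.3,
                            room_width = 6, room_length = 9,
                            wall_margin = 0.3) {
  stopifnot(n_bouts >= 1, steps_per_bout_mean > 1,
            steps_per_bout_dispersion > 0, step_length_sd >= 0,
            heading_sd >= 0, curvature_drift_sd >= 0, pause_sd >= 0,
            step_interval > 0, step_interval < 0.5)
  if (step_length_mean <= 0 ||
      step_length_mean >= min(room_width, room_length)) {
    abort("step_length_mean must be positive and smaller than the room",
          class = "varietywalk_validation_error")
  }
  structure(as.list(environment()), class = "path_gen_params")
}

#' Generate a synthetic free-play walking session
#'
#' Draws one session from the correlated-random-walk model described in
#' [path_gen_params()]. Deterministic given `seed`; with `seed = NULL` the
#' current RNG stream is used (so cohorts can be generated reproducibly
#' from a single upstream seed).
#'
#' @param params A [path_gen_params()].
#' @param seed Optional integer seed.
#' @param session_id Identifier for the generated session.
#' @return A [walk_session()]; [segment_bouts()] at the default threshold
#'   recovers exactly `params$n_bouts` bouts.
#' @examples
#' s <- generate_session(path_gen_params(n_bouts = 5), seed = 1)
#' nrow(segment_bouts(s))
#' @export
generate_session <- function(params, seed = NULL, session_id = "synthetic") {
  stopifnot(inherits(params, "path_gen_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  n_steps <- 1L + rnbinom(p$n_bouts, mu = p$steps_per_bout_mean - 1,
                          size = p$steps_per_bout_dispersion)
  drift <- rnorm(p$n_bouts, 0, p$curvature_drift_sd)
  pauses <- pmax(0.6, rnorm(p$n_bouts, p$pause_mean, p$pause_sd))
  cx <- p$room_width / 2
  cy <- p$room_length / 2
  pos <- c(runif(1, 1, p$room_width - 1), runif(1, 1, p$room_length - 1))
  t_now <- 0
  out <- vector("list", p$n_bouts)
  for (b in seq_len(p$n_bouts)) {
    nb <- n_steps[b]
    xs <- numeric(nb); ys <- numeric(nb)
    xs[1L] <- pos[1L]; ys[1L] <- pos[2L]
    heading <- runif(1, 0, 360)
    if (nb > 1L) {
      lens <- pmax(0.02, rnorm(nb - 1L, p$step_length_mean, p$step_length_sd))
      turns <- rnorm(nb - 1L, drift[b], p$heading_sd)
      # fast path: plain correlated random walk, valid iff no step comes
      # within the wall margin (so wall steering would never have fired)
      rad <- (heading + cumsum(turns)) * pi / 180
      fx <- xs[1L] + cumsum(lens * cos(rad))
      fy <- ys[1L] + cumsum(lens * sin(rad))
      fx <- c(xs[1L], fx); fy <- c(ys[1L], fy)
      if (all(fx >= p$wall_margin) && all(fx <= p$room_width - p$wall_margin) &&
          all(fy >= p$wall_margin) && all(fy <= p$room_length - p$wall_margin)) {
        fx <- fx[-1L]; fy <- fy[-1L]
        xs[-1L] <- fx
        ys[-1L] <- fy
      } else {
        lo_x <- p$wall_margin; hi_x <- p$room_width - p$wall_margin
        lo_y <- p$wall_margin; hi_y <- p$room_length - p$wall_margin
        # candidate deflections, smallest magnitude first: 0, +5, -5, ...
        cand <- as.vector(rbind(seq(0, 180, by = 5), -seq(0, 180, by = 5)))[-2L]
        for (i in seq_len(nb - 1L)) {
          heading <- heading + turns[i]
          placed <- FALSE
          for (d in cand) {
            rad <- (heading + d) * pi / 180
            nx <- xs[i] + lens[i] * cos(rad)
            ny <- ys[i] + lens[i] * sin(rad)
            if (nx >= lo_x && nx <= hi_x && ny >= lo_y && ny <= hi_y) {
              # walkers graze walls: the smallest heading deflection that
              # keeps the step in the room (reversals only in corners)
              heading <- heading + d
              placed <- TRUE
              break
            }
          }
          if (!placed) { # step longer than the free space: head to center
            heading <- atan2(cy - ys[i], cx - xs[i]) * 180 / pi
            rad <- heading * pi / 180
            nx <- min(max(xs[i] + lens[i] * cos(rad), lo_x), hi_x)
            ny <- min(max(ys[i] + lens[i] * sin(rad), lo_y), hi_y)
          }
          xs[i + 1L] <- nx
          ys[i + 1L] <- ny
        }
      }
    }
    out[[b]] <- list(t = t_now + p$step_interval * (seq_len(nb) - 1L),
                     x = xs, y = ys)
    t_now <- t_now + p$step_interval * (nb - 1L) + pauses[b]
    pos <- c(xs[nb], ys[nb])
  }
  steps <- tibble(t = unlist(lapply(out, `[[`, "t")),
                  x = unlist(lapply(out, `[[`, "x")),
                  y = unlist(lapply(out, `[[`, "y")))
  walk_session(steps, session_id = session_id,
               room_width = p$room_width, room_length = p$room_length,
               duration = ceiling(max(steps$t)) + 1)
}

#' Qualitative variety presets
#'
#' Five generator parameterizations whose measured variety profiles
#' reproduce, qualitatively, the relative high/low feature combinations of
#' the five path-variety groups (named by the conventional team colors):
#' `green` high direction variety and many stops but low shape variety;
#' `yellow` high shape variety and many stops but low direction variety;
#' `blue` high shape and length variety with few stops; `red` high shape
#' and length variety, relatively few stops, low direction variety;
#' `purple` relatively high variety on all dimensions. Only the ordinal
#' pattern is meaningful — the numeric values are this package's design,
#' not estimates from any cohort.
#'
#' @return Named list of [path_gen_params()].
#' @export
variety_presets <- function() {
  list(
    green = path_gen_params(n_bouts = 80, steps_per_bout_mean = 7,
                            steps_per_bout_dispersion = 40,
                            heading_sd = 70, curvature_drift_sd = 2,
                            pause_mean = 8, pause_sd = 3),
    yellow = path_gen_params(n_bouts = 66, steps_per_bout_mean = 7,
                             steps_per_bout_dispersion = 40,
                             heading_sd = 8, curvature_drift_sd = 15,
                             pause_mean = 11, pause_sd = 4),
    blue = path_gen_params(n_bouts = 25, steps_per_bout_mean = 16,
                           steps_per_bout_dispersion = 1,
                           heading_sd = 20, curvature_drift_sd = 20,
                           pause_mean = 20, pause_sd = 6),
    red = path_gen_params(n_bouts = 38, steps_per_bout_mean = 12,
                          steps_per_bout_dispersion = 3,
                          heading_sd = 5, curvature_drift_sd = 14,
                          pause_mean = 13, pause_sd = 4),
    purple = path_gen_params(n_bouts = 50, steps_per_bout_mean = 12,
                             steps_per_bout_dispersion = 1.2,
                             heading_sd = 85, curvature_drift_sd = 25,
                             pause_mean = 10, pause_sd = 3))
}

#' Generate a labeled cohort of synthetic sessions
#'
#' Draws `n_per_group` sessions from each parameter set, with the group
#' label retained, for end-to-end pipeline and parameter-recovery tests.
#' Within a group, each session's bout count is jittered
#' (`Poisson(n_bouts)`, minimum 2) so the start/stop dimension carries
#' realistic walker-to-walker variation; set `jitter_n_bouts = FALSE` for
#' exact counts.
#'
#' @param params_per_group Named list of [path_gen_params()] (default
#'   [variety_presets()]).
#' @param n_per_group Sessions per group (default 15).
#' @param seed Integer seed for the whole cohort (default 1).
#' @param jitter_n_bouts Jitter per-session bout counts (default `TRUE`).
#' @return A tibble with columns `session_id`, `group` and a `session` list
#'   column; `nrow = length(params_per_group) * n_per_group`.
#' @export
generate_cohort <- function(params_per_group = variety_presets(),
                            n_per_group = 15, seed = 1,
                            jitter_n_bouts = TRUE) {
  stopifnot(length(params_per_group) >= 1, n_per_group >= 1)
  groups <- names(params_per_group) %||% as.character(seq_along(params_per_group))
  set.seed(seed)
  purrr::map2_dfr(params_per_group, groups, function(p, g) {
    purrr::map_dfr(seq_len(n_per_group), function(i) {
      pi <- p
      if (jitter_n_bouts) pi$n_bouts <- max(2L, rpois(1L, p$n_bouts))
      id <- paste0(g, "-", sprintf("%02d", i))
      tibble(session_id = id, group = g,
             session = list(generate_session(pi, session_id = id)))
    })
  })
}
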