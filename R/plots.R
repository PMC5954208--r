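#' Plot a walking session's path
#'
#' Draws the step-by-step path through the playroom, one line per walking
#' bout, with the room walls framed.
#'
#' @param object A [walk_session()].
#' @param stationary_threshold Passed to [segment_bouts()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.walk_session <- function(object, stationary_threshold = 0.5, ...) {
  bouts <- segment_bouts(object, stationary_threshold)
  dims <- room_dims(object)
  pts <- tidyr::unnest(bouts[c("bout", "steps")], "steps")
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y, group = .data$bout)) +
    ggplot2::geom_path(alpha = 0.6, colour = "steelblue") +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::annotate("rect", xmin = 0, xmax = dims[["width"]],
                      ymin = 0, ymax = dims[["length"]],
                      fill = NA, colour = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("Session ", session_id(object)),
                  subtitle = sprintf("%d bouts, %d steps",
                                     nrow(bouts), sum(bouts$n_steps)),
                  x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot a training course
#'
#' Walk targets are joined in schedule order; stops are marked at the
#' preceding waypoint.
#'
#' @param object A [walk_course()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.walk_course <- function(object, ...) {
  df <- as_tibble(object)
  df$order <- seq_len(nrow(df))
  walks <- df[df$mode == "walk", ]
  prev <- prev_positions(df)
  stops <- df[df$mode == "stop", ]
  stops$x <- prev[df$mode == "stop", 1L]
  stops$y <- prev[df$mode == "stop", 2L]
  p <- ggplot2::ggplot(walks, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("Course ", attr(object, "course_id")),
                  subtitle = sprintf("%.0f s scheduled", course_duration(object)),
                  x = "field x (m)", y = "field y (m)") +
    ggplot2::theme_minimal()
  if (nrow(stops) > 0L && any(is.finite(stops$x))) {
    p <- p + ggplot2::geom_point(data = stops[is.finite(stops$x), ],
                                 shape = 4, colour = "black", size = 2)
  }
  p
}

#' Plot a league table
#'
#' League points per team, ordered by rank.
#'
#' @param object A `league_table` from [build_league()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.league_table <- function(object, ...) {
  df <- as_tibble(object)
  df$team <- factor(df$team, levels = rev(df$team))
  ggplot2::ggplot(df, ggplot2::aes(.data$points, .data$team)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "League points", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heat map of pairwise wins
#'
#' Rows are teams, columns opponents, fill the number of wins (ties
#' excluded).
#'
#' @param matrices Output of [pairwise_matrices()].
#' @return A ggplot.
#' @export
plot_win_matrix <- function(matrices) {
  w <- matrices$wins
  df <- tibble(team = rep(rownames(w), times = ncol(w)),
               opponent = rep(colnames(w), each = nrow(w)),
               wins = as.vector(w))
  df <- df[df$team != df$opponent, ]
  df$team <- factor(df$team, levels = rev(rownames(w)))
  df$opponent <- factor(df$opponent, levels = colnames(w))
  ggplot2::ggplot(df, ggplot2::aes(.data$opponent, .data$team,
                                   fill = .data$wins)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue4") +
    ggplot2::labs(x = "Opponent", y = NULL, fill = "Wins") +
    ggplot2::theme_minimal()
}
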