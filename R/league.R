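#' League points from a win/tie record
#'
#' The standard soccer league scoring rule: 3 points per win, 1 per tie,
#' 0 per loss.
#'
#' @param wins,ties Non-negative counts (vectorized).
#' @return Integer vector of league points.
#' @examples
#' league_points(2888, 1037)  # 9701
#' @export
league_points <- function(wins, ties) {
  if (any(wins < 0) || any(ties < 0) ||
      any(wins != round(wins)) || any(ties != round(ties))) {
    abort("wins and ties must be non-negative integer counts",
          class = "varietywalk_validation_error")
  }
  as.integer(3 * wins + ties)
}

ledger_long <- function(ledger) {
  ledger <- as_tibble(ledger)
  dplyr::bind_rows(
    tibble(team = ledger$team_a, opponent = ledger$team_b,
           scored = ledger$goals_a, conceded = ledger$goals_b),
    tibble(team = ledger$team_b, opponent = ledger$team_a,
           scored = ledger$goals_b, conceded = ledger$goals_a))
}

#' Aggregate a match ledger into a league table
#'
#' One row per team with wins/losses/ties from goal comparisons, league
#' points (3/1/0), per-game goals scored and conceded as mean with standard
#' error, and the average goal difference (mean over the team's games of
#' goals scored minus conceded — the magnitude measure of success, where
#' points measure consistency). Teams are sorted by points, ties broken by
#' average goal difference then name.
#'
#' @param ledger A [match_ledger()] (or data frame with its columns).
#' @return A tibble with class `league_table`: columns `team`, `points`,
#'   `wins`, `losses`, `ties`, `games`, `goals_scored_mean`,
#'   `goals_scored_se`, `goals_conceded_mean`, `goals_conceded_se`,
#'   `avg_goal_difference`.
#' @export
build_league <- function(ledger) {
  ledger <- match_ledger(ledger)
  if (nrow(ledger) == 0L) {
    abort("ledger is empty", class = "varietywalk_validation_error")
  }
  out <- ledger_long(ledger) |>
    dplyr::group_by(team = .data$team) |>
    dplyr::summarise(
      wins = sum(.data$scored > .data$conceded),
      losses = sum(.data$scored < .data$conceded),
      ties = sum(.data$scored == .data$conceded),
      games = dplyr::n(),
      goals_scored_mean = mean(.data$scored),
      goals_scored_se = se_mean(.data$scored),
      goals_conceded_mean = mean(.data$conceded),
      goals_conceded_se = se_mean(.data$conceded),
      avg_goal_difference = mean(.data$scored - .data$conceded),
      .groups = "drop") |>
    dplyr::mutate(points = league_points(.data$wins, .data$ties)) |>
    dplyr::arrange(dplyr::desc(.data$points),
                   dplyr::desc(.data$avg_goal_difference), .data$team) |>
    dplyr::relocate("team", "points", "wins", "losses", "ties", "games")
  structure(out, class = c("league_table", class(out)))
}

#' Pairwise win and goal matrices
#'
#' `wins[i, j]` counts the games team i beat team j (ties excluded, so the
#' matrix need not be symmetric); `goals[i, j]` is the mean goals team i
#' scored against j (`NA` when the pair never met); `games[i, j]` counts
#' their meetings and `ties[i, j]` their ties. For every pair,
#' `wins[i, j] + wins[j, i] + ties[i, j] == games[i, j]`, and
#' goals-for/goals-against are antisymmetric by construction.
#'
#' @inheritParams build_league
#' @param teams Optional character vector fixing row/column order (default:
#'   league-table order).
#' @return A list of matrices `wins`, `goals`, `games`, `ties` with teams on
#'   rows (as scorers) and opponents on columns.
#' @export
pairwise_matrices <- function(ledger, teams = NULL) {
  ledger <- match_ledger(ledger)
  long <- ledger_long(ledger)
  if (is.null(teams)) teams <- build_league(ledger)$team
  m0 <- matrix(0, length(teams), length(teams),
               dimnames = list(teams, teams))
  wins <- games <- ties <- m0
  goal_sum <- m0
  for (r in seq_len(nrow(long))) {
    i <- long$team[r]; j <- long$opponent[r]
    games[i, j] <- games[i, j] + 1
    wins[i, j] <- wins[i, j] + (long$scored[r] > long$conceded[r])
    ties[i, j] <- ties[i, j] + (long$scored[r] == long$conceded[r])
    goal_sum[i, j] <- goal_sum[i, j] + long$scored[r]
  }
  goals <- ifelse(games > 0, goal_sum / games, NA_real_)
  diag(goals) <- NA_real_
  list(wins = wins, goals = goals, games = games, ties = ties)
}

#' One-way ANOVA on per-game goal differences, with pairwise comparisons
#'
#' Tests whether teams differ in average goal difference: a one-way ANOVA
#' over per-game goal differences (goals scored minus conceded) grouped by
#' team, followed by all pairwise two-sample t tests (pooled variance by
#' default, Welch optional) with Bonferroni correction. Each pair is
#' reported with the higher-scoring team first so mean differences are
#' positive.
#'
#' @inheritParams build_league
#' @param var_equal Pooled-variance t tests if `TRUE` (default), Welch
#'   otherwise.
#' @return An object of class `goal_diff_anova`: list with `statistic` (F),
#'   `df` (c(between, within)), `p_value`, `group_means`, `pairwise` (tibble
#'   with `team_a`, `team_b`, `mean_diff`, `se`, `statistic`, `df`,
#'   `p_value`, `p_adj`), `degenerate` (no within-group variance anywhere).
#'   [tidy()] returns the pairwise table, [glance()] the omnibus row.
#' @export
goal_difference_anova <- function(ledger, var_equal = TRUE) {
  ledger <- match_ledger(ledger)
  long <- ledger_long(ledger)
  long$gd <- long$scored - long$conceded
  counts <- table(long$team)
  if (length(counts) < 2L || any(counts < 2L)) {
    abort("need at least 2 teams with at least 2 games each",
          class = "varietywalk_validation_error")
  }
  long$team <- factor(long$team)
  fit <- aov(gd ~ team, data = long)
  a <- anova(fit)
  degenerate <- a["Residuals", "Sum Sq"] < 1e-12
  group_means <- long |>
    dplyr::group_by(team = as.character(.data$team)) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$gd),
                     se = se_mean(.data$gd), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean))
  pairs <- utils::combn(group_means$team, 2L)
  m <- ncol(pairs)
  pairwise <- purrr::map_dfr(seq_len(m), function(p) {
    ta <- pairs[1L, p]; tb <- pairs[2L, p]  # ta has the larger mean
    xa <- long$gd[long$team == ta]
    xb <- long$gd[long$team == tb]
    tt <- tryCatch(t.test(xa, xb, var.equal = var_equal),
                   error = function(e) NULL) # constant data: undefined test
    tibble(team_a = ta, team_b = tb,
           mean_diff = mean(xa) - mean(xb),
           se = if (is.null(tt)) NA_real_ else unname(tt$stderr),
           statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
           df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
           p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  pairwise$p_adj <- pmin(1, pairwise$p_value * m)
  structure(list(statistic = unname(a["team", "F value"]),
                 df = c(a["team", "Df"], a["Residuals", "Df"]),
                 p_value = unname(a["team", "Pr(>F)"]),
                 group_means = group_means,
                 pairwise = pairwise,
                 degenerate = degenerate,
                 n = nrow(long)),
            class = "goal_diff_anova")
}

#' @export
print.goal_diff_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA on per-game goal difference: F(%d, %d) = %.2f, p %s\n",
              x$df[1L], x$df[2L], x$statistic,
              format.pval(x$p_value, eps = 1e-3)))
  if (x$degenerate) cat("  (degenerate: no within-group variance)\n")
  cat(sprintf("  %d pairwise comparisons (Bonferroni adjusted)\n",
              nrow(x$pairwise)))
  invisible(x)
}

#' @rdname goal_difference_anova
#' @param x A `goal_diff_anova` object.
#' @param ... Unused.
#' @export
tidy.goal_diff_anova <- function(x, ...) x$pairwise

#' @rdname goal_difference_anova
#' @export
glance.goal_diff_anova <- function(x, ...) {
  tibble(statistic = x$statistic, df_between = x$df[1L],
         df_within = x$df[2L], p_value = x$p_value, n = x$n,
         degenerate = x$degenerate)
}
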