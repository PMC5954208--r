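#' Bundled tournament scoring records
#'
#' Published scoring tables from two round-robin tournaments of simulated
#' robot soccer in which every pair of teams played 1,000 head-to-head
#' matches: tournament 1 compares a team trained on free-play walking paths
#' against geometric baselines (5 teams, 4,000 games each), tournament 2
#' compares teams trained on five path-variety clusters plus a line
#' baseline (6 teams, 5,000 games each). One row per team: league points,
#' wins/losses/ties, and per-game goals scored/conceded as mean and
#' standard error. These records serve as reference inputs for the league
#' arithmetic in [league_points()] and as consistency fixtures.
#'
#' @param tournament 1 or 2.
#' @return A tibble with columns `team`, `league_points`, `wins`, `losses`,
#'   `ties`, `goals_scored_mean`, `goals_scored_se`, `goals_conceded_mean`,
#'   `goals_conceded_se`.
#' @examples
#' tab <- tournament_scoring(1)
#' all(league_points(tab$wins, tab$ties) == tab$league_points)
#' @export
tournament_scoring <- function(tournament = 1) {
  stopifnot(tournament %in% c(1, 2))
  path <- system.file("extdata",
                      paste0("tournament", tournament, "_scoring.csv"),
                      package = "varietywalk", mustWork = TRUE)
  readr::read_csv(path, col_types = "ciiiidddd", progress = FALSE)
}
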