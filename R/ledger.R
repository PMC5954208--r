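#' Construct a match ledger
#'
#' A ledger records one row per head-to-head game: the two team names and
#' the goals each scored. Ledgers feed [build_league()],
#' [pairwise_matrices()] and [goal_difference_anova()].
#'
#' @param matches Data frame with columns `team_a`, `team_b` (character,
#'   distinct within a row) and `goals_a`, `goals_b` (non-negative
#'   integers).
#' @return A tibble with class `match_ledger`.
#' @examples
#' match_ledger(data.frame(team_a = "infants", team_b = "lines",
#'                         goals_a = 2, goals_b = 0))
#' @export
match_ledger <- function(matches) {
  matches <- as_tibble(matches)
  required <- c("team_a", "team_b", "goals_a", "goals_b")
  missing_cols <- setdiff(required, names(matches))
  if (length(missing_cols) > 0L) {
    abort(paste0("ledger missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "varietywalk_format_error")
  }
  matches <- matches[required]
  matches$team_a <- as.character(matches$team_a)
  matches$team_b <- as.character(matches$team_b)
  if (any(matches$team_a == matches$team_b)) {
    abort(paste0("self-match (team_a == team_b) at row(s): ",
                 paste(which(matches$team_a == matches$team_b),
                       collapse = ", ")),
          class = "varietywalk_validation_error")
  }
  for (col in c("goals_a", "goals_b")) {
    g <- matches[[col]]
    if (!is.numeric(g) || anyNA(g) || any(g < 0) || any(g != round(g))) {
      abort(paste0("column '", col,
                   "' must contain non-negative integer goal counts"),
            class = "varietywalk_validation_error")
    }
    matches[[col]] <- as.integer(round(g))
  }
  structure(matches, class = c("match_ledger", class(matches)))
}

#' Read a match ledger from CSV
#'
#' Canonical dialect: comma-separated, columns
#' `team_a,team_b,goals_a,goals_b`.
#'
#' @param path File to read.
#' @return A [match_ledger()].
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "varietywalk_io_error")
  }
  match_ledger(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a match ledger to CSV
#'
#' @param ledger A [match_ledger()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  out <- as_tibble(ledger)
  class(out) <- setdiff(class(out), "match_ledger")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
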