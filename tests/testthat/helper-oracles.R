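# Independent re-implementations used as oracles. These deliberately take
# different computational routes from the package code.

make_session <- function(t, x, y, ...) {
  walk_session(data.frame(t = t, x = x, y = y), ...)
}

# a plausible random session: bouts at 0.2-0.4 s cadence, pauses >= 0.6 s
random_session <- function(seed, n_bouts = 8, room_width = 6, room_length = 9) {
  set.seed(seed)
  t <- c(); x <- c(); y <- c()
  now <- 0
  px <- runif(1, 1, room_width - 1); py <- runif(1, 1, room_length - 1)
  for (b in seq_len(n_bouts)) {
    n <- sample(1:12, 1)
    gaps <- runif(n - 1, 0.2, 0.45)
    t <- c(t, now + cumsum(c(0, gaps)))
    xb <- pmin(pmax(px + cumsum(c(0, runif(n - 1, -0.3, 0.3))), 0.05),
               room_width - 0.05)
    yb <- pmin(pmax(py + cumsum(c(0, runif(n - 1, -0.3, 0.3))), 0.05),
               room_length - 0.05)
    x <- c(x, xb); y <- c(y, yb)
    now <- max(t) + runif(1, 0.6, 6)
    px <- xb[n]; py <- yb[n]
  }
  make_session(t, x, y, session_id = paste0("rand", seed),
               room_width = room_width, room_length = room_length)
}

# linear-scan bout labels
oracle_bout_labels <- function(t, threshold = 0.5) {
  ids <- integer(length(t))
  cur <- 0L
  for (i in seq_along(t)) {
    if (i == 1L || t[i] - t[i - 1L] >= threshold) cur <- cur + 1L
    ids[i] <- cur
  }
  ids
}

# curvature recomputed with explicit loops over points
oracle_curvature <- function(x, y) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  dist2 <- function(i, j) sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2)
  total <- 0
  for (i in 1:(n - 1)) total <- total + dist2(i, i + 1)
  if (total == 0) return(NA_real_)
  overall <- dist2(1, n) / total
  ratios <- c()
  for (i in 1:(n - 2)) {
    arc <- dist2(i, i + 1) + dist2(i + 1, i + 2)
    if (arc > 0) ratios <- c(ratios, dist2(i, i + 2) / arc)
  }
  (overall + mean(ratios)) / 2
}

# heading changes via absolute angles + wrapped differences (the package
# uses the cross/dot atan2 form instead)
oracle_heading_changes <- function(x, y) {
  dx <- diff(x); dy <- diff(y)
  keep <- dx != 0 | dy != 0
  dx <- dx[keep]; dy <- dy[keep]
  if (length(dx) < 2) return(numeric(0))
  ang <- atan2(dy, dx) * 180 / pi
  delta <- diff(ang)
  abs(((delta + 180) %% 360) - 180)
}

# spreadsheet-style variety profile
oracle_profile <- function(session, threshold = 0.5) {
  t <- session$t
  ids <- oracle_bout_labels(t, threshold)
  curvs <- c(); turns <- c(); lens <- c()
  for (b in unique(ids)) {
    xb <- session$x[ids == b]; yb <- session$y[ids == b]
    lens <- c(lens, length(xb))
    cv <- oracle_curvature(xb, yb)
    if (!is.na(cv)) curvs <- c(curvs, cv)
    turns <- c(turns, oracle_heading_changes(xb, yb))
  }
  se <- function(v) if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
  list(n_bouts = length(unique(ids)), shape = se(curvs),
       direction = se(turns), length = se(lens))
}

# exhaustive minimum within-cluster sum of squares over all balanced
# 2-partitions
oracle_balanced_wss <- function(X) {
  n <- nrow(X)
  half <- n / 2
  combs <- utils::combn(n, half)
  best <- Inf
  for (j in seq_len(ncol(combs))) {
    A <- combs[, j]
    B <- setdiff(seq_len(n), A)
    wss <- sum(scale(X[A, , drop = FALSE], scale = FALSE)^2) +
      sum(scale(X[B, , drop = FALSE], scale = FALSE)^2)
    if (wss < best) best <- wss
  }
  best
}

# brute-force league recount straight from the match rows
oracle_league_row <- function(ledger, team) {
  rows_a <- ledger[ledger$team_a == team, ]
  rows_b <- ledger[ledger$team_b == team, ]
  scored <- c(rows_a$goals_a, rows_b$goals_b)
  conceded <- c(rows_a$goals_b, rows_b$goals_a)
  list(wins = sum(scored > conceded), losses = sum(scored < conceded),
       ties = sum(scored == conceded),
       points = 3 * sum(scored > conceded) + sum(scored == conceded),
       gd = mean(scored - conceded))
}

random_ledger <- function(seed, teams = c("a", "b", "c", "d"),
                          games_per_pair = 6, lambda = 1.5) {
  set.seed(seed)
  pairs <- utils::combn(teams, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
    data.frame(team_a = pairs[1, p], team_b = pairs[2, p],
               goals_a = rpois(games_per_pair, lambda),
               goals_b = rpois(games_per_pair, lambda))
  }))
  match_ledger(out)
}
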