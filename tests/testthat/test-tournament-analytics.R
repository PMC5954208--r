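test_that("league points follow the 3/1/0 rule", {
  expect_equal(league_points(2888, 1037), 9701L)
  expect_equal(league_points(3420, 1526), 11786L)
  expect_equal(league_points(0, 0), 0L)
  expect_equal(league_points(c(1, 2), c(0, 3)), c(3L, 9L))
  expect_error(league_points(-1, 0), class = "varietywalk_validation_error")
  expect_error(league_points(1.5, 0), class = "varietywalk_validation_error")
})

test_that("league tables aggregate single matches and ties correctly", {
  lt <- build_league(data.frame(team_a = "A", team_b = "B",
                                goals_a = 2, goals_b = 1))
  expect_equal(lt$points, c(3L, 0L))
  expect_equal(lt$team, c("A", "B"))
  expect_equal(lt$avg_goal_difference, c(1, -1))

  ties <- build_league(data.frame(team_a = c("A", "A", "B"),
                                  team_b = c("B", "C", "C"),
                                  goals_a = 1, goals_b = 1))
  expect_true(all(ties$points == ties$games))
  expect_true(all(ties$ties == ties$games))
})

test_that("league tables match a brute-force recount and conservation laws", {
  for (seed in 1:5) {
    led <- random_ledger(seed)
    lt <- build_league(led)
    expect_equal(sum(lt$wins), sum(lt$losses))
    expect_equal(sum(lt$ties) %% 2, 0)
    expect_true(all(lt$wins + lt$losses + lt$ties == lt$games))
    for (tm in lt$team) {
      want <- oracle_league_row(led, tm)
      row <- lt[lt$team == tm, ]
      expect_equal(row$wins, want$wins)
      expect_equal(row$losses, want$losses)
      expect_equal(row$ties, want$ties)
      expect_equal(row$points, want$points)
      expect_equal(row$avg_goal_difference, want$gd)
    }
    # permutation invariance in ledger order
    perm <- led[sample(nrow(led)), ]
    expect_equal(as.data.frame(build_league(perm)), as.data.frame(lt))
  }
})

test_that("pairwise matrices satisfy conservation and antisymmetry", {
  led <- random_ledger(7, teams = c("a", "b", "c", "d", "e"))
  pm <- pairwise_matrices(led)
  teams <- rownames(pm$wins)
  for (i in teams) {
    for (j in teams) {
      if (i == j) next
      expect_equal(pm$wins[i, j] + pm$wins[j, i] + pm$ties[i, j],
                   pm$games[i, j])
      expect_equal(pm$ties[i, j], pm$ties[j, i])
    }
  }
  # mean goals scored by i against j = mean goals conceded by j against i,
  # recomputed directly from the match rows
  long_ij <- led[led$team_a == "a" & led$team_b == "b", ]
  expect_equal(pm$goals["a", "b"], mean(long_ij$goals_a))
  expect_equal(pm$goals["b", "a"], mean(long_ij$goals_b))

  # unplayed pairs: zero wins, undefined mean goals
  led2 <- match_ledger(data.frame(team_a = c("a", "c"), team_b = c("b", "d"),
                                  goals_a = 1, goals_b = 0))
  pm2 <- pairwise_matrices(led2)
  expect_equal(pm2$wins["a", "c"], 0)
  expect_true(is.na(pm2$goals["a", "c"]))
})

test_that("the goal-difference ANOVA matches closed-form hand computation", {
  # textbook-style 3-group toy data, one game per row against a dummy side
  g <- list(A = c(2, 3, 4, 3), B = c(0, 1, 1, 2), C = c(-1, 0, 1, 0))
  led <- match_ledger(data.frame(
    team_a = rep(names(g), each = 4),
    team_b = "zzz-opponent",
    goals_a = unlist(g) + 3,
    goals_b = 3))
  fit <- goal_difference_anova(led)
  # hand-computed one-way ANOVA over the three trained teams + opponent group
  vals <- c(unlist(g), -(unlist(g)))
  grp <- c(rep(names(g), each = 4), rep("zzz-opponent", 12))
  grand <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(vals, grp, function(v) sum((v - mean(v))^2)))
  df1 <- 3; df2 <- length(vals) - 4
  f_hand <- (ssb / df1) / (ssw / df2)
  expect_equal(fit$statistic, f_hand, tolerance = 1e-10)
  expect_equal(fit$df, c(df1, df2))
  expect_equal(fit$p_value, stats::pf(f_hand, df1, df2, lower.tail = FALSE),
               tolerance = 1e-12)

  # Bonferroni: adjusted p = min(1, raw * m)
  m <- nrow(fit$pairwise)
  expect_equal(fit$pairwise$p_adj,
               pmin(1, fit$pairwise$p_value * m))
  # pairs are ordered so mean differences are non-negative
  expect_true(all(fit$pairwise$mean_diff >= 0))
  # pooled two-sample t reproduced for one pair
  tt <- t.test(g$A, g$B, var.equal = TRUE)
  row <- fit$pairwise[fit$pairwise$team_a == "A" & fit$pairwise$team_b == "B", ]
  expect_equal(row$statistic, unname(tt$statistic), tolerance = 1e-10)
})

test_that("identical groups give a null ANOVA and degeneracy is flagged", {
  # symmetric results: every team's goal differences have the same mean
  led <- match_ledger(data.frame(team_a = "A", team_b = "B",
                                 goals_a = c(1, 0, 2, 0),
                                 goals_b = c(0, 1, 0, 2)))
  fit <- goal_difference_anova(led)
  expect_equal(fit$statistic, 0, tolerance = 1e-12)
  expect_equal(fit$p_value, 1, tolerance = 1e-12)

  degen <- match_ledger(data.frame(team_a = rep(c("A", "B"), each = 2),
                                   team_b = "C",
                                   goals_a = 2, goals_b = 0))
  # aov warns about the perfect fit; the flag is what matters here
  expect_true(suppressWarnings(goal_difference_anova(degen))$degenerate)
  expect_error(goal_difference_anova(data.frame(team_a = "A", team_b = "B",
                                                goals_a = 1, goals_b = 0)),
               class = "varietywalk_validation_error")
})

test_that("the bundled tournament records are internally consistent", {
  t1 <- tournament_scoring(1)
  t2 <- tournament_scoring(2)
  expect_equal(nrow(t1), 5L)
  expect_equal(nrow(t2), 6L)
  expect_equal(league_points(t1$wins, t1$ties), t1$league_points)
  expect_equal(league_points(t2$wins, t2$ties), t2$league_points)
  expect_true(all(t1$wins + t1$losses + t1$ties == 4000L))
  expect_true(all(t2$wins + t2$losses + t2$ties == 5000L))
})
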