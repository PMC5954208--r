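test_that("bout segmentation follows the 500 ms stationary rule", {
  s1 <- make_session(t = c(0, 0.4, 0.8), x = c(1, 1.2, 1.4), y = 2)
  b1 <- segment_bouts(s1)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$n_steps, 3L)

  s2 <- make_session(t = c(0, 0.4, 1.0, 1.4), x = c(1, 1.2, 1.4, 1.6), y = 2)
  b2 <- segment_bouts(s2)
  expect_equal(nrow(b2), 2L)
  expect_equal(b2$n_steps, c(2L, 2L))
  expect_equal(b2$onset, c(0, 1.0))
  expect_equal(b2$offset, c(0.4, 1.4))

  expect_equal(nrow(segment_bouts(walk_session(data.frame(t = double(),
                                                          x = double(),
                                                          y = double())))),
               0L)
})

test_that("segmentation matches a brute-force linear scan and partitions steps", {
  for (seed in 1:8) {
    s <- random_session(seed)
    b <- segment_bouts(s)
    expect_equal(rep(b$bout, b$n_steps), oracle_bout_labels(s$t))
    expect_equal(sum(b$n_steps), nrow(s))
    expect_true(all(b$path_length >= b$displacement - 1e-12))
  }
})

test_that("inserting a stationary gap adds exactly one bout", {
  s <- random_session(3)
  before <- nrow(segment_bouts(s))
  i <- which(diff(s$t) < 0.5)[1] # split point inside a bout
  shifted <- s$t + ifelse(seq_along(s$t) > i, 5, 0)
  s2 <- make_session(shifted, s$x, s$y)
  expect_equal(nrow(segment_bouts(s2)), before + 1L)
})

test_that("curvature matches the worked example and the loop oracle", {
  sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(as.numeric(bout_curvature(sq)), (1 / 3 + sqrt(2) / 2) / 2,
               tolerance = 1e-12)
  expect_equal(as.numeric(bout_curvature(sq)), oracle_curvature(sq$x, sq$y),
               tolerance = 1e-12)

  # collinear, equally spaced: exactly 1
  lin <- data.frame(x = c(0, 1, 2, 3), y = 0)
  expect_identical(as.numeric(bout_curvature(lin)), 1)

  # short and degenerate bouts are undefined, with a reason
  short <- bout_curvature(data.frame(x = c(0, 1, 2), y = 0))
  expect_true(is.na(short))
  expect_match(attr(short, "reason"), "fewer steps")
  still <- bout_curvature(data.frame(x = rep(1, 5), y = rep(2, 5)))
  expect_true(is.na(still))
  expect_match(attr(still, "reason"), "zero total distance")

  # random bouts: bounded in (0, 1], oracle-equal
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:15, 1)
    x <- cumsum(runif(n, -1, 1)); y <- cumsum(runif(n, -1, 1))
    cv <- as.numeric(bout_curvature(data.frame(x = x, y = y)))
    expect_gt(cv, 0)
    expect_lte(cv, 1 + 1e-12)
    expect_equal(cv, oracle_curvature(x, y), tolerance = 1e-12)
  }
})

test_that("heading changes match plane geometry", {
  expect_equal(as.numeric(heading_changes(data.frame(x = 0:3, y = 0))),
               c(0, 0))
  zig <- data.frame(x = c(0, 1, 1, 2), y = c(0, 0, 1, 1))
  expect_equal(as.numeric(heading_changes(zig)), c(90, 90))
  expect_equal(as.numeric(heading_changes(zig, signed = TRUE)), c(90, -90))
  rev <- data.frame(x = c(0, 1, 0), y = 0)
  expect_equal(as.numeric(heading_changes(rev)), 180)
  # repeated positions are skipped and counted
  rep2 <- heading_changes(data.frame(x = c(0, 1, 1, 2), y = c(0, 0, 0, 0)))
  expect_equal(as.numeric(rep2), 0)
  expect_equal(attr(rep2, "n_skipped"), 1L)
  expect_length(heading_changes(data.frame(x = c(0, 1), y = 0)), 0)
})

test_that("variety metrics are invariant to rigid motions", {
  set.seed(42)
  n <- 12
  x <- cumsum(runif(n, -0.5, 1)); y <- cumsum(runif(n, -0.5, 1))
  th <- 0.7; dx <- 2.2; dy <- -1.3
  xr <- cos(th) * x - sin(th) * y + dx
  yr <- sin(th) * x + cos(th) * y + dy
  expect_equal(as.numeric(bout_curvature(data.frame(x = x, y = y))),
               as.numeric(bout_curvature(data.frame(x = xr, y = yr))),
               tolerance = 1e-9)
  expect_equal(as.numeric(heading_changes(data.frame(x = x, y = y))),
               as.numeric(heading_changes(data.frame(x = xr, y = yr))),
               tolerance = 1e-9)
})

test_that("variety profiles flag degenerate dispersions instead of zeroing them", {
  # identical straight bouts: no dispersion anywhere
  t <- c(0, 0.3, 0.6, 0.9, 2, 2.3, 2.6, 2.9)
  x <- c(1, 1.3, 1.6, 1.9, 1, 1.3, 1.6, 1.9)
  y <- c(2, 2, 2, 2, 3, 3, 3, 3)
  p <- variety_profile(make_session(t, x, y))
  expect_equal(p$n_bouts, 2L)
  expect_equal(p$shape_variety, 0)
  expect_equal(p$direction_variety, 0)
  expect_equal(p$length_variety, 0)

  # a single bout leaves length variety undefined
  p1 <- variety_profile(make_session(c(0, 0.3, 0.6, 0.9), x[1:4], y[1:4]))
  expect_equal(p1$n_bouts, 1L)
  expect_true(is.na(p1$length_variety))
  expect_true(is.na(p1$shape_variety))  # one eligible bout only

  # empty session
  p0 <- variety_profile(walk_session(data.frame(t = double(), x = double(),
                                                y = double())))
  expect_equal(p0$n_bouts, 0L)
  expect_true(is.na(p0$direction_variety))
})

test_that("variety profiles equal an independent spreadsheet-style recomputation", {
  for (seed in 1:6) {
    s <- random_session(seed, n_bouts = 10)
    got <- variety_profile(s)
    want <- oracle_profile(s)
    expect_equal(got$n_bouts, want$n_bouts)
    expect_equal(got$shape_variety, want$shape, tolerance = 1e-9)
    expect_equal(got$direction_variety, want$direction, tolerance = 1e-9)
    expect_equal(got$length_variety, want$length, tolerance = 1e-9)
  }
})
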