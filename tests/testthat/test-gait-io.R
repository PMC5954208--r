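test_that("a well-formed step table round-trips through walk_session", {
  s <- make_session(t = c(0, 0.3, 0.6), x = c(1, 1.2, 1.4), y = c(2, 2.1, 2.2))
  expect_s3_class(s, "walk_session")
  expect_equal(nrow(s), 3L)
  expect_equal(s$t, c(0, 0.3, 0.6))
  expect_equal(session_id(s), "session")
  expect_equal(unname(room_dims(s)), c(6, 9))
})

test_that("session validation rejects exactly the invariant violations", {
  # non-monotone timestamps, naming the offending row
  expect_error(make_session(t = c(0, 0.5, 0.4), x = 1:3, y = 1),
               "row\\(s\\): 3", class = "varietywalk_validation_error")
  expect_error(make_session(t = c(0, 0, 0.4), x = 1:3, y = 1),
               class = "varietywalk_validation_error")
  # missing columns are a format error
  expect_error(walk_session(data.frame(t = 1, x = 1)),
               "missing column", class = "varietywalk_format_error")
  # out-of-room points: error by default, clamp on request
  expect_error(make_session(t = c(0, 0.3), x = c(1, 7), y = 1),
               "outside", class = "varietywalk_validation_error")
  clamped <- make_session(t = c(0, 0.3), x = c(1, 7), y = 1,
                          on_out_of_room = "clamp")
  expect_equal(clamped$x[2], 6)
  # negative time, non-finite coordinate
  expect_error(make_session(t = c(-1, 0), x = 1, y = 1),
               class = "varietywalk_validation_error")
  expect_error(make_session(t = c(0, 0.3), x = c(1, Inf), y = 1),
               class = "varietywalk_validation_error")
  expect_error(walk_session(data.frame(t = 0, x = 1, y = 1, foot = "l")),
               class = "varietywalk_validation_error")
})

test_that("session CSV write/read is a byte-identical round trip", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  s <- random_session(11)
  write_session(s, f1)
  write_session(read_session(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_session(f1)
  expect_equal(back$t, s$t)
  expect_equal(back$x, s$x)
  expect_equal(back$y, s$y)
  # id defaults to the file name
  expect_equal(session_id(back), sub("\\.csv$", "", basename(f1)))
})

test_that("course schedules round-trip through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  c1 <- walk_course(data.frame(mode = c("walk", "stop", "walk"),
                               x = c(1.25, NA, -0.5),
                               y = c(0.75, NA, 2),
                               duration = c(3.3, 2.0, 1.7)),
                    course_id = "demo")
  write_course(c1, f)
  c2 <- read_course(f)
  expect_equal(as.data.frame(c2), as.data.frame(c1))
  expect_equal(attr(c2, "course_id"), "demo")
  expect_equal(attr(c2, "nominal_walk_speed"), attr(c1, "nominal_walk_speed"))
  # the capped 2.0 s stop survives exactly
  expect_identical(c2$duration[2], 2)
})

test_that("an empty course serializes to a schedule with zero elements", {
  f <- withr::local_tempfile(fileext = ".json")
  write_course(walk_course(data.frame()), f)
  obj <- jsonlite::read_json(f)
  expect_equal(obj$schema_version, "1.0")
  expect_length(obj$elements, 0)
  expect_equal(nrow(read_course(f)), 0L)
})

test_that("course construction merges consecutive stops and checks bounds", {
  m <- walk_course(data.frame(mode = c("walk", "stop", "stop"),
                              x = c(1, NA, NA), y = c(1, NA, NA),
                              duration = c(1, 0.5, 0.8)))
  expect_equal(nrow(m), 2L)
  expect_equal(m$duration[2], 1.3)
  expect_error(walk_course(data.frame(mode = "stop", x = NA, y = NA,
                                      duration = 3)),
               "cap", class = "varietywalk_validation_error")
  expect_error(walk_course(data.frame(mode = "walk", x = 99, y = 0,
                                      duration = 1)),
               "bounds", class = "varietywalk_validation_error")
  expect_error(walk_course(data.frame(mode = "stop", x = NA, y = NA,
                                      duration = 0)),
               class = "varietywalk_validation_error")
})

test_that("ledgers parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  led <- match_ledger(data.frame(team_a = c("A", "B"), team_b = c("B", "C"),
                                 goals_a = c(1, 0), goals_b = c(0, 0)))
  expect_equal(nrow(led), 2L)
  write_ledger(led, f)
  expect_equal(as.data.frame(read_ledger(f)), as.data.frame(led))
  expect_error(match_ledger(data.frame(team_a = "A", team_b = "A",
                                       goals_a = 1, goals_b = 0)),
               "self-match", class = "varietywalk_validation_error")
  expect_error(match_ledger(data.frame(team_a = "A", team_b = "B",
                                       goals_a = -1, goals_b = 0)),
               class = "varietywalk_validation_error")
  expect_error(match_ledger(data.frame(team_a = "A", team_b = "B",
                                       goals_a = 1.5, goals_b = 0)),
               class = "varietywalk_validation_error")
})

test_that("a 1,000-game generated ledger parses to 1,000 records", {
  f <- withr::local_tempfile(fileext = ".csv")
  set.seed(5)
  big <- match_ledger(data.frame(team_a = "infants", team_b = "lines",
                                 goals_a = rpois(1000, 2),
                                 goals_b = rpois(1000, 0.2)))
  write_ledger(big, f)
  expect_equal(nrow(read_ledger(f)), 1000L)
})

test_that("random valid sessions survive validation round trips", {
  for (seed in 1:5) {
    f <- withr::local_tempfile(fileext = ".csv")
    s <- random_session(seed)
    write_session(s, f)
    back <- read_session(f)
    expect_equal(back$t, s$t, tolerance = 1e-12)
    expect_equal(back$x, s$x, tolerance = 1e-12)
  }
})
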