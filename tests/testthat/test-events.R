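dig_tbl <- function(ivals, ...) {
  tibble::tibble(
    event_type = "digging",
    onset_s = vapply(ivals, `[`, numeric(1), 1),
    offset_s = vapply(ivals, `[`, numeric(1), 2),
    ...
  )
}

test_that("digging inclusion applies duration and baseline rules", {
  res <- select_digging_trials(dig_tbl(list(c(20, 25), c(30, 32), c(50, 56))))
  expect_equal(res$included, c(TRUE, FALSE, TRUE))
  expect_match(res$exclusion_reason[2], "duration")

  res2 <- select_digging_trials(dig_tbl(list(c(20, 25), c(33, 37))))
  expect_equal(res2$included, c(TRUE, FALSE))
  expect_match(res2$exclusion_reason[2], "baseline")

  empty <- select_digging_trials(dig_tbl(list()))
  expect_equal(nrow(empty), 0)

  expect_error(select_digging_trials(dig_tbl(list(c(10, 20), c(15, 25)))),
               "overlap")
})

test_that("turning inclusion applies angle, ITI and dig-overlap rules", {
  turns <- tibble::tibble(
    event_type = "turning",
    onset_s = c(10, 30, 50), offset_s = c(11, 31, 51),
    turn_angle = c(85, 120, 95)
  )
  res <- select_turning_trials(turns)
  expect_equal(res$included, c(FALSE, TRUE, TRUE))
  expect_match(res$exclusion_reason[1], "angle")

  close_turns <- tibble::tibble(
    event_type = "turning", onset_s = c(10, 12), offset_s = c(11, 13),
    turn_angle = c(120, 120)
  )
  res2 <- select_turning_trials(close_turns)
  expect_equal(res2$included, c(TRUE, FALSE))

  with_dig <- dplyr::bind_rows(
    tibble::tibble(event_type = "turning", onset_s = 20, offset_s = 21,
                   turn_angle = 120),
    tibble::tibble(event_type = "digging", onset_s = 18, offset_s = 24)
  )
  expect_false(select_turning_trials(with_dig)$included)

  no_angle <- tibble::tibble(event_type = "turning", onset_s = 1, offset_s = 2)
  expect_error(select_turning_trials(no_angle), "turn_angle")
})

test_that("lick bouts split at gaps >= 1 s (strict-below keeps the bout)", {
  b <- segment_lick_bouts(c(0.0, 0.3, 0.7, 2.0, 2.5))
  expect_equal(b$start, c(0.0, 2.0))
  expect_equal(b$end, c(0.7, 2.5))
  expect_equal(b$n_licks, c(3L, 2L))
  expect_equal(b$bout_length, c(0.7, 0.5))

  one <- segment_lick_bouts(5)
  expect_equal(one$bout_length, 0)
  expect_equal(one$n_licks, 1L)

  # exact 1.0 s gaps split
  b2 <- segment_lick_bouts(c(0, 1, 2))
  expect_equal(nrow(b2), 3)

  expect_error(segment_lick_bouts(c(2, 1)), "increasing")
})

test_that("lick initiation is the first lick strictly inside (cue, cue+3]", {
  r <- lick_initiation(c(10.4, 10.6), 10.0)
  expect_equal(r$initiation, 10.4)
  expect_true(r$rewarded)

  r2 <- lick_initiation(13.5, 10.0)
  expect_true(is.na(r2$initiation))
  expect_false(r2$rewarded)

  r3 <- lick_initiation(c(10.0, 10.5), 10.0)  # lick at the cue doesn't count
  expect_equal(r3$initiation, 10.5)
})

test_that("digging metrics: duration, per-minute frequency, success rate", {
  ev <- dig_tbl(list(c(10, 12), c(60, 63), c(120, 124), c(200, 205), c(300, 306)),
                retrieved_pellet = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  m <- digging_metrics(ev, window_start = 0, window_s = 600)
  expect_equal(m$mean_duration_s, 4)
  expect_equal(m$frequency_per_min, 0.5)
  expect_equal(m$success_rate, 0.4)

  m0 <- digging_metrics(dig_tbl(list()), 0, 600)
  expect_true(is.na(m0$mean_duration_s))
  expect_equal(m0$frequency_per_min, 0)
  expect_true(is.na(m0$success_rate))

  m1 <- digging_metrics(dig_tbl(list(c(5, 8)), retrieved_pellet = TRUE), 0, 600)
  expect_equal(unlist(m1[1, 1:3], use.names = FALSE), c(3, 0.1, 1))
})

test_that("bout segmentation equals the O(n^2) grouping oracle on random streams", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(1:200, 1)
    licks <- sort(cumsum(runif(n, 0.05, 1.6)))
    got <- segment_lick_bouts(licks)
    want <- oracle_bouts(licks)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_licks, want$n_licks)
    # idempotence: re-segmenting bout starts never merges separate bouts
    expect_equal(nrow(segment_lick_bouts(got$start)), nrow(got))
  }
})

test_that("inclusion filters match brute-force rules and ignore storage order", {
  set.seed(32)
  for (i in 1:60) {
    n <- sample(2:12, 1)
    gaps <- runif(n, 0.1, 15)
    durs <- runif(n, 0.5, 8)
    onsets <- cumsum(gaps + c(0, durs[-n]))  # sequential, never overlapping
    digs <- tibble::tibble(event_type = "digging", onset_s = onsets,
                           offset_s = onsets + durs)
    got <- select_digging_trials(digs)
    expect_equal(got$included, oracle_digging(digs))
    # storage order independence
    shuf <- digs[sample(n), ]
    expect_equal(select_digging_trials(shuf)$included, got$included)
    # exactly one primary reason per exclusion
    expect_true(all(!got$included == !is.na(got$exclusion_reason)))
  }
})

test_that("turning inclusion matches brute-force rules on random streams", {
  set.seed(33)
  for (i in 1:40) {
    nt <- sample(2:8, 1)
    t_on <- sort(runif(nt, 0, 200))
    turns <- tibble::tibble(event_type = "turning", onset_s = t_on,
                            offset_s = t_on + 1,
                            turn_angle = runif(nt, 40, 180))
    nd <- sample(0:4, 1)
    d_on <- sort(runif(max(nd, 1), 0, 200))[seq_len(nd)]
    digs <- tibble::tibble(event_type = "digging", onset_s = d_on,
                           offset_s = d_on + runif(nd, 1, 6))
    ev <- dplyr::bind_rows(turns, digs)
    got <- select_turning_trials(ev)
    expect_equal(got$included, oracle_turning(turns, digs))
  }
})
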