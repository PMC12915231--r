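fs <- 40

test_that("identical parameters and seed reproduce bit-identical sessions", {
  p <- sim_params(seed = 71)
  b1 <- simulate_session(p)
  b2 <- simulate_session(p)
  expect_identical(b1$session, b2$session)
  expect_identical(b1$events, b2$events)
  expect_identical(b1$motion_energy, b2$motion_energy)
  expect_identical(b1$truth, b2$truth)
  b3 <- simulate_session(sim_params(seed = 72))
  expect_false(identical(b1$session$region_a_raw, b3$session$region_a_raw))
})

test_that("generated events always satisfy the digging inclusion rules", {
  for (s in 73:77) {
    b <- simulate_session(sim_params(seed = s))
    sel <- select_digging_trials(b$events)
    expect_true(all(sel$included))
    expect_true(all(sel$offset_s - sel$onset_s >= 3))
  }
})

test_that("a session too short for the requested events names the constraint", {
  expect_error(simulate_session(sim_params(session_length = 60,
                                           n_events = c(digging = 10))),
               "session_length")
})

test_that("isosbestic channels carry artifacts but no calcium component", {
  p <- sim_params(noise_sd = 0, motion_artifact_sd = 0.02, seed = 78)
  b <- simulate_session(p)
  s <- b$session
  # signal minus isosbestic isolates baseline_F * calcium exactly
  ca <- (s$region_a_raw - s$isosbestic_a) / 100
  on <- b$truth$event_onsets[1]
  i_pre <- round((on - 8) * fs):round((on - 6) * fs)
  i_post <- round((on + 1) * fs):round((on + 2) * fs)
  expect_lt(max(abs(ca[i_pre])), 1e-9)   # clean pre-event baseline
  expect_gt(mean(ca[i_post]), 0.1)       # transient present after onset
})

test_that("noiseless identical-drive sessions give perfect trial correlation", {
  p <- sim_params(noise_sd = 0, shared_fraction = 1, inter_region_lag = 0,
                  bleach_amplitude = 0, motion_artifact_sd = 0, seed = 79)
  b <- simulate_session(p)
  digs <- dplyr::filter(select_digging_trials(b$events), included)
  for (on in digs$onset_s[1:4]) {
    a <- compute_dff(b$session$region_a_raw, fs, on, "digging")$dff
    bb <- compute_dff(b$session$region_b_raw, fs, on, "digging")$dff
    expect_equal(static_correlation(a, bb, fs, "digging"), 1.0, tolerance = 1e-9)
  }
})

test_that("a pure inter-region shift is recovered exactly downstream", {
  p <- sim_params(noise_sd = 0, shared_fraction = 1, inter_region_lag = 0.25,
                  bleach_amplitude = 0, motion_artifact_sd = 0, seed = 80)
  b <- simulate_session(p)
  digs <- dplyr::filter(select_digging_trials(b$events), included)
  for (on in digs$onset_s[1:4]) {
    a <- trim_trace(bandpass(compute_dff(b$session$region_a_raw, fs, on)$dff, fs), fs)
    bb <- trim_trace(bandpass(compute_dff(b$session$region_b_raw, fs, on)$dff, fs), fs)
    expect_equal(phase_lag(a, bb, fs), 0.25)
  }
  expect_equal(b$truth$true_lag, 0.25)
})

test_that("shared-fraction extremes drive trial correlation toward 1 and 0", {
  hi <- simulate_session(sim_params(shared_fraction = 1, noise_sd = 0.001,
                                    inter_region_lag = 0, seed = 81))
  expect_gt(hi$truth$true_correlation, 0.98)
  lo <- simulate_session(sim_params(shared_fraction = 0, seed = 82))
  expect_lt(abs(lo$truth$true_correlation), 0.35)

  r_of <- function(b) {
    digs <- dplyr::filter(select_digging_trials(b$events), included)
    mean(vapply(digs$onset_s, function(on) {
      a <- compute_dff(b$session$region_a_raw, fs, on)$dff
      bb <- compute_dff(b$session$region_b_raw, fs, on)$dff
      suppressWarnings(static_correlation(a, bb, fs, "digging"))
    }, numeric(1)), na.rm = TRUE)
  }
  expect_gt(r_of(hi), 0.95)
  expect_lt(abs(r_of(lo)), 0.5)
})

test_that("VAR realizations have least-squares-retrievable coefficients", {
  v <- simulate_var_pair(a_xy = 0.5, a_yx = 0, order = 1, n = 4000, seed = 83,
                         a_xx = 0.3, a_yy = 0.1)
  fit <- lm(v$y[-1] ~ v$x[-4000] + v$y[-4000])
  expect_lt(abs(unname(coef(fit)[2]) - 0.5), 0.05)
  expect_lt(abs(unname(coef(fit)[3]) - 0.1), 0.05)
  # determinism
  expect_identical(v, simulate_var_pair(0.5, 0, 1, 4000, seed = 83,
                                        a_xx = 0.3, a_yy = 0.1))
})

test_that("lick stream simulation respects cue structure and bout geometry", {
  cues <- c(10, 30, 50)
  expect_length(simulate_lick_stream(cues, response_prob = 0, seed = 84), 0)

  licks <- simulate_lick_stream(cues, response_prob = 1,
                                ili_distribution = 0.15, licks_per_cue = 5,
                                seed = 85)
  expect_length(licks, 15)
  expect_true(all(diff(licks) > 0))
  bouts <- segment_lick_bouts(licks)
  expect_equal(nrow(bouts), 3)  # one bout per cue at 1 s threshold
  expect_equal(bouts$n_licks, rep(5L, 3))

  sparse <- simulate_lick_stream(10, ili_distribution = 1.5, licks_per_cue = 4,
                                 seed = 86)
  expect_equal(nrow(segment_lick_bouts(sparse)), 4)  # every lick its own bout
})

test_that("coupled-trial generator hits the requested population correlation", {
  trials <- simulate_coupled_trials(0.6, n_trials = 80, seed = 87)
  rs <- purrr::map2_dbl(trials$dff_a, trials$dff_b,
                        ~ static_correlation(.x, .y, fs, "digging"))
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs) - 0.6), 3 * se + 0.02)
})
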