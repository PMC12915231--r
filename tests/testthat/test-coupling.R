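fs <- 40

test_that("static correlation: identity, sign flip, zero variance", {
  p <- random_trial_pair()
  expect_equal(static_correlation(p$a, p$a, fs, "digging"), 1.0)
  expect_equal(static_correlation(p$a, -p$a, fs, "digging"), -1.0)
  expect_warning(r <- static_correlation(p$a, rep(1, 400), fs, "digging"),
                 "zero-variance")
  expect_true(is.na(r))
})

test_that("static correlation is exactly invariant to positive affine rescaling", {
  p <- random_trial_pair()
  r0 <- static_correlation(p$a, p$b, fs, "digging")
  r1 <- static_correlation(2.5 * p$a + 0.3, p$b, fs, "digging")
  r2 <- static_correlation(p$a, 0.01 * p$b - 7, fs, "digging")
  expect_equal(r1, r0, tolerance = 1e-9)
  expect_equal(r2, r0, tolerance = 1e-9)
})

test_that("sliding window count is floor((T-4)/0.5)+1 and full window = static r", {
  for (T in c(4, 6, 10, 30)) {
    p <- random_trial_pair(n = T * fs)
    s <- sliding_correlation(p$a, p$b, fs)
    expect_equal(nrow(s), floor((T - 4) / 0.5) + 1)
  }
  # identical traces: every window r = 1
  p <- random_trial_pair(n = 10 * fs)
  s <- sliding_correlation(p$a, p$a, fs)
  expect_equal(s$r, rep(1, 13))
  # full-epoch window equals the plain Pearson r of the same traces
  s1 <- sliding_correlation(p$a, p$b, fs, window = 10)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$r, cor(p$a, p$b))
  # shorter than a window: empty with warning
  expect_warning(s0 <- sliding_correlation(rnorm(20), rnorm(20), fs), "shorter")
  expect_equal(nrow(s0), 0)
})

test_that("phase lag sign convention and pure-shift recovery", {
  p <- random_trial_pair(n = 600)
  k <- 10  # 0.25 s at 40 Hz
  # b delayed relative to a: b(t) = a(t - 0.25) -> A precedes B -> tau = -0.25
  a <- p$a[(k + 1):600]
  b_del <- p$a[1:(600 - k)]
  expect_equal(phase_lag(a, b_del, fs), -0.25)
  # b advanced: b(t) = a(t + 0.25) -> B precedes A -> tau = +0.25
  expect_equal(phase_lag(b_del, a, fs), +0.25)
  # identical traces: tau = 0
  expect_equal(phase_lag(p$a, p$a, fs), 0)
  # anti-correlated shifted pair still found via |c|
  expect_equal(phase_lag(a, -b_del, fs), -0.25)
})

test_that("phase lag matches the exhaustive-scan oracle on random trials", {
  set.seed(41)
  for (i in 1:100) {
    p <- random_trial_pair(n = 320)
    expect_identical(phase_lag(p$a, p$b, fs), oracle_phase_lag(p$a, p$b, fs))
  }
})

test_that("noiseless shifts of 1..80 samples are recovered exactly", {
  set.seed(42)
  base <- random_trial_pair(n = 1200)$a
  for (k in c(1, 2, 5, 10, 20, 40, 80)) {
    a <- base[(k + 1):1200]
    b <- base[1:(1200 - k)]
    expect_equal(phase_lag(a, b, fs), -k / fs)
  }
})

test_that("cross-correlogram: c(0) = static r, symmetry, bounded, null level", {
  p <- random_trial_pair(n = 400)
  cc <- cross_correlogram(p$a, p$b, fs)
  expect_equal(cc$r[cc$lag_s == 0], cor(p$a, p$b))
  expect_true(all(abs(cc$r) <= 1))
  # even signal: c(tau) = c(-tau)
  sym <- cos(2 * pi * 1 * ((0:399) - 199.5) / fs)
  cs <- cross_correlogram(sym, sym, fs, max_lag = 1)
  expect_equal(cs$r, rev(cs$r), tolerance = 1e-10)
  # white-noise pair at n = 10000: max |c| small
  set.seed(43)
  cw <- cross_correlogram(rnorm(10000), rnorm(10000), fs)
  expect_lt(max(abs(cw$r)), 0.05)
})

test_that("tie-breaking prefers smaller |lag|, then negative lag", {
  # period-4-sample integer pattern: |c| = 1 exactly at every even lag
  x <- rep(c(1, 0, -1, 0), 100)
  expect_equal(phase_lag(x, x, fs, max_lag = 0.1), 0)
  # quarter-period shift: |c| = 1 at odd lags; +-1 tie resolves to -1 sample
  y <- rep(c(0, 1, 0, -1), 100)
  expect_equal(phase_lag(x, y, fs, max_lag = 0.1), -1 / fs)
})

test_that("plateau and peak amplitudes use half-open windows after onset", {
  # constant 0.3 on the plateau interval
  d <- rep(0, 400); d[241:280] <- 0.3
  expect_equal(plateau_amplitude(d, fs), 0.3)
  # linear ramp 0 -> 1 over the [-5,5) window: mean over [1,2) = 0.65
  ramp <- seq(0, 1, length.out = 401)[1:400]
  expect_equal(plateau_amplitude(ramp, fs), mean(ramp[241:280]))
  # impulse of height 1 at t = 0.25 s: one sample out of 20 -> 0.05
  d2 <- rep(0, 400); d2[211] <- 1
  expect_equal(peak_amplitude(d2, fs), 1 / 20)
  expect_equal(peak_amplitude(rep(0, 400), fs), 0)
  expect_equal(peak_amplitude(rep(0.2, 400), fs), 0.2)
  expect_error(plateau_amplitude(rep(0, 100), fs), "interval")
})

test_that("synthetic plateau is recovered within noise tolerance", {
  b <- simulate_session(sim_params(noise_sd = 0.005, seed = 44))
  digs <- dplyr::filter(select_digging_trials(b$events), included)
  ca <- isosbestic_correct(b$session$region_a_raw, b$session$isosbestic_a, fs)
  plats <- vapply(digs$onset_s, function(on) {
    plateau_amplitude(compute_dff(ca, fs, on, "digging")$dff, fs)
  }, numeric(1))
  expect_equal(mean(plats), b$truth$true_plateau[["a"]], tolerance = 0.1)
})

test_that("sum-dFF bins, QC exclusion and partial-bin dropping", {
  # strictly increasing F: r = 1, retained
  x <- seq(100, 200, length.out = 16 * fs)
  s <- sum_dff(x, fs)
  expect_equal(s$n_bins, 2)
  expect_equal(s$n_excluded_bins, 0)
  expect_true(all(s$bins$retained))

  # constant bin: undefined r, excluded
  y <- c(seq(100, 120, length.out = 8 * fs), rep(110, 8 * fs))
  s2 <- sum_dff(y, fs)
  expect_equal(s2$n_excluded_bins, 1)
  expect_match(s2$bins$exclusion_reason[2], "zero variance")

  # partial final bin dropped
  s3 <- sum_dff(seq(100, 130, length.out = 20 * fs), fs)
  expect_equal(s3$n_bins, 2)

  # one bin corrupted by a sign-flipped artifact (negative values):
  # F0 < 0 there makes dF/F0 a negative-slope affine map, r = -1 -> excluded
  z <- 100 + as.numeric(signal::filtfilt(signal::butter(2, 0.05), rnorm(32 * fs)))
  z[(8 * fs + 1):(16 * fs)] <- -z[(8 * fs + 1):(16 * fs)]
  s4 <- sum_dff(z, fs)
  expect_equal(which(!s4$bins$retained), 2L)

  # sum equals the sum of retained bins' dF/F0 values
  manual <- sum(vapply(c(1, 3, 4), function(k) {
    f <- z[((k - 1) * 8 * fs + 1):(k * 8 * fs)]
    f0 <- as.numeric(quantile(f, 0.2))
    sum((f - f0) / f0)
  }, numeric(1)))
  expect_equal(s4$sum_dff, manual)
})
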