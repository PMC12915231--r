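# Coupling statistics between the two regional dF/F0 signals.

prep_pair <- function(dff_a, dff_b, fs, behavior) {
  a <- bandpass(dff_a, fs)
  b <- bandpass(dff_b, fs)
  if (behavior %in% c("digging", "licking")) {
    a <- trim_trace(a, fs)
    b <- trim_trace(b, fs)
  }
  list(a = a, b = b)
}

#' Static Pearson correlation between regional signals
#'
#' Bandpasses both dF/F0 traces (0.001-3 Hz), trims 1 s at each end for
#' digging and licking trials (never for turning), and returns the Pearson
#' correlation. A zero-variance trace makes r undefined: the trial is
#' reported as NA with a warning so callers can exclude it.
#'
#' @param dff_a,dff_b equal-length dF/F0 traces from one trial window.
#' @param fs sampling rate (Hz).
#' @param behavior behavior label driving the trim policy.
#' @return Pearson r, or NA when undefined.
#' @export
static_correlation <- function(dff_a, dff_b, fs, behavior = "digging") {
  assert_numeric_vector(dff_a, "dff_a")
  assert_numeric_vector(dff_b, "dff_b")
  if (length(dff_a) != length(dff_b)) abort("traces must have equal length")
  p <- prep_pair(dff_a, dff_b, fs, behavior)
  if (sd(p$a) < .Machine$double.eps || sd(p$b) < .Machine$double.eps) {
    warn("zero-variance trace: correlation undefined, trial should be excluded")
    return(NA_real_)
  }
  cor(p$a, p$b)
}

#' Sliding-window correlation
#'
#' Advances a window of `window` seconds in `step`-second increments across
#' the epoch and computes Pearson r within each complete window; incomplete
#' trailing windows are excluded, so the count is
#' `floor((T - window) / step) + 1`.
#'
#' @param dff_a,dff_b processed equal-length traces (bandpass/trim upstream).
#' @param fs sampling rate (Hz).
#' @param window,step window length and advance (s).
#' @return tibble with `window_center_s` and `r`; zero rows (with a warning)
#'   when the trace is shorter than one window.
#' @export
sliding_correlation <- function(dff_a, dff_b, fs, window = 4, step = 0.5) {
  assert_numeric_vector(dff_a, "dff_a")
  assert_numeric_vector(dff_b, "dff_b")
  if (length(dff_a) != length(dff_b)) abort("traces must have equal length")
  w <- round(window * fs)
  s <- round(step * fs)
  n <- length(dff_a)
  if (n < w) {
    warn("trace shorter than one window: empty sliding-correlation series")
    return(tibble(window_center_s = numeric(0), r = numeric(0)))
  }
  starts <- seq.int(1L, n - w + 1L, by = s)
  tibble(
    window_center_s = (starts - 1L + (w - 1) / 2) / fs,
    r = vapply(starts, function(i) {
      a <- dff_a[i:(i + w - 1L)]
      b <- dff_b[i:(i + w - 1L)]
      if (sd(a) < .Machine$double.eps || sd(b) < .Machine$double.eps) NA_real_ else cor(a, b)
    }, numeric(1))
  )
}

lagged_cor <- function(a, b, tau) {
  # Pearson r between a(t) and b(t - tau) over the overlapping samples
  n <- length(a)
  if (tau >= 0) {
    ai <- seq.int(1L + tau, n); bi <- seq.int(1L, n - tau)
  } else {
    ai <- seq.int(1L, n + tau); bi <- seq.int(1L - tau, n)
  }
  x <- a[ai]; y <- b[bi]
  if (sd(x) < .Machine$double.eps || sd(y) < .Machine$double.eps) return(NA_real_)
  cor(x, y)
}

#' Cross-correlogram of two traces
#'
#' Normalized cross-correlation over lags `-max_lag..max_lag`: at each lag the
#' Pearson r between `dff_a(t)` and `dff_b(t - tau)` is computed over the
#' overlapping samples, keeping every value in `[-1, 1]` regardless of trace
#' length. `c(0)` equals the static Pearson r of the supplied traces.
#'
#' @param dff_a,dff_b processed equal-length traces.
#' @param fs sampling rate (Hz).
#' @param max_lag maximum absolute lag (s); must be below half the duration.
#' @return tibble of class `xcorr_tbl` with `lag_s` and `r`.
#' @export
cross_correlogram <- function(dff_a, dff_b, fs, max_lag = 2) {
  assert_numeric_vector(dff_a, "dff_a")
  assert_numeric_vector(dff_b, "dff_b")
  if (length(dff_a) != length(dff_b)) abort("traces must have equal length")
  lmax <- round(max_lag * fs)
  if (lmax >= length(dff_a) / 2) abort("`max_lag` must be below half the trace duration")
  lags <- seq.int(-lmax, lmax)
  out <- tibble(
    lag_s = lags / fs,
    r = vapply(lags, function(tau) lagged_cor(dff_a, dff_b, tau), numeric(1))
  )
  class(out) <- c("xcorr_tbl", class(out))
  out
}

#' Phase lag between the two regional signals
#'
#' The signed lag at which the absolute cross-correlation is maximal — the
#' optimal temporal shift aligning the two signals. Sign convention: a
#' positive lag means region B (second trace) precedes region A by that many
#' seconds. Ties in |r| are broken toward smaller |lag|, then toward negative
#' lag. Lags where either overlapping segment has zero variance are skipped;
#' if every lag is degenerate the trial is excluded (NA with warning).
#'
#' @inheritParams cross_correlogram
#' @return lag in seconds, or NA when degenerate.
#' @export
phase_lag <- function(dff_a, dff_b, fs, max_lag = 2) {
  cc <- cross_correlogram(dff_a, dff_b, fs, max_lag)
  ok <- !is.na(cc$r)
  if (!any(ok)) {
    warn("cross-correlation undefined at every lag: trial excluded")
    return(NA_real_)
  }
  cc <- cc[ok, ]
  argmax_lag(cc$lag_s, cc$r)
}

# |r| argmax with documented tie-breaking: values within 1e-12 of the peak
# count as tied; prefer smaller |lag|, then negative lag
argmax_lag <- function(lag_s, r) {
  tied <- which(abs(r) >= max(abs(r)) - 1e-12)
  o <- order(abs(lag_s[tied]), lag_s[tied])
  lag_s[tied[o[1]]]
}

#' Binned sum-dFF activity with quality control
#'
#' Splits a raw free-moving / treadmill fluorescence trace into equal bins
#' (default 8 s; a trailing partial bin is dropped), normalizes each bin as
#' dF/F0 with F0 the 20th percentile of that bin, and excludes bins whose
#' Pearson correlation between the bin's dF/F0 and raw F falls below
#' `qc_threshold` or is undefined (zero variance, or non-positive F0). The
#' summary sums the retained bins' dF/F0 samples.
#'
#' @param raw_f raw fluorescence trace for the session.
#' @param fs sampling rate (Hz).
#' @param bin_s bin length (s).
#' @param qc_threshold minimum within-bin correlation to retain a bin.
#' @return list of class `activity_summary`: `sum_dff`, `n_bins`,
#'   `n_excluded_bins`, and a per-bin tibble `bins` (`bin`, `F0`, `r`,
#'   `retained`, `exclusion_reason`).
#' @export
sum_dff <- function(raw_f, fs, bin_s = 8, qc_threshold = 0.8) {
  assert_numeric_vector(raw_f, "raw_f")
  assert_scalar(fs, "fs", positive = TRUE)
  w <- round(bin_s * fs)
  n_bins <- length(raw_f) %/% w
  if (n_bins < 1L) abort("session shorter than one bin")
  bins <- purrr::map_dfr(seq_len(n_bins), function(k) {
    f <- raw_f[seq.int((k - 1L) * w + 1L, k * w)]
    f0 <- as.numeric(quantile(f, 0.20))
    if (!is.finite(f0) || f0 <= 0) {
      return(tibble(bin = k, F0 = f0, r = NA_real_, retained = FALSE,
                    exclusion_reason = "non-positive F0", sum = NA_real_))
    }
    dff <- (f - f0) / f0
    r <- if (sd(f) < .Machine$double.eps) NA_real_ else cor(dff, f)
    retained <- !is.na(r) && r >= qc_threshold
    tibble(
      bin = k, F0 = f0, r = r, retained = retained,
      exclusion_reason = dplyr::case_when(
        is.na(r) ~ "undefined correlation (zero variance)",
        r < qc_threshold ~ sprintf("correlation %.3f below QC threshold", r),
        TRUE ~ NA_character_
      ),
      sum = sum(dff)
    )
  })
  structure(
    list(
      sum_dff = sum(bins$sum[bins$retained]),
      n_bins = n_bins,
      n_excluded_bins = sum(!bins$retained),
      bins = select(bins, -"sum")
    ),
    class = "activity_summary"
  )
}

#' Plateau amplitude of a digging trial
#'
#' Mean dF/F0 over the plateau stage, the half-open interval `[1, 2)` s after
#' digging initiation, on a trial window that starts at `window_start` s
#' relative to onset.
#'
#' @param dff trial dF/F0 trace aligned to the analysis window.
#' @param fs sampling rate (Hz).
#' @param window_start trial-window start relative to onset (s).
#' @param interval amplitude interval relative to onset (s), half-open.
#' @return mean dF/F0 over the interval.
#' @export
plateau_amplitude <- function(dff, fs, window_start = -5, interval = c(1, 2)) {
  assert_numeric_vector(dff, "dff")
  i0 <- round((interval[1] - window_start) * fs) + 1L
  i1 <- round((interval[2] - window_start) * fs)
  if (i0 < 1L || i1 > length(dff)) {
    abort("trial window does not cover the amplitude interval")
  }
  mean(dff[seq.int(i0, i1)])
}

#' Peak amplitude of a licking trial
#'
#' Mean dF/F0 over the half-open interval `[0, 0.5)` s after lick initiation.
#'
#' @inheritParams plateau_amplitude
#' @export
peak_amplitude <- function(dff, fs, window_start = -5) {
  plateau_amplitude(dff, fs, window_start, interval = c(0, 0.5))
}
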