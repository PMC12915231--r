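# Raw fluorescence -> artifact-corrected, behavior-locked dF/F0 segments.

#' Behavior-specific analysis windows
#'
#' Peri-event analysis and baseline windows, in seconds relative to behavior
#' onset. Digging and licking use a (-5, 5) s window with baseline (-4, -2) s;
#' contralateral turning uses (-1, 1) s with baseline (-1, 0) s.
#'
#' @param behavior one of `"digging"`, `"licking"`, `"turning"`.
#' @return list with `window` and `baseline`, each length-2 numeric (s).
#' @export
behavior_window <- function(behavior = c("digging", "licking", "turning")) {
  behavior <- match.arg(behavior)
  if (behavior == "turning") {
    list(window = c(-1, 1), baseline = c(-1, 0))
  } else {
    list(window = c(-5, 5), baseline = c(-4, -2))
  }
}

low_pass_trend <- function(x, fs, cutoff = 0.005) {
  # slow trend (bleaching-scale); cutoff well below any calcium dynamics
  if (length(x) < 12L) return(rep(mean(x), length(x)))
  bf <- signal::butter(2, min(cutoff / (fs / 2), 0.5), type = "low")
  as.numeric(signal::filtfilt(bf, x - mean(x))) + mean(x)
}

#' Isosbestic-based bleaching and motion correction
#'
#' Removes the calcium-independent component (photobleaching drift plus motion
#' artifact) from a signal channel using its isosbestic reference. The slope
#' and intercept are estimated by least squares between the low-pass-detrended
#' signal and detrended isosbestic traces over the whole session; the scaled
#' isosbestic is then subtracted from the raw signal and the signal's mean
#' level restored, so the output has the same length and mean as the input.
#'
#' @param signal raw signal-channel fluorescence (arbitrary units).
#' @param isosbestic raw isosbestic-channel fluorescence, same length.
#' @param fs sampling rate (Hz).
#' @return corrected trace, numeric vector of the same length.
#' @export
isosbestic_correct <- function(signal, isosbestic, fs) {
  assert_numeric_vector(signal, "signal")
  assert_numeric_vector(isosbestic, "isosbestic")
  assert_scalar(fs, "fs", positive = TRUE)
  if (length(signal) != length(isosbestic)) {
    abort("`signal` and `isosbestic` must have equal length")
  }
  trend_s <- low_pass_trend(signal, fs)
  recenter <- function(y) y + (mean(signal) - mean(y))  # preserve mean level
  if (var(isosbestic) < .Machine$double.eps) {
    warn("isosbestic channel has zero variance; correction skipped, returning detrended signal")
    return(recenter(signal - trend_s))
  }
  s_d <- signal - trend_s
  i_d <- isosbestic - low_pass_trend(isosbestic, fs)
  a_hat <- sum(i_d * s_d) / sum(i_d * i_d)
  b_hat <- mean(signal - a_hat * isosbestic)
  recenter(signal - (a_hat * isosbestic + b_hat))
}

window_indices <- function(onset_idx, win, fs) {
  # half-open sample range [round(start*fs), round(end*fs)) relative to onset
  lo <- onset_idx + round(win[1] * fs)
  hi <- onset_idx + round(win[2] * fs) - 1L
  seq.int(lo, hi)
}

#' Compute peri-event dF/F0
#'
#' Extracts one behavior-locked trial from a full-session fluorescence trace
#' and normalizes it as dF/F0 = (F - F0) / F0, where F0 is the mean of F over
#' the behavior-specific baseline window. Window and baseline are realized as
#' half-open sample-index ranges; the onset is snapped to the nearest sample.
#'
#' @param trace full-session (corrected) raw fluorescence.
#' @param fs sampling rate (Hz).
#' @param onset_s behavior onset on the session clock (s); the session clock
#'   is assumed to start at `t0`.
#' @param behavior behavior label selecting the window pair (see
#'   [behavior_window()]), ignored when `window`/`baseline` given explicitly.
#' @param window,baseline optional explicit windows (s relative to onset).
#' @param t0 session time of the first sample (s).
#' @return tibble with `time_rel_s` and `dff`, plus attributes `F0` (raw-unit
#'   baseline mean) and `behavior`.
#' @export
compute_dff <- function(trace, fs, onset_s, behavior = "digging",
                        window = NULL, baseline = NULL, t0 = 0) {
  assert_numeric_vector(trace, "trace")
  assert_scalar(fs, "fs", positive = TRUE)
  assert_scalar(onset_s, "onset_s")
  if (is.null(window) || is.null(baseline)) {
    bw <- behavior_window(behavior)
    if (is.null(window)) window <- bw$window
    if (is.null(baseline)) baseline <- bw$baseline
  }
  if (baseline[1] < window[1] || baseline[2] > window[2]) {
    abort("baseline window must lie inside the analysis window")
  }
  onset_idx <- round((onset_s - t0) * fs) + 1L
  wi <- window_indices(onset_idx, window, fs)
  bi <- window_indices(onset_idx, baseline, fs)
  if (length(bi) < 1L) abort("baseline window is empty")
  if (min(wi) < 1L || max(wi) > length(trace)) {
    abort(sprintf(
      "trial window [%.2f, %.2f] s around onset %.2f s exceeds recording bounds",
      window[1], window[2], onset_s
    ))
  }
  f0 <- mean(trace[bi])
  if (!is.finite(f0) || f0 <= 0) {
    abort(sprintf("degenerate baseline: F0 = %.4g must be > 0", f0))
  }
  out <- tibble(
    time_rel_s = (wi - onset_idx) / fs,
    dff = (trace[wi] - f0) / f0
  )
  attr(out, "F0") <- f0
  attr(out, "behavior") <- behavior
  out
}

#' Zero-phase bandpass filter
#'
#' Band-limits a trace with a second-order Butterworth high-pass / low-pass
#' cascade applied forward-backward (zero phase, so lag estimates downstream
#' are unaffected). The trace mean is removed before filtering, making the DC
#' gain exactly zero even on segments far shorter than the high-pass corner
#' period. Default band 0.001-3 Hz.
#'
#' @param x numeric trace.
#' @param fs sampling rate (Hz); must exceed `2 * high`.
#' @param low,high band edges (Hz).
#' @return filtered trace, same length.
#' @export
bandpass <- function(x, fs, low = 0.001, high = 3) {
  assert_numeric_vector(x, "x")
  assert_scalar(fs, "fs", positive = TRUE)
  if (fs <= 2 * high) abort("`fs` must exceed twice the upper band edge")
  if (length(x) < 24L) abort("trace too short to bandpass filter")
  xm <- x - mean(x)
  hp <- signal::butter(2, low / (fs / 2), type = "high")
  lp <- signal::butter(2, high / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(lp, signal::filtfilt(hp, xm)))
}

#' Trim trace edges
#'
#' Removes `round(seconds * fs)` samples from each end of a trace; applied to
#' digging and licking trials only (pipeline policy), never to turning trials.
#'
#' @param x numeric trace.
#' @param fs sampling rate (Hz).
#' @param seconds seconds to drop at each end.
#' @return shortened trace.
#' @export
trim_trace <- function(x, fs, seconds = 1) {
  assert_numeric_vector(x, "x")
  assert_scalar(fs, "fs", positive = TRUE)
  k <- round(seconds * fs)
  if (length(x) - 2L * k < 2L) {
    abort(sprintf(
      "trace of %d samples too short to trim %d samples from each end",
      length(x), k
    ))
  }
  x[seq.int(k + 1L, length(x) - k)]
}
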