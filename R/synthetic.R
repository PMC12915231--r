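# Synthetic dual-region photometry sessions with known ground truth.
#
# The generator encodes the statistical structure the estimators assume: two
# calcium traces driven by a shared behavior-locked transient with a
# configurable inter-region lag, region-specific amplitude, slow exponential
# bleaching, a motion artifact common to each region's signal and isosbestic
# channels, Gaussian sensor noise, digging event trains obeying the trial
# inclusion rules, and a motion-energy regressor correlated with the latent
# drive.

#' Simulation parameters
#'
#' Constructor for the parameter set of [simulate_session()]. Amplitudes and
#' noise are in dF/F0 units (fractions of baseline fluorescence); the motion
#' artifact SD is likewise a fraction of `baseline_F`. A positive
#' `inter_region_lag` means region B precedes region A.
#'
#' @param sampling_rate photometry sampling rate (Hz).
#' @param session_length session duration (s).
#' @param n_events named counts of behavioral events, e.g.
#'   `c(digging = 8, turning = 0)`.
#' @param amplitude length-2 named transient amplitude per region (dF/F0).
#' @param rise,decay transient kinetics (s).
#' @param inter_region_lag signed lag (s); positive = B precedes A.
#' @param shared_fraction fraction of region B's drive shared with region A,
#'   in `[0, 1]`.
#' @param noise_sd per-channel Gaussian sensor noise SD (dF/F0 units).
#' @param bleach_tau,bleach_amplitude exponential bleaching time constant (s)
#'   and total fractional amplitude.
#' @param motion_artifact_sd SD of the common motion artifact (fraction of
#'   baseline).
#' @param baseline_F baseline fluorescence (raw units).
#' @param motion_coupling_gain gain from latent drive to motion energy.
#' @param me_noise_sd motion-energy sensor noise SD.
#' @param fs_video video frame rate for the motion-energy trace (Hz).
#' @param event_duration length-2 range of digging durations (s).
#' @param success_prob probability a digging event retrieves a pellet.
#' @param seed integer seed; identical parameter sets (including the seed)
#'   reproduce bit-identical sessions.
#' @return validated list of class `sim_params`.
#' @export
sim_params <- function(sampling_rate = 40,
                       session_length = 320,
                       n_events = c(digging = 12, turning = 0),
                       amplitude = c(a = 0.30, b = 0.25),
                       rise = 0.15,
                       decay = 0.8,
                       inter_region_lag = 0,
                       shared_fraction = 0.9,
                       noise_sd = 0.02,
                       bleach_tau = 600,
                       bleach_amplitude = 0.15,
                       motion_artifact_sd = 0.01,
                       baseline_F = 100,
                       motion_coupling_gain = 2,
                       me_noise_sd = 0.2,
                       fs_video = 30,
                       event_duration = c(3.5, 6),
                       success_prob = 0.6,
                       seed = 1L) {
  p <- list(
    sampling_rate = sampling_rate, session_length = session_length,
    n_events = n_events, amplitude = amplitude, rise = rise, decay = decay,
    inter_region_lag = inter_region_lag, shared_fraction = shared_fraction,
    noise_sd = noise_sd, bleach_tau = bleach_tau,
    bleach_amplitude = bleach_amplitude,
    motion_artifact_sd = motion_artifact_sd, baseline_F = baseline_F,
    motion_coupling_gain = motion_coupling_gain, me_noise_sd = me_noise_sd,
    fs_video = fs_video, event_duration = event_duration,
    success_prob = success_prob, seed = as.integer(seed)
  )
  assert_scalar(p$sampling_rate, "sampling_rate", positive = TRUE)
  assert_scalar(p$session_length, "session_length", positive = TRUE)
  if (p$shared_fraction < 0 || p$shared_fraction > 1) {
    abort("`shared_fraction` must lie in [0, 1]")
  }
  if (p$rise <= 0 || p$decay <= 0 || p$rise >= p$decay) {
    abort("transient kinetics require 0 < rise < decay")
  }
  if (is.null(names(p$n_events))) names(p$n_events) <- "digging"
  if (p$baseline_F <= 0) abort("`baseline_F` must be > 0")
  structure(p, class = "sim_params")
}

# double-exponential calcium impulse response, peak-normalized
calcium_kernel <- function(fs, rise, decay, support = NULL) {
  if (is.null(support)) support <- 6 * decay
  t <- seq(0, support, by = 1 / fs)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

smooth_noise <- function(n, fs, cutoff = 2, sd_target = 1) {
  z <- rnorm(n + 200)
  bf <- signal::butter(2, min(cutoff / (fs / 2), 0.99), type = "low")
  z <- as.numeric(signal::filtfilt(bf, z))[101:(n + 100)]
  s <- sd(z)
  if (s < .Machine$double.eps) rep(0, n) else z * (sd_target / s)
}

shift_trace <- function(x, k) {
  # positive k: advance the trace (x_out(t) = x(t + k samples)), zero-padded
  n <- length(x)
  if (k == 0) return(x)
  if (k > 0) c(x[(k + 1):n], rep(0, k)) else c(rep(0, -k), x[1:(n + k)])
}

schedule_digging <- function(p) {
  fs <- p$sampling_rate
  n_dig <- as.integer(p$n_events[["digging"]])
  if (n_dig == 0L) {
    return(tibble(event_type = character(0), onset_s = numeric(0),
                  offset_s = numeric(0)))
  }
  lead_in <- 12    # >= 10 s clean baseline + 5 s analysis pre-window headroom
  tail_out <- 8    # analysis window + margin after the last onset
  min_gap <- 10.5  # dig-free interval enforced between offset and next onset
  needed <- lead_in + n_dig * (min_gap + p$event_duration[1]) + tail_out
  if (p$session_length < needed) {
    abort(sprintf(
      "session_length %.0f s too short for %d digging events (needs >= %.0f s for the 10 s baseline and 3 s duration rules)",
      p$session_length, n_dig, needed
    ))
  }
  # sample onsets uniformly over the constraint-satisfying region: allocate
  # the free slack by sorted uniforms (the conditional law of naive rejection)
  durs <- runif(n_dig, p$event_duration[1], p$event_duration[2])
  consumed <- if (n_dig > 1) sum(durs[-n_dig] + min_gap) else 0
  slack <- (p$session_length - tail_out) - lead_in - consumed
  if (slack <= 0) {
    abort("could not place digging events satisfying inclusion rules; lengthen the session")
  }
  u <- sort(runif(n_dig, 0, slack))
  onsets <- lead_in + u + c(0, cumsum(durs[-n_dig] + min_gap))
  offs <- onsets + durs
  stopifnot(all(diff(onsets) - durs[-n_dig] >= min_gap), all(offs + 1 < p$session_length))
  tibble(event_type = "digging", onset_s = onsets, offset_s = offs)
}

schedule_turning <- function(p, digs) {
  n_turn <- if ("turning" %in% names(p$n_events)) as.integer(p$n_events[["turning"]]) else 0L
  if (n_turn == 0L) {
    return(tibble(event_type = character(0), onset_s = numeric(0),
                  offset_s = numeric(0), turn_angle = numeric(0)))
  }
  picked <- numeric(0)
  for (attempt in 1:5000) {
    if (length(picked) == n_turn) break
    cand <- runif(1, 3, p$session_length - 3)
    clear_digs <- !any(digs$offset_s > cand - 1 & digs$onset_s < cand + 1)
    clear_turns <- all(abs(picked - cand) >= 4.5)
    if (clear_digs && clear_turns) picked <- c(picked, cand)
  }
  if (length(picked) < n_turn) abort("could not place turning events; lengthen the session")
  picked <- sort(picked)
  tibble(event_type = "turning", onset_s = picked, offset_s = picked + 1,
         turn_angle = runif(n_turn, 95, 180))
}

#' Simulate a dual-region photometry session
#'
#' Generates raw fluorescence for two signal channels and their isosbestic
#' references, a behavioral event table obeying the digging inclusion rules
#' (at least 10 s digging-free baseline and at least 3 s duration for every
#' scheduled event), a motion-energy trace at video rate, and a ground-truth
#' record of the coupling parameters. Signal channels compose as
#' `F = baseline_F * (1 + bleach + motion + calcium + noise)`; isosbestic
#' channels carry the identical bleach and motion components but no calcium.
#' Region B's calcium drive is region A's drive time-shifted by
#' `inter_region_lag` mixed with an independent drive at weight
#' `1 - shared_fraction`.
#'
#' @param params a [sim_params()] object.
#' @return list with `session` (tibble `time_s`, `region_a_raw`,
#'   `region_b_raw`, `isosbestic_a`, `isosbestic_b`; attributes
#'   `sampling_rate`, `metadata`), `events` (tibble), `motion_energy`
#'   (tibble `time_s`, `value` at `fs_video`), and `truth` (list: `true_lag`,
#'   `true_correlation`, `true_beta`, `event_onsets`, `true_plateau`).
#' @export
simulate_session <- function(params) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  p <- params
  fs <- p$sampling_rate
  n <- round(p$session_length * fs)
  t <- (seq_len(n) - 1) / fs

  events <- with_seed(substream_seed(p$seed, "events"), {
    digs <- schedule_digging(p)
    turns <- schedule_turning(p, digs)
    if (nrow(digs)) {
      digs$retrieved_pellet <- runif(nrow(digs)) < p$success_prob
    }
    bind_rows(digs, turns) %>% arrange(.data$onset_s)
  })
  digs <- dplyr::filter(events, .data$event_type == "digging")

  # shared behavior-locked drive: event boxcar convolved with the kernel
  box <- rep(0, n)
  for (i in seq_len(nrow(digs))) {
    i0 <- round(digs$onset_s[i] * fs) + 1L
    i1 <- min(round(digs$offset_s[i] * fs), n)
    box[i0:i1] <- 1
  }
  kern <- calcium_kernel(fs, p$rise, p$decay)
  drive <- stats::filter(c(box, rep(0, length(kern))), kern, method = "convolution",
                         sides = 1)
  drive <- as.numeric(drive)[seq_len(n)]
  drive[is.na(drive)] <- 0
  if (max(drive) > 0) drive <- drive / max(drive)

  lag_k <- round(p$inter_region_lag * fs)
  drive_b_shared <- shift_trace(drive, lag_k)
  indep <- with_seed(substream_seed(p$seed, "independent-drive"), {
    u <- smooth_noise(n, fs, cutoff = 2, sd_target = max(sd(drive), 1e-12))
    u - min(u)  # keep the independent drive nonnegative like the shared one
  })
  f_sh <- p$shared_fraction
  ca_a <- p$amplitude[["a"]] * drive
  ca_b <- p$amplitude[["b"]] * (f_sh * drive_b_shared + (1 - f_sh) * indep)

  bleach <- p$bleach_amplitude * (exp(-t / p$bleach_tau) - 1)
  mot_a <- if (p$motion_artifact_sd > 0) {
    with_seed(substream_seed(p$seed, "motion-a"),
              smooth_noise(n, fs, cutoff = 2, sd_target = p$motion_artifact_sd))
  } else rep(0, n)
  mot_b <- if (p$motion_artifact_sd > 0) {
    with_seed(substream_seed(p$seed, "motion-b"),
              smooth_noise(n, fs, cutoff = 2, sd_target = p$motion_artifact_sd))
  } else rep(0, n)

  eps <- with_seed(substream_seed(p$seed, "sensor-noise"), {
    matrix(rnorm(4L * n, sd = p$noise_sd), ncol = 4)
  })

  session <- tibble(
    time_s = t,
    region_a_raw = p$baseline_F * (1 + bleach + mot_a + ca_a + eps[, 1]),
    region_b_raw = p$baseline_F * (1 + bleach + mot_b + ca_b + eps[, 2]),
    isosbestic_a = p$baseline_F * (1 + bleach + mot_a + eps[, 3]),
    isosbestic_b = p$baseline_F * (1 + bleach + mot_b + eps[, 4])
  )
  attr(session, "sampling_rate") <- fs
  attr(session, "metadata") <- list(seed = p$seed)

  # motion energy at video rate, driven by the same latent drive
  me <- with_seed(substream_seed(p$seed, "motion-energy"), {
    tv <- seq(0, max(t), by = 1 / p$fs_video)
    latent_v <- approx(t, drive, xout = tv, rule = 2)$y
    val <- p$motion_coupling_gain * latent_v
    if (p$me_noise_sd > 0) val <- val + rnorm(length(tv), sd = p$me_noise_sd)
    tibble(time_s = tv, value = pmax(val, 0))
  })

  truth <- session_truth(p, t, fs, digs, ca_a, ca_b, me)
  list(session = session, events = events, motion_energy = me, truth = truth)
}

session_truth <- function(p, t, fs, digs, ca_a, ca_b, me) {
  n <- length(t)
  # population trial correlation implied by the mixing weights and noise:
  # computed from the noiseless calcium components over the trial windows
  wi <- unlist(lapply(digs$onset_s, function(on) {
    i <- round(on * fs) + 1L + seq.int(round(-5 * fs), round(5 * fs) - 1L)
    i[i >= 1 & i <= n]
  }))
  true_cor <- if (length(wi) > 2) {
    va <- var(ca_a[wi]) + p$noise_sd^2
    vb <- var(ca_b[wi]) + p$noise_sd^2
    if (va > 0 && vb > 0) cov(ca_a[wi], ca_b[wi]) / sqrt(va * vb) else NA_real_
  } else NA_real_

  plate <- function(ca) {
    if (nrow(digs) == 0L) return(NA_real_)
    mean(vapply(digs$onset_s, function(on) {
      i <- round(on * fs) + 1L + seq.int(round(1 * fs), round(2 * fs) - 1L)
      mean(ca[i[i >= 1 & i <= n]])
    }, numeric(1)))
  }

  # population GLM slope of the region-A calcium on the convolved,
  # photometry-rate motion-energy regressor
  true_beta <- tryCatch({
    mer <- resample_trace(me$value, from = p$fs_video, to = fs, n_out = n)
    x <- gaussian_convolve(mer, fs)
    if (var(x) > 0) cov(ca_a, x) / var(x) else NA_real_
  }, error = function(e) NA_real_)

  list(
    true_lag = p$inter_region_lag,
    true_correlation = true_cor,
    true_beta = true_beta,
    event_onsets = digs$onset_s,
    true_plateau = c(a = plate(ca_a), b = plate(ca_b))
  )
}

#' Simulate a bivariate VAR process
#'
#' Draws a realization of a two-variable vector autoregression of the given
#' order for Granger-causality testing. Coefficient arguments may be scalars
#' (placed at lag 1) or length-`order` vectors; `a_xy` is the effect of
#' lagged x on y. The companion-matrix spectral radius must be below 1.
#'
#' @param a_xy,a_yx cross coefficients (x driving y, y driving x).
#' @param order VAR order.
#' @param n sample length (after burn-in); must exceed `10 * order`.
#' @param noise_sd innovation SD (both equations).
#' @param seed integer seed.
#' @param a_xx,a_yy own-lag coefficients.
#' @return tibble with columns `x` and `y`.
#' @export
simulate_var_pair <- function(a_xy, a_yx, order = 1, n = 2000, noise_sd = 1,
                              seed = 1L, a_xx = 0, a_yy = 0) {
  pad <- function(a) {
    a <- as.numeric(a)
    if (length(a) == 1L && order > 1L) a <- c(a, rep(0, order - 1L))
    if (length(a) != order) abort("coefficient vectors must have length 1 or `order`")
    a
  }
  a_xy <- pad(a_xy); a_yx <- pad(a_yx); a_xx <- pad(a_xx); a_yy <- pad(a_yy)
  if (n <= 10 * order) abort("`n` must exceed 10 * order")
  # companion matrix of the stacked VAR(p)
  A_blocks <- lapply(seq_len(order), function(k) {
    matrix(c(a_xx[k], a_xy[k], a_yx[k], a_yy[k]), 2, 2)
  })
  comp <- matrix(0, 2 * order, 2 * order)
  for (k in seq_len(order)) comp[1:2, (2 * k - 1):(2 * k)] <- A_blocks[[k]]
  if (order > 1) comp[3:(2 * order), 1:(2 * (order - 1))] <- diag(2 * (order - 1))
  sr <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (sr >= 1) {
    abort(sprintf("explosive coefficient set: companion spectral radius %.3f >= 1", sr))
  }
  burn <- 200L
  with_seed(seed, {
    ex <- rnorm(n + burn, sd = noise_sd)
    ey <- rnorm(n + burn, sd = noise_sd)
    x <- numeric(n + burn); y <- numeric(n + burn)
    for (tt in seq.int(order + 1L, n + burn)) {
      xs <- x[tt - seq_len(order)]; ys <- y[tt - seq_len(order)]
      x[tt] <- sum(a_xx * xs) + sum(a_yx * ys) + ex[tt]
      y[tt] <- sum(a_xy * xs) + sum(a_yy * ys) + ey[tt]
    }
    tibble(x = x[(burn + 1):(burn + n)], y = y[(burn + 1):(burn + n)])
  })
}

#' Simulate a lick-sensor timestamp stream
#'
#' For each cue the animal responds with probability `response_prob`; a
#' response is a bout whose first lick follows the cue by a short latency and
#' whose inter-lick intervals are drawn from `ili_distribution` (a constant,
#' or a function of `n` returning draws).
#'
#' @param cue_times sorted cue timestamps (s).
#' @param response_prob per-cue response probability.
#' @param ili_distribution constant inter-lick interval (s) or `function(n)`.
#' @param licks_per_cue licks per responding bout.
#' @param latency_range range of first-lick latency after the cue (s).
#' @param seed integer seed.
#' @return strictly increasing lick timestamps (numeric).
#' @export
simulate_lick_stream <- function(cue_times, response_prob = 1,
                                 ili_distribution = 0.15, licks_per_cue = 5,
                                 latency_range = c(0.2, 0.8), seed = 1L) {
  if (length(cue_times) && is.unsorted(cue_times)) abort("`cue_times` must be sorted")
  draw_ili <- if (is.function(ili_distribution)) {
    ili_distribution
  } else {
    function(n) rep(ili_distribution, n)
  }
  licks <- with_seed(seed, {
    unlist(lapply(cue_times, function(cue) {
      if (runif(1) >= response_prob) return(numeric(0))
      first <- cue + runif(1, latency_range[1], latency_range[2])
      cumsum(c(first, draw_ili(licks_per_cue - 1L)))
    }))
  })
  licks <- sort(licks)
  if (length(licks) > 1 && any(diff(licks) <= 0)) {
    abort("generated lick stream is not strictly increasing; space the cues further apart")
  }
  licks
}

#' Simulate a motion-energy trace
#'
#' Returns a nonnegative motion-energy trace at the video frame rate,
#' proportional to a latent drive plus Gaussian noise (rectified at zero).
#'
#' @param latent_drive latent drive sampled at `fs_latent`.
#' @param gain multiplicative gain (>= 0).
#' @param noise_sd additive noise SD.
#' @param fs_video output frame rate (Hz).
#' @param fs_latent sampling rate of `latent_drive` (Hz).
#' @param seed integer seed.
#' @return tibble with `time_s` and `value` at `fs_video`.
#' @export
simulate_motion_energy <- function(latent_drive, gain, noise_sd = 0,
                                   fs_video = 30, fs_latent = 40, seed = 1L) {
  if (gain < 0) abort("`gain` must be >= 0")
  assert_numeric_vector(latent_drive, "latent_drive")
  t_lat <- (seq_along(latent_drive) - 1) / fs_latent
  tv <- seq(0, max(t_lat), by = 1 / fs_video)
  base <- gain * approx(t_lat, latent_drive, xout = tv, rule = 2)$y
  val <- with_seed(seed, {
    if (noise_sd > 0) base + rnorm(length(tv), sd = noise_sd) else base
  })
  tibble(time_s = tv, value = pmax(val, 0))
}

#' Simulate trial pairs with an exact population correlation
#'
#' Builds `n_trials` pairs of smooth (3 Hz low-passed Gaussian) dF/F0-like
#' traces whose population Pearson correlation is exactly `rho`:
#' `a = z1`, `b = rho * z1 + sqrt(1 - rho^2) * z2` with `z1, z2` independent
#' realizations of the same process. Identical linear filtering downstream
#' (the 0.001-3 Hz bandpass) leaves the population correlation unchanged.
#'
#' @param rho target population correlation in `[-1, 1]`.
#' @param n_trials number of trial pairs.
#' @param duration trial length (s).
#' @param fs sampling rate (Hz).
#' @param seed integer seed.
#' @return nested tibble: `trial`, list-columns `dff_a`, `dff_b`.
#' @export
simulate_coupled_trials <- function(rho, n_trials, duration = 10, fs = 40,
                                    seed = 1L) {
  if (abs(rho) > 1) abort("`rho` must lie in [-1, 1]")
  n <- round(duration * fs)
  bf <- signal::butter(2, min(3 / (fs / 2), 0.99), type = "low")
  # no per-trial standardization: z1 and z2 share one population spectrum, so
  # the mixture has population correlation exactly rho
  draw <- function() {
    as.numeric(signal::filtfilt(bf, rnorm(n + 200)))[101:(n + 100)]
  }
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_trials), function(i) {
      z1 <- draw()
      z2 <- draw()
      tibble(trial = i,
             dff_a = list(z1),
             dff_b = list(rho * z1 + sqrt(1 - rho^2) * z2))
    })
  })
}
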