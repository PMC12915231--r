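# Behavioral definitions: trial inclusion, lick bouts, digging metrics.
#
# Event tables are tibbles with columns event_type, onset_s, offset_s and
# optional attribute columns (turn_angle, retrieved_pellet). Point events
# (licks, cues) have offset_s == onset_s.

validate_events <- function(events) {
  need <- c("event_type", "onset_s", "offset_s")
  miss <- setdiff(need, names(events))
  if (length(miss)) abort(paste("event table missing column(s):", paste(miss, collapse = ", ")))
  if (any(events$offset_s < events$onset_s)) abort("event offsets must be >= onsets")
  dplyr::arrange(as_tibble(events), .data$onset_s)
}

#' Select digging trials for photometry analysis
#'
#' A digging event is included iff it lasts at least `min_duration` seconds
#' and no other digging occurs within the `baseline_s` seconds preceding its
#' onset (a clean non-digging baseline; other behaviors are allowed there).
#' Exclusions are logged with the first violated rule, evaluated in the fixed
#' order duration, then baseline.
#'
#' @param events event tibble (see module header); only rows with
#'   `event_type == "digging"` are considered.
#' @param min_duration minimum digging duration (s).
#' @param baseline_s required digging-free pre-onset interval (s).
#' @return tibble of digging events with columns `included` (logical) and
#'   `exclusion_reason` (NA when included).
#' @export
select_digging_trials <- function(events, min_duration = 3, baseline_s = 10) {
  events <- validate_events(events)
  digs <- dplyr::filter(events, .data$event_type == "digging")
  if (nrow(digs) == 0L) {
    return(mutate(digs, included = logical(0), exclusion_reason = character(0)))
  }
  if (any(digs$onset_s[-1] < digs$offset_s[-nrow(digs)])) {
    abort("overlapping digging events")
  }
  dur_ok <- (digs$offset_s - digs$onset_s) >= min_duration
  base_ok <- vapply(seq_len(nrow(digs)), function(i) {
    lo <- digs$onset_s[i] - baseline_s
    others <- digs[-i, ]
    !any(others$offset_s > lo & others$onset_s < digs$onset_s[i])
  }, logical(1))
  mutate(
    digs,
    included = dur_ok & base_ok,
    exclusion_reason = dplyr::case_when(
      !dur_ok ~ sprintf("duration < %g s", min_duration),
      !base_ok ~ sprintf("digging within %g s pre-onset baseline", baseline_s),
      TRUE ~ NA_character_
    )
  )
}

#' Select contralateral turning trials
#'
#' Includes a turning event iff the turn angle is at least `min_angle`
#' degrees, at least `min_iti` seconds have elapsed since the previous turning
#' event, and the turn does not overlap any digging event in time. Rule order
#' for the logged reason: angle, inter-trial interval, digging overlap.
#'
#' @param events event tibble; turning rows must carry a `turn_angle` column.
#' @param min_angle minimum turn magnitude (degrees).
#' @param min_iti minimum inter-trial interval between turns (s).
#' @return turning-event tibble with `included` and `exclusion_reason`.
#' @export
select_turning_trials <- function(events, min_angle = 90, min_iti = 4) {
  events <- validate_events(events)
  turns <- dplyr::filter(events, .data$event_type == "turning")
  digs <- dplyr::filter(events, .data$event_type == "digging")
  if (nrow(turns) == 0L) {
    return(mutate(turns, included = logical(0), exclusion_reason = character(0)))
  }
  if (!"turn_angle" %in% names(turns) || anyNA(turns$turn_angle)) {
    abort("turning events must carry a `turn_angle` attribute")
  }
  angle_ok <- abs(turns$turn_angle) >= min_angle
  iti_ok <- c(TRUE, diff(turns$onset_s) >= min_iti)
  overlap_ok <- vapply(seq_len(nrow(turns)), function(i) {
    !any(digs$offset_s > turns$onset_s[i] & digs$onset_s < turns$offset_s[i])
  }, logical(1))
  mutate(
    turns,
    included = angle_ok & iti_ok & overlap_ok,
    exclusion_reason = dplyr::case_when(
      !angle_ok ~ sprintf("turn angle < %g degrees", min_angle),
      !iti_ok ~ sprintf("inter-trial interval < %g s", min_iti),
      !overlap_ok ~ "overlaps digging event",
      TRUE ~ NA_character_
    )
  )
}

#' Segment licks into bouts
#'
#' Partitions a strictly increasing lick timestamp stream into maximal runs
#' whose consecutive inter-lick intervals are strictly below `max_ili`; a gap
#' of exactly `max_ili` splits. Bout length is last lick minus first lick, so
#' a single lick forms a bout of length zero.
#'
#' @param lick_times strictly increasing lick timestamps (s).
#' @param max_ili inter-lick interval threshold (s).
#' @return tibble with `start`, `end`, `n_licks`, `bout_length`.
#' @export
segment_lick_bouts <- function(lick_times, max_ili = 1.0) {
  if (length(lick_times) == 0L) {
    return(tibble(start = numeric(0), end = numeric(0),
                  n_licks = integer(0), bout_length = numeric(0)))
  }
  assert_numeric_vector(lick_times, "lick_times")
  if (is.unsorted(lick_times, strictly = TRUE)) {
    abort("`lick_times` must be strictly increasing")
  }
  bout_id <- cumsum(c(1, as.integer(diff(lick_times) >= max_ili)))
  tibble(t = lick_times, bout = bout_id) %>%
    group_by(.data$bout) %>%
    summarise(start = min(.data$t), end = max(.data$t),
              n_licks = dplyr::n(), .groups = "drop") %>%
    mutate(bout_length = .data$end - .data$start) %>%
    select("start", "end", "n_licks", "bout_length")
}

#' Per-cue lick initiation
#'
#' For each cue, the lick initiation is the first lick strictly after the cue
#' and within `response_window` seconds of it; cues with no such lick are
#' unrewarded trials.
#'
#' @param lick_times sorted lick timestamps (s).
#' @param cue_times sorted cue timestamps (s).
#' @param response_window response window after the cue (s).
#' @return tibble with `cue`, `initiation` (NA when unrewarded), `rewarded`.
#' @export
lick_initiation <- function(lick_times, cue_times, response_window = 3) {
  if (length(cue_times) == 0L) {
    return(tibble(cue = numeric(0), initiation = numeric(0), rewarded = logical(0)))
  }
  if (is.unsorted(cue_times) || (length(lick_times) && is.unsorted(lick_times))) {
    abort("inputs must be sorted")
  }
  init <- vapply(cue_times, function(cue) {
    hit <- lick_times[lick_times > cue & lick_times <= cue + response_window]
    if (length(hit)) hit[1] else NA_real_
  }, numeric(1))
  tibble(cue = cue_times, initiation = init, rewarded = !is.na(init))
}

#' Digging performance metrics
#'
#' Mean digging duration, digging frequency (events per minute) and success
#' rate (fraction of pellet-retrieving digs) over an analysis window,
#' conventionally the first 10 minutes after the animal acquires the center
#' pellet. Only events whose onsets fall inside the window count. With zero
#' events, duration and success rate are undefined (NA) and frequency is 0.
#'
#' @param events event tibble; digging rows may carry `retrieved_pellet`.
#' @param window_start,window_s analysis window anchor and length (s).
#' @return one-row tibble: `mean_duration_s`, `frequency_per_min`,
#'   `success_rate`, `n_events`.
#' @export
digging_metrics <- function(events, window_start = 0, window_s = 600) {
  events <- validate_events(events)
  digs <- dplyr::filter(
    events,
    .data$event_type == "digging",
    .data$onset_s >= window_start,
    .data$onset_s < window_start + window_s
  )
  n <- nrow(digs)
  success <- if (n == 0L) {
    NA_real_
  } else if ("retrieved_pellet" %in% names(digs)) {
    mean(as.logical(digs$retrieved_pellet))
  } else {
    NA_real_
  }
  tibble(
    mean_duration_s = if (n) mean(digs$offset_s - digs$onset_s) else NA_real_,
    frequency_per_min = n / (window_s / 60),
    success_rate = success,
    n_events = n
  )
}
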