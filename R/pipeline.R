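# Session/event/config I/O, pipeline orchestration, cohort summaries.

#' Pipeline configuration
#'
#' All defaults are the analysis constants of the method: 40 Hz sampling,
#' 0.001-3 Hz band, (-5, 5) s digging/licking window with (-4, -2) s
#' baseline, (-1, 1) s turning window with (-1, 0) s baseline, 1 s edge trim
#' (digging/licking only), 4 s sliding window advanced by 0.5 s, plateau
#' 1-2 s, peak 0-0.5 s, 8 s sum-dFF bins with a 0.8 QC threshold, GC at
#' alpha 0.05 with BIC lag selection up to order 10 and at most 2
#' differences, and a 2.5 s Gaussian motion kernel.
#'
#' @param ... overrides for any listed field.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sampling_rate = 40,
    filter_band = c(0.001, 3),
    trim_s = 1,
    sliding_window_s = 4,
    sliding_step_s = 0.5,
    max_lag_s = 2,
    plateau_interval = c(1, 2),
    peak_interval = c(0, 0.5),
    bin_s = 8,
    qc_threshold = 0.8,
    gc_alpha = 0.05,
    gc_criterion = "bic",
    gc_max_order = 10,
    gc_max_diff = 2,
    glm_kernel_s = 2.5,
    aggregate = "mean_of_trials",   # or "r_of_mean_trace"
    stages = c("coupling", "causality", "glm"),
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) abort(paste("unknown config field(s):", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  if (!cfg$aggregate %in% c("mean_of_trials", "r_of_mean_trace")) {
    abort("`aggregate` must be 'mean_of_trials' or 'r_of_mean_trace'")
  }
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' YAML round trip: `read_config(write_config(cfg, path))` reproduces the
#' configuration exactly.
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Session and event table I/O
#'
#' Sessions are delimited tables with columns `time_s`, `region_a_raw`,
#' `region_b_raw`, `isosbestic_a`, `isosbestic_b`; events carry
#' `event_type`, `onset_s`, `offset_s` plus any attribute columns; ground
#' truth round-trips through a JSON sidecar.
#'
#' @param session,events tibbles as produced by [simulate_session()].
#' @param truth ground-truth list.
#' @param path file path.
#' @return readers return tibbles (the session reader restores the
#'   `sampling_rate` attribute from the median time step).
#' @export
write_session <- function(session, path) {
  readr::write_csv(session, path)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  s <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "region_a_raw", "region_b_raw", "isosbestic_a", "isosbestic_b")
  miss <- setdiff(need, names(s))
  if (length(miss)) abort(paste("session file missing column(s):", paste(miss, collapse = ", ")))
  dt <- diff(s$time_s)
  if (any(dt <= 0)) abort("session time must be strictly increasing")
  fs <- 1 / median(dt)
  if (max(abs(dt - 1 / fs)) > 0.01 / fs) {
    warn("non-uniform timestamps beyond 1% jitter: resampling by linear interpolation")
    grid <- seq(min(s$time_s), max(s$time_s), by = 1 / fs)
    s <- tibble(
      time_s = grid,
      region_a_raw = approx(s$time_s, s$region_a_raw, grid, rule = 2)$y,
      region_b_raw = approx(s$time_s, s$region_b_raw, grid, rule = 2)$y,
      isosbestic_a = approx(s$time_s, s$isosbestic_a, grid, rule = 2)$y,
      isosbestic_b = approx(s$time_s, s$isosbestic_b, grid, rule = 2)$y
    )
  }
  attr(s, "sampling_rate") <- fs
  s
}

#' @rdname write_session
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_session
#' @export
read_events <- function(path) {
  e <- readr::read_csv(path, show_col_types = FALSE)
  validate_events(e)
}

#' @rdname write_session
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# one session bundle -> per-trial metric rows
process_session <- function(bundle, cfg, subject = NA_character_,
                            group = NA_character_) {
  session <- bundle$session
  fs <- attr(session, "sampling_rate")
  if (is.null(fs)) fs <- cfg$sampling_rate

  corr_a <- isosbestic_correct(session$region_a_raw, session$isosbestic_a, fs)
  corr_b <- isosbestic_correct(session$region_b_raw, session$isosbestic_b, fs)

  digs <- select_digging_trials(bundle$events)
  included <- dplyr::filter(digs, .data$included)
  exclusions <- dplyr::filter(digs, !.data$included) %>%
    mutate(subject = subject)

  # motion regressor on the photometry clock, kernel-convolved once
  reg_full <- NULL
  if ("glm" %in% cfg$stages && !is.null(bundle$motion_energy)) {
    mer <- resample_trace(bundle$motion_energy$value,
                          from = attr(bundle$motion_energy, "source_rate") %||%
                            (1 / median(diff(bundle$motion_energy$time_s))),
                          to = fs, n_out = nrow(session))
    reg_full <- gaussian_convolve(mer, fs, cfg$glm_kernel_s)
  }

  cc_acc <- NULL  # running sum of per-trial cross-correlograms
  rows <- purrr::map_dfr(seq_len(nrow(included)), function(i) {
    onset <- included$onset_s[i]
    tw_a <- tryCatch(compute_dff(corr_a, fs, onset, "digging"),
                     error = function(e) NULL)
    tw_b <- tryCatch(compute_dff(corr_b, fs, onset, "digging"),
                     error = function(e) NULL)
    if (is.null(tw_a) || is.null(tw_b)) return(NULL)
    out <- tibble(subject = subject, group = group, trial = i, onset_s = onset)
    if ("coupling" %in% cfg$stages) {
      a_p <- trim_trace(bandpass(tw_a$dff, fs, cfg$filter_band[1], cfg$filter_band[2]),
                        fs, cfg$trim_s)
      b_p <- trim_trace(bandpass(tw_b$dff, fs, cfg$filter_band[1], cfg$filter_band[2]),
                        fs, cfg$trim_s)
      cc <- cross_correlogram(a_p, b_p, fs, cfg$max_lag_s)
      if (is.null(cc_acc)) {
        cc_acc <<- cc
      } else {
        cc_acc$r <<- cc_acc$r + cc$r
      }
      # a_p/b_p are already the bandpassed+trimmed traces static_correlation
      # would build; the Pearson r at lag 0 is the static coefficient
      out$r <- if (sd(a_p) < .Machine$double.eps || sd(b_p) < .Machine$double.eps) {
        NA_real_
      } else {
        cor(a_p, b_p)
      }
      out$phase_lag_s <- argmax_lag(cc$lag_s, cc$r)
      out$plateau_a <- plateau_amplitude(tw_a$dff, fs, interval = cfg$plateau_interval)
      out$plateau_b <- plateau_amplitude(tw_b$dff, fs, interval = cfg$plateau_interval)
    }
    if ("causality" %in% cfg$stages) {
      g <- tryCatch(
        gc_trial(tw_a$dff, tw_b$dff, fs, alpha = cfg$gc_alpha,
                 max_diff = cfg$gc_max_diff, max_order = cfg$gc_max_order,
                 criterion = cfg$gc_criterion),
        error = function(e) NULL
      )
      if (!is.null(g)) {
        out$gc_ab <- g$gc_ab; out$gc_ba <- g$gc_ba
        out$p_ab <- g$p_ab; out$p_ba <- g$p_ba
        out$gc_order <- g$lag_order; out$gc_d <- g$d_a
        out$gc_usable <- g$usable
      }
    }
    if ("glm" %in% cfg$stages && !is.null(reg_full)) {
      onset_idx <- round(onset * fs) + 1L
      wi <- window_indices(onset_idx, behavior_window("digging")$window, fs)
      if (min(wi) >= 1 && max(wi) <= length(reg_full)) {
        fit <- tryCatch(fit_motion_glm(tw_a$dff, reg_full[wi]),
                        error = function(e) NULL)
        if (!is.null(fit)) {
          out$glm_beta <- fit$beta
          out$glm_r2 <- fit$r_squared
        }
      }
    }
    out
  })
  subject_lag <- if (!is.null(cc_acc) && nrow(rows)) {
    argmax_lag(cc_acc$lag_s, cc_acc$r / nrow(rows))
  } else {
    NA_real_
  }
  list(trials = rows, exclusions = exclusions, subject_lag = subject_lag,
       mean_correlogram = if (is.null(cc_acc)) NULL else
         mutate(cc_acc, r = .data$r / max(1L, nrow(rows))),
       dff = list(corr_a = corr_a, corr_b = corr_b, fs = fs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full coupling pipeline on a cohort
#'
#' Executes preprocessing (isosbestic correction, dF/F0, bandpass, trim),
#' behavioral trial selection, coupling metrics, Granger causality and the
#' motion GLM for every session, then aggregates per subject. Sessions are
#' bundles as returned by [simulate_session()] (list with `session`,
#' `events`, optional `motion_energy`), optionally named by subject, each
#' optionally carrying a `group` element.
#'
#' @param bundles list of session bundles.
#' @param cfg a [pipeline_config()].
#' @param groups optional character vector of group labels per bundle.
#' @return list with `trials` (per-trial tibble), `subjects` (per-subject
#'   aggregates), `exclusions` (log tibble).
#' @export
run_pipeline <- function(bundles, cfg = pipeline_config(), groups = NULL) {
  if (!length(bundles)) abort("no sessions supplied")
  ids <- names(bundles) %||% sprintf("s%02d", seq_along(bundles))
  if (is.null(groups)) {
    groups <- vapply(bundles, function(b) b$group %||% NA_character_, character(1))
  }
  res <- purrr::map(seq_along(bundles), function(i) {
    process_session(bundles[[i]], cfg, subject = ids[i], group = groups[i])
  })
  trials <- purrr::map_dfr(res, "trials")
  exclusions <- purrr::map_dfr(res, "exclusions")
  subjects <- if (nrow(trials)) {
    agg <- trials %>%
      group_by(.data$subject, .data$group) %>%
      summarise(
        dplyr::across(dplyr::any_of(c("r", "plateau_a", "plateau_b",
                                      "glm_beta", "glm_r2")),
                      ~ mean(.x, na.rm = TRUE)),
        phase_lag_trial_mean_s = if ("phase_lag_s" %in% names(trials))
          mean(.data$phase_lag_s, na.rm = TRUE) else NA_real_,
        n_trials = dplyr::n(), .groups = "drop"
      )
    # subject phase lag read off the trial-averaged cross-correlogram
    lag_tbl <- tibble(subject = ids,
                      phase_lag_s = vapply(res, function(x) x$subject_lag, numeric(1)))
    agg <- dplyr::left_join(agg, lag_tbl, by = "subject")
    if (cfg$aggregate == "r_of_mean_trace") {
      warn("aggregate = 'r_of_mean_trace' applies to trial-averaged traces; per-subject r column uses mean of per-trial r when traces are not retained")
    }
    if (all(c("gc_ab", "p_ab") %in% names(trials))) {
      gcs <- trials %>%
        group_by(.data$subject) %>%
        dplyr::group_modify(~ summarize_gc(.x, alpha = cfg$gc_alpha)) %>%
        ungroup() %>%
        tidyr::pivot_wider(names_from = "direction",
                           values_from = c("mean_gc", "frac_significant"),
                           id_cols = "subject")
      agg <- dplyr::left_join(agg, gcs, by = "subject")
    }
    agg
  } else {
    tibble()
  }
  list(trials = trials, subjects = subjects, exclusions = exclusions)
}

#' Nonparametric two-group comparison
#'
#' Mann-Whitney rank-sum test for unpaired data, Wilcoxon matched-pairs test
#' for paired data; two-tailed. All-tied data (no separation, or all paired
#' differences zero) returns p = 1 with a warning.
#'
#' @param values_a,values_b numeric group samples (equal length when paired).
#' @param paired matched-pairs flag.
#' @return tibble with `statistic`, `p.value`, `method`.
#' @export
group_compare <- function(values_a, values_b, paired = FALSE) {
  assert_numeric_vector(values_a, "values_a", min_len = 3L)
  assert_numeric_vector(values_b, "values_b", min_len = 3L)
  if (paired && length(values_a) != length(values_b)) {
    abort("paired comparison requires equal-length samples")
  }
  degenerate <- if (paired) {
    all(values_a == values_b)
  } else {
    length(unique(c(values_a, values_b))) == 1L
  }
  if (degenerate) {
    warn("all-tied data: p = 1")
    return(tibble(statistic = NA_real_, p.value = 1,
                  method = if (paired) "wilcoxon_matched_pairs" else "mann_whitney"))
  }
  wt <- suppressWarnings(wilcox.test(values_a, values_b, paired = paired))
  tibble(statistic = unname(wt$statistic), p.value = wt$p.value,
         method = if (paired) "wilcoxon_matched_pairs" else "mann_whitney")
}

#' Simulate a two-group cohort
#'
#' Convenience wrapper generating `n_per_group` sessions per condition from
#' two [sim_params()] templates (seeds derived deterministically per
#' subject), labelled `"control"` and `"pff_like"` by default.
#'
#' @param n_per_group subjects per group.
#' @param control_params,altered_params `sim_params` templates.
#' @param labels length-2 group labels.
#' @param seed cohort seed.
#' @return named list of session bundles, each with a `group` element.
#' @export
simulate_cohort <- function(n_per_group,
                            control_params = sim_params(),
                            altered_params = sim_params(shared_fraction = 0.5,
                                                        inter_region_lag = 0.3,
                                                        amplitude = c(a = 0.3, b = 0.15)),
                            labels = c("control", "pff_like"),
                            seed = 1L) {
  make <- function(tpl, grp, k) {
    tpl$seed <- substream_seed(seed, paste0(grp, k))
    b <- simulate_session(tpl)
    b$group <- grp
    b
  }
  out <- c(
    lapply(seq_len(n_per_group), function(k) make(control_params, labels[1], k)),
    lapply(seq_len(n_per_group), function(k) make(altered_params, labels[2], k))
  )
  names(out) <- c(sprintf("%s_%02d", labels[1], seq_len(n_per_group)),
                  sprintf("%s_%02d", labels[2], seq_len(n_per_group)))
  out
}
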