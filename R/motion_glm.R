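# Motion-energy GLM: regressing dF/F0 on kernel-convolved motion energy.

#' Motion energy from a grayscale frame stack
#'
#' Frame-by-frame summed absolute grayscale difference:
#' `value[i] = sum(|frame[i+1] - frame[i]|)`, one value per frame transition.
#'
#' @param frames 3-D numeric array `(height, width, n_frames)` or a list of
#'   equal-dimension matrices.
#' @param fs_video frame rate (Hz), recorded on the output.
#' @return tibble with `time_s` (transition times) and `value`
#'   (`n_frames - 1` rows).
#' @export
motion_energy <- function(frames, fs_video = 30) {
  if (is.list(frames) && !is.array(frames)) {
    dims <- lapply(frames, dim)
    if (length(unique(dims)) != 1L) abort("all frames must share the same shape")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be a (height, width, n_frames) array or list of matrices")
  }
  nf <- dim(frames)[3]
  if (nf < 2L) abort("need at least 2 frames")
  val <- vapply(seq_len(nf - 1L), function(i) {
    sum(abs(frames[, , i + 1L] - frames[, , i]))
  }, numeric(1))
  out <- tibble(time_s = seq_len(nf - 1L) / fs_video, value = val)
  attr(out, "source_rate") <- fs_video
  out
}

#' Resample a trace onto a new uniform clock
#'
#' Linear interpolation onto a uniform grid at `to` Hz spanning the source
#' trace, with endpoints clamped; nonnegativity is preserved (interpolation
#' is convex). When source and target clocks coincide the trace is returned
#' unchanged.
#'
#' @param x numeric trace sampled uniformly at `from` Hz starting at t = 0.
#' @param from,to source and target sampling rates (Hz).
#' @param n_out optional exact output length; the grid is then
#'   `(0:(n_out-1)) / to`, clamped extrapolation beyond the source span.
#' @return numeric trace at the target rate.
#' @export
resample_trace <- function(x, from, to = 40, n_out = NULL) {
  assert_numeric_vector(x, "x")
  assert_scalar(from, "from", positive = TRUE)
  assert_scalar(to, "to", positive = TRUE)
  t_src <- (seq_along(x) - 1) / from
  t_tgt <- if (is.null(n_out)) {
    seq(0, max(t_src), by = 1 / to)
  } else {
    (seq_len(n_out) - 1) / to
  }
  if (length(x) == 1L) return(rep(x, length(t_tgt)))
  approx(t_src, x, xout = t_tgt, rule = 2)$y
}

#' Convolve with a unit-area Gaussian kernel
#'
#' Smooths a regressor with a Gaussian kernel to account for calcium
#' indicator dynamics. The default reads the kernel width as a full width of
#' `width` seconds, i.e. `sigma = width / 6`, truncated at three sigma;
#' `parameterization = "sigma"` instead takes `width` as sigma directly.
#' Edges use reflective padding, and the kernel is normalized to unit sum so
#' constant traces pass unchanged.
#'
#' @param x numeric trace.
#' @param fs sampling rate (Hz).
#' @param width kernel width (s); interpretation set by `parameterization`.
#' @param parameterization `"full_width"` (default) or `"sigma"`.
#' @return smoothed trace, same length.
#' @export
gaussian_convolve <- function(x, fs, width = 2.5,
                              parameterization = c("full_width", "sigma")) {
  assert_numeric_vector(x, "x")
  parameterization <- match.arg(parameterization)
  sigma <- if (parameterization == "full_width") width / 6 else width
  half <- max(1L, round(3 * sigma * fs))
  if (length(x) <= half) abort("trace shorter than the kernel support")
  u <- seq.int(-half, half) / fs
  k <- exp(-u^2 / (2 * sigma^2))
  k <- k / sum(k)
  xp <- c(rev(x[seq_len(half) + 1L]), x, x[length(x) - seq_len(half)])
  as.numeric(stats::filter(xp, k, method = "convolution", sides = 2))[half + seq_along(x)]
}

#' Fit the motion-energy GLM for one trial
#'
#' Ordinary least squares of the trial dF/F0 on the convolved motion-energy
#' regressor, with intercept: returns the coupling coefficient beta and the
#' coefficient of determination `R^2 = 1 - RSS/TSS`. Per-mouse aggregation is
#' the mean of trial-level values. A zero-variance regressor leaves the fit
#' undefined and raises an error so callers can exclude the trial.
#'
#' @param dff trial dF/F0 trace.
#' @param regressor convolved motion-energy regressor, same length.
#' @return object of class `motion_glm`: `beta`, `intercept`, `r_squared`,
#'   `n_samples`, plus the fitted values for plotting.
#' @export
fit_motion_glm <- function(dff, regressor) {
  assert_numeric_vector(dff, "dff", min_len = 3L)
  assert_numeric_vector(regressor, "regressor", min_len = 3L)
  if (length(dff) != length(regressor)) abort("`dff` and `regressor` must have equal length")
  if (var(regressor) < .Machine$double.eps) {
    abort("zero-variance regressor: fit undefined, exclude this trial")
  }
  mx <- mean(regressor); my <- mean(dff)
  beta <- sum((regressor - mx) * (dff - my)) / sum((regressor - mx)^2)
  intercept <- my - beta * mx
  fitted <- intercept + beta * regressor
  tss <- sum((dff - my)^2)
  r2 <- if (tss > 0) 1 - sum((dff - fitted)^2) / tss else NA_real_
  structure(
    list(beta = beta, intercept = intercept, r_squared = r2,
         n_samples = length(dff), fitted = fitted,
         dff = dff, regressor = regressor),
    class = "motion_glm"
  )
}

#' @export
print.motion_glm <- function(x, ...) {
  cat(sprintf("Motion-energy GLM: beta = %.4f, intercept = %.4f, R^2 = %.3f (n = %d)\n",
              x$beta, x$intercept, x$r_squared, x$n_samples))
  invisible(x)
}

#' @rdname fit_motion_glm
#' @param x a `motion_glm` object.
#' @param ... unused.
#' @export
tidy.motion_glm <- function(x, ...) {
  tibble(term = c("(Intercept)", "motion_energy"),
         estimate = c(x$intercept, x$beta))
}

#' @rdname fit_motion_glm
#' @export
glance.motion_glm <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n_samples)
}
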