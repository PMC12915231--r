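# Time-domain Granger causality between the two regional signals.

# Quantiles of the Dickey-Fuller tau distribution for the constant-only
# (drift, no trend) testing regression, asymptotic case; p-values are
# obtained by monotone interpolation and clamped to [0.01, 0.99].
DF_TAU_P <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
DF_TAU_Q <- c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)

lag_matrix <- function(x, p) {
  n <- length(x)
  m <- matrix(NA_real_, n - p, p)
  for (k in seq_len(p)) m[, k] <- x[seq.int(p + 1L - k, n - k)]
  m
}

#' Augmented Dickey-Fuller stationarity test
#'
#' Unit-root test with a constant term (no trend): the testing regression is
#' `diff(y) ~ 1 + y[t-1] + diff(y)[t-1..k]`, with the augmentation order `k`
#' chosen by AIC up to `12 * (n/100)^0.25`. The series is called stationary
#' when the interpolated tau p-value falls below `alpha`. A (near-)constant
#' series carries no unit-root information and is reported stationary with a
#' warning.
#'
#' @param x numeric series, length >= 30.
#' @param alpha significance level.
#' @return list: `is_stationary`, `statistic` (tau), `p`, `k` (lags used).
#' @export
adf_test <- function(x, alpha = 0.05) {
  assert_numeric_vector(x, "x", min_len = 30L)
  if (sd(x) < 1e-12 * (abs(mean(x)) + 1)) {
    warn("constant series: ADF uninformative, reported stationary")
    return(list(is_stationary = TRUE, statistic = NA_real_, p = NA_real_, k = 0L))
  }
  n <- length(x)
  kmax <- min(floor(12 * (n / 100)^0.25), n %/% 4L)
  dy <- diff(x)
  best <- NULL
  for (k in 0:kmax) {
    yl <- x[seq.int(kmax + 1L, n - 1L)]
    resp <- dy[seq.int(kmax + 1L, n - 1L)]
    X <- cbind(1, yl)
    if (k > 0) {
      for (j in seq_len(k)) X <- cbind(X, dy[seq.int(kmax + 1L - j, n - 1L - j)])
    }
    fit <- stats::lm.fit(X, resp)
    rss <- sum(fit$residuals^2)
    nn <- length(resp)
    aic <- nn * log(rss / nn) + 2 * ncol(X)
    if (is.null(best) || aic < best$aic) best <- list(aic = aic, fit = fit, X = X, k = k, rss = rss, nn = nn)
  }
  fit <- best$fit
  dof <- best$nn - ncol(best$X)
  sigma2 <- best$rss / dof
  XtX_inv <- chol2inv(chol(crossprod(best$X)))
  se_rho <- sqrt(sigma2 * XtX_inv[2, 2])
  tau <- fit$coefficients[2] / se_rho
  p <- as.numeric(approx(DF_TAU_Q, DF_TAU_P, xout = tau, rule = 2)$y)
  list(is_stationary = p < alpha, statistic = as.numeric(tau), p = p, k = best$k)
}

#' Difference a series until stationary
#'
#' Applies first differences repeatedly until the ADF test rejects the unit
#' root or `max_diff` differences have been taken; callers should exclude
#' series still non-stationary at `max_diff` from causality summaries.
#'
#' @param x numeric series.
#' @param alpha ADF significance level.
#' @param max_diff maximum differencing order.
#' @return list: `series`, `d` (order used), `stationary` (logical).
#' @export
difference_until_stationary <- function(x, alpha = 0.05, max_diff = 2) {
  d <- 0L
  repeat {
    res <- adf_test(x, alpha)
    if (res$is_stationary || d >= max_diff) {
      return(list(series = x, d = d, stationary = res$is_stationary))
    }
    x <- diff(x)
    d <- d + 1L
  }
}

var_fit <- function(x, y, p, t_start = p + 1L, ridge = 0) {
  # OLS fit of the bivariate VAR(p); common sample from t_start allows
  # information criteria comparable across orders.
  n <- length(x)
  idx <- seq.int(t_start, n)
  Y <- cbind(x[idx], y[idx])
  X <- cbind(1, lag_matrix(x, p)[idx - p, , drop = FALSE],
             lag_matrix(y, p)[idx - p, , drop = FALSE])
  XtX <- crossprod(X)
  if (ridge > 0) XtX <- XtX + diag(ridge, ncol(X))
  B <- tryCatch(
    solve(XtX, crossprod(X, Y)),
    error = function(e) solve(XtX + diag(1e-8 * max(diag(XtX)), ncol(X)),
                              crossprod(X, Y))
  )
  E <- Y - X %*% B
  list(B = B, E = E, n_obs = nrow(Y), Sigma = crossprod(E) / nrow(Y))
}

#' Select the VAR lag order by information criterion
#'
#' Fits the bivariate autoregression at each order up to `max_order` on a
#' common sample and returns the order minimizing BIC (default) or AIC. Near
#' singular designs (e.g. one channel a copy of the other) are stabilized by
#' a small ridge, so selection never crashes on degenerate trials.
#'
#' @param x,y equal-length stationary series.
#' @param max_order largest order considered; capped (with a warning) when
#'   the series is too short.
#' @param criterion `"bic"` or `"aic"`.
#' @return selected order (integer).
#' @export
select_lag_order <- function(x, y, max_order = 10, criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  assert_numeric_vector(x, "x"); assert_numeric_vector(y, "y")
  if (length(x) != length(y)) abort("series must have equal length")
  n <- length(x)
  if (n <= 10 * max_order) {
    max_order <- max(1L, floor((n - 1) / 10))
    warn(sprintf("series too short: max_order capped at %d", max_order))
  }
  ics <- vapply(seq_len(max_order), function(p) {
    f <- var_fit(x, y, p, t_start = max_order + 1L)
    detS <- det(f$Sigma)
    if (detS <= 0) detS <- .Machine$double.xmin
    k_params <- 2 * (1 + 2 * p)   # per-equation params * 2 equations
    pen <- if (criterion == "bic") log(f$n_obs) else 2
    log(detS) + pen * k_params / f$n_obs
  }, numeric(1))
  which.min(ics)
}

#' Time-domain Granger causality between two series
#'
#' For each direction, the restricted model regresses the target on its own
#' `order` lags; the full model adds the source's `order` lags. GC is the log
#' ratio of restricted to full residual variances (in nats, >= 0 by nesting);
#' significance is the standard nested-model F test with
#' `(order, n - 2*order - 1)` degrees of freedom.
#'
#' @param x,y equal-length stationary series (direction `ab` is x -> y).
#' @param order VAR lag order (>= 1).
#' @param d_a,d_b differencing orders applied upstream (recorded only).
#' @return object of class `gc_result`: `gc_ab`, `gc_ba`, `p_ab`, `p_ba`,
#'   `f_ab`, `f_ba`, `lag_order`, `d_a`, `d_b`, `n_effective`.
#' @export
granger_causality <- function(x, y, order, d_a = 0L, d_b = 0L) {
  assert_numeric_vector(x, "x"); assert_numeric_vector(y, "y")
  if (length(x) != length(y)) abort("series must have equal length")
  order <- as.integer(order)
  if (order < 1L) abort("`order` must be >= 1")
  n <- length(x)
  n_eff <- n - order
  df2 <- n_eff - 2L * order - 1L
  if (df2 <= 0) abort("series too short for the requested order")

  direction <- function(src, tgt) {
    Ltgt <- lag_matrix(tgt, order)
    Lsrc <- lag_matrix(src, order)
    resp <- tgt[seq.int(order + 1L, n)]
    Xr <- cbind(1, Ltgt)
    Xf <- cbind(Xr, Lsrc)
    qr_f <- qr(Xf)
    if (qr_f$rank < ncol(Xf)) {
      bad <- colnames(Xf)
      abort("singular design in Granger regression: collinear lag columns")
    }
    rss_r <- sum(qr.resid(qr(Xr), resp)^2)
    rss_f <- sum(qr.resid(qr_f, resp)^2)
    gc <- log(rss_r / rss_f)
    f_stat <- ((rss_r - rss_f) / order) / (rss_f / df2)
    list(gc = max(gc, 0), f = f_stat, p = pf(f_stat, order, df2, lower.tail = FALSE))
  }
  ab <- direction(x, y)
  ba <- direction(y, x)
  structure(
    list(
      gc_ab = ab$gc, gc_ba = ba$gc,
      f_ab = ab$f, f_ba = ba$f,
      p_ab = ab$p, p_ba = ba$p,
      lag_order = order, d_a = as.integer(d_a), d_b = as.integer(d_b),
      n_effective = n_eff
    ),
    class = "gc_result"
  )
}

#' Full per-trial Granger-causality pipeline
#'
#' Bandpass-filters both trial signals (0.001-3 Hz), assesses stationarity by
#' ADF, differences both channels to the maximum of their individually
#' required orders (balanced bivariate model), selects the lag order by
#' information criterion, and computes both-direction GC. Trials still
#' non-stationary at `max_diff` are flagged (`usable = FALSE`).
#'
#' @param x,y raw trial signals (region A, region B).
#' @param fs sampling rate (Hz).
#' @param alpha ADF significance level.
#' @param max_diff maximum differencing order.
#' @param max_order maximum VAR order for selection.
#' @param criterion information criterion for lag selection.
#' @return `gc_result` with an extra `usable` flag.
#' @export
gc_trial <- function(x, y, fs, alpha = 0.05, max_diff = 2, max_order = 10,
                     criterion = "bic") {
  xb <- bandpass(x, fs)
  yb <- bandpass(y, fs)
  sx <- difference_until_stationary(xb, alpha, max_diff)
  sy <- difference_until_stationary(yb, alpha, max_diff)
  d <- max(sx$d, sy$d)
  xd <- if (d > sx$d) diff(sx$series, differences = d - sx$d) else sx$series
  yd <- if (d > sy$d) diff(sy$series, differences = d - sy$d) else sy$series
  m <- min(length(xd), length(yd))
  xd <- tail(xd, m); yd <- tail(yd, m)
  p <- suppressWarnings(select_lag_order(xd, yd, max_order, criterion))
  res <- granger_causality(xd, yd, p, d_a = d, d_b = d)
  res$usable <- sx$stationary && sy$stationary
  res
}

#' Summarize Granger causality over trials
#'
#' Per direction, the mean GC over significant trials only (p < `alpha`) and
#' the fraction of trials significant; the mean is NA when no trial reaches
#' significance.
#'
#' @param trials tibble with columns `gc_ab`, `gc_ba`, `p_ab`, `p_ba`
#'   (e.g. `purrr::map_dfr(gc_results, tidy_wide)`) or a list of `gc_result`.
#' @param alpha per-trial significance level.
#' @return tibble with one row per direction: `direction`, `mean_gc`,
#'   `frac_significant`, `n_significant`, `n_trials`.
#' @export
summarize_gc <- function(trials, alpha = 0.05) {
  if (!is.data.frame(trials)) {
    trials <- purrr::map_dfr(trials, function(g) {
      tibble(gc_ab = g$gc_ab, gc_ba = g$gc_ba, p_ab = g$p_ab, p_ba = g$p_ba)
    })
  }
  if (nrow(trials) == 0L) abort("no trials to summarize")
  one <- function(gc, p, label) {
    sig <- !is.na(p) & p < alpha
    tibble(
      direction = label,
      mean_gc = if (any(sig)) mean(gc[sig]) else NA_real_,
      frac_significant = mean(sig),
      n_significant = sum(sig),
      n_trials = length(p)
    )
  }
  bind_rows(
    one(trials$gc_ab, trials$p_ab, "a_to_b"),
    one(trials$gc_ba, trials$p_ba, "b_to_a")
  )
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf(
    "Granger causality (order %d, d = %d/%d, n_eff = %d)\n  A -> B: GC = %.4f nats (F = %.2f, p = %.3g)\n  B -> A: GC = %.4f nats (F = %.2f, p = %.3g)\n",
    x$lag_order, x$d_a, x$d_b, x$n_effective,
    x$gc_ab, x$f_ab, x$p_ab, x$gc_ba, x$f_ba, x$p_ba
  ))
  invisible(x)
}

#' @rdname granger_causality
#' @param x a `gc_result`.
#' @param ... unused.
#' @export
tidy.gc_result <- function(x, ...) {
  tibble(
    direction = c("a_to_b", "b_to_a"),
    gc = c(x$gc_ab, x$gc_ba),
    statistic = c(x$f_ab, x$f_ba),
    p.value = c(x$p_ab, x$p_ba),
    df1 = x$lag_order,
    df2 = x$n_effective - 2L * x$lag_order - 1L
  )
}

#' @rdname granger_causality
#' @export
glance.gc_result <- function(x, ...) {
  tibble(
    lag_order = x$lag_order, d_a = x$d_a, d_b = x$d_b,
    n_effective = x$n_effective
  )
}
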