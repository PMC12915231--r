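# Independent brute-force oracles used to cross-check the implementation.
# Each is written from the definition, without reusing package internals.

# exhaustive lag scan: argmax over tau of |cor(a(t), b(t - tau))|
oracle_phase_lag <- function(a, b, fs, max_lag = 2) {
  lmax <- round(max_lag * fs)
  n <- length(a)
  best <- NULL
  for (tau in -lmax:lmax) {
    if (tau >= 0) {
      x <- a[(1 + tau):n]; y <- b[1:(n - tau)]
    } else {
      x <- a[1:(n + tau)]; y <- b[(1 - tau):n]
    }
    if (sd(x) == 0 || sd(y) == 0) next
    r <- cor(x, y)
    cand <- list(tau = tau, absr = abs(r))
    if (is.null(best) ||
        cand$absr > best$absr + 1e-15 ||
        (abs(cand$absr - best$absr) <= 1e-15 &&
         (abs(cand$tau) < abs(best$tau) ||
          (abs(cand$tau) == abs(best$tau) && cand$tau < best$tau)))) {
      best <- cand
    }
  }
  best$tau / fs
}

# O(n^2) bout grouping: licks i and j share a bout iff a chain of
# consecutive gaps < max_ili connects them
oracle_bouts <- function(licks, max_ili = 1.0) {
  n <- length(licks)
  if (n == 0) return(data.frame(start = numeric(0), end = numeric(0), n_licks = integer(0)))
  same <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && all(diff(licks[i:j]) < max_ili)) same[i, j] <- same[j, i] <- TRUE
    }
  }
  grp <- integer(n); g <- 0L
  for (i in seq_len(n)) {
    if (grp[i] == 0L) {
      g <- g + 1L
      grp[which(same[i, ])] <- g
    }
  }
  do.call(rbind, lapply(split(seq_len(n), grp), function(ix) {
    data.frame(start = min(licks[ix]), end = max(licks[ix]), n_licks = length(ix))
  }))
}

# literal rule application for digging inclusion
oracle_digging <- function(digs, min_duration = 3, baseline_s = 10) {
  sapply(seq_len(nrow(digs)), function(i) {
    if (digs$offset_s[i] - digs$onset_s[i] < min_duration) return(FALSE)
    for (j in seq_len(nrow(digs))) {
      if (j == i) next
      # any digging intersecting (onset - baseline_s, onset)
      if (digs$offset_s[j] > digs$onset_s[i] - baseline_s &&
          digs$onset_s[j] < digs$onset_s[i]) return(FALSE)
    }
    TRUE
  })
}

oracle_turning <- function(turns, digs, min_angle = 90, min_iti = 4) {
  sapply(seq_len(nrow(turns)), function(i) {
    if (abs(turns$turn_angle[i]) < min_angle) return(FALSE)
    if (i > 1 && turns$onset_s[i] - turns$onset_s[i - 1] < min_iti) return(FALSE)
    if (nrow(digs)) {
      for (j in seq_len(nrow(digs))) {
        if (digs$offset_s[j] > turns$onset_s[i] && digs$onset_s[j] < turns$offset_s[i]) {
          return(FALSE)
        }
      }
    }
    TRUE
  })
}

# direct nested-OLS Granger causality via lm(), both directions
oracle_gc <- function(x, y, p) {
  n <- length(x)
  mk <- function(z) sapply(seq_len(p), function(k) z[(p + 1 - k):(n - k)])
  one <- function(src, tgt) {
    resp <- tgt[(p + 1):n]
    Lt <- mk(tgt); Ls <- mk(src)
    fr <- lm(resp ~ Lt)
    ff <- lm(resp ~ Lt + Ls)
    rss_r <- sum(residuals(fr)^2); rss_f <- sum(residuals(ff)^2)
    df2 <- (n - p) - 2 * p - 1
    fstat <- ((rss_r - rss_f) / p) / (rss_f / df2)
    list(gc = log(rss_r / rss_f), f = fstat,
         p = pf(fstat, p, df2, lower.tail = FALSE))
  }
  list(ab = one(x, y), ba = one(y, x))
}

# helper: processed (bandpassed + trimmed) random smooth trial pair
random_trial_pair <- function(n = 400, fs = 40) {
  bf <- signal::butter(2, 3 / (fs / 2), "low")
  a <- as.numeric(signal::filtfilt(bf, rnorm(n)))
  b <- as.numeric(signal::filtfilt(bf, rnorm(n)))
  list(a = a, b = b)
}
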