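# Physiological signal smoothing and HRV-behavior coupling.

#' Sampled physiological signal
#'
#' @param values Numeric sample vector; `values[i]` is the sample at session
#'   time `(i - 1) / rate` seconds (plus `t0`).
#' @param rate Sampling rate in Hz (> 0).
#' @param channel Signal channel label (`"HRV"`, `"SCR"`, `"EMG"`).
#' @param t0 Offset of the first sample to the session clock, seconds.
#' @return A `physio_signal` object.
#' @export
physio_signal <- function(values, rate, channel = "HRV", t0 = 0) {
  values <- as.numeric(values)
  if (rate <= 0) stop("rate must be > 0")
  if (any(!is.finite(values))) stop("signal values must be finite")
  structure(list(values = values, rate = rate, channel = channel, t0 = t0),
            class = "physio_signal")
}

#' @export
print.physio_signal <- function(x, ...) {
  cat(x$channel, " signal: ", length(x$values), " samples @ ", x$rate,
      " Hz (", format(length(x$values) / x$rate, digits = 4), " s)\n", sep = "")
  invisible(x)
}

#' Causal moving-average smoothing
#'
#' `y[n] = mean(x[(n - M + 1):n])`, with partial-window normalization at the
#' start so the output has the same length as the input: the first `M - 1`
#' outputs average over the samples available so far. A constant input is
#' returned unchanged; `M = 1` is the identity.
#'
#' @param signal A [physio_signal()] or numeric vector.
#' @param M Window length in samples (1 <= M <= length of signal).
#' @return Smoothed signal of the same type and length, with window recorded
#'   in attribute `"M"`.
#' @export
moving_average <- function(signal, M) {
  x <- if (inherits(signal, "physio_signal")) signal$values else as.numeric(signal)
  if (M < 1 || M != round(M)) stop("M must be a positive integer")
  if (M > length(x)) stop("window M exceeds series length")
  cs <- cumsum(x)
  n <- length(x)
  y <- numeric(n)
  head_n <- seq_len(min(M, n))
  y[head_n] <- cs[head_n] / head_n
  if (n > M) {
    idx <- (M + 1):n
    y[idx] <- (cs[idx] - cs[idx - M]) / M
  }
  if (inherits(signal, "physio_signal")) {
    signal$values <- y
    attr(signal, "M") <- M
    signal
  } else structure(y, M = M)
}

#' Binary behavior-event indicator series
#'
#' Rasterizes the events of one category onto the sampling grid of a
#' physiological signal: sample `i` is 1 iff session time `(i - 1) / rate`
#' falls inside any `[onset, offset)` event of the category.
#'
#' @param log An [event_log()] (single child/session expected).
#' @param category Category code.
#' @param rate Sampling rate in Hz (must match the paired signal).
#' @param length_out Series length in samples.
#' @return A list of class `event_series`: `values` (0/1), `rate`, `b_bar`
#'   (mean occurrence probability).
#' @export
behavior_indicator <- function(log, category, rate, length_out) {
  alphabet <- attr(log, "alphabet")
  .check_codes(category, alphabet)
  ev <- log[log$category == category, , drop = FALSE]
  if (nrow(ev) && max(ev$offset) > length_out / rate)
    warning("series length shorter than the span of the event log")
  tt <- (seq_len(length_out) - 1) / rate
  v <- integer(length_out)
  for (r in seq_len(nrow(ev)))
    v[tt >= ev$onset[r] & tt < ev$offset[r]] <- 1L
  structure(list(values = v, rate = rate, b_bar = mean(v)),
            class = "event_series")
}

#' Normalized cross-correlation between a signal and an event series
#'
#' Pearson cross-correlation `CC(tau)` between the physiological series and
#' the behavior indicator for lags `tau` in `[-max_lag, max_lag]` samples.
#' Positive `tau` means the behavior sample leads by `tau` relative to the
#' physiological sample being correlated (behavior follows the HRV sample).
#' Statistics are recomputed on the overlapping region at each lag, so
#' `|CC| <= 1` for every lag; a lag whose overlap has zero variance yields
#' `NA`.
#'
#' @param hrv A [physio_signal()] or numeric vector.
#' @param b An `event_series` ([behavior_indicator()]) or numeric vector of
#'   equal length.
#' @param max_lag Maximum lag in samples.
#' @return A list of class `coupling_result`: `lag` (samples), `lag_s`
#'   (seconds, when a rate is known), `cc`, `N`, `peak_lag` (lag of maximum
#'   `|CC|`; ties broken toward the smallest `|lag|`).
#' @export
cross_correlation <- function(hrv, b, max_lag) {
  rate <- NULL
  if (inherits(hrv, "physio_signal")) { rate <- hrv$rate; hrv <- hrv$values }
  if (inherits(b, "event_series")) { rate <- rate %||% b$rate; b <- b$values }
  hrv <- as.numeric(hrv); b <- as.numeric(b)
  if (length(hrv) != length(b)) stop("series must have equal length")
  if (stats::sd(hrv) == 0 || stats::sd(b) == 0)
    stop("zero-variance series: cross-correlation undefined")
  N <- length(hrv)
  if (max_lag < 0 || max_lag >= N) stop("max_lag must be in [0, N)")
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(tau) {
    if (tau >= 0) { x <- hrv[1:(N - tau)]; y <- b[(1 + tau):N] }
    else { x <- hrv[(1 - tau):N]; y <- b[1:(N + tau)] }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, 0)
  ok <- which(!is.na(cc))
  peak <- ok[order(-abs(cc[ok]), abs(lags[ok]))][1]
  structure(list(lag = lags, lag_s = if (!is.null(rate)) lags / rate else NULL,
                 cc = cc, N = N, peak_lag = lags[peak]),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat("Cross-correlation over lags [", min(x$lag), ", ", max(x$lag),
      "] samples; peak |CC| = ",
      format(max(abs(x$cc), na.rm = TRUE), digits = 4),
      " at lag ", x$peak_lag, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Event-locked pre/post contrast of a physiological signal
#'
#' For every event of the category, averages the signal over
#' `[onset - pre_window, onset)` and `[onset, onset + post_window)` and
#' reports the per-event difference together with a paired t test across
#' events. Events whose windows fall outside the recorded series are skipped.
#'
#' @param signal A [physio_signal()].
#' @param log An [event_log()].
#' @param category Category code whose onsets define the locking points.
#' @param pre_window,post_window Window lengths in seconds.
#' @return A list of class `event_locked_contrast`: `pre` and `post`
#'   (per-event means), `difference` (mean post - pre), `t`, `df`, `p`
#'   (`NA` when fewer than 2 usable events or zero variance), `n_events`.
#' @export
event_locked_contrast <- function(signal, log, category, pre_window, post_window) {
  stopifnot(inherits(signal, "physio_signal"))
  alphabet <- attr(log, "alphabet")
  .check_codes(category, alphabet)
  if (pre_window <= 0 || post_window <= 0)
    stop("windows must be positive")
  x <- signal$values; rate <- signal$rate
  n <- length(x)
  onsets <- log$onset[log$category == category] - signal$t0
  pre <- post <- numeric(0)
  for (on in onsets) {
    i0 <- floor((on - pre_window) * rate) + 1
    i1 <- floor(on * rate)            # last sample strictly before onset
    j0 <- floor(on * rate) + 1
    j1 <- floor((on + post_window) * rate)
    if (i0 < 1 || j1 > n || i1 < i0 || j1 < j0) next
    pre <- c(pre, mean(x[i0:i1]))
    post <- c(post, mean(x[j0:j1]))
  }
  if (!length(pre)) stop("no events with both windows inside the series")
  d <- post - pre
  tt <- list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
  if (length(d) >= 2 && stats::sd(d) > 0)
    tt <- stats::t.test(post, pre, paired = TRUE)
  structure(list(pre = pre, post = post, difference = mean(d),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, n_events = length(d)),
            class = "event_locked_contrast")
}

#' @export
print.event_locked_contrast <- function(x, ...) {
  cat("Event-locked contrast over ", x$n_events, " events: post - pre = ",
      format(x$difference, digits = 4), "\n", sep = "")
  invisible(x)
}
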