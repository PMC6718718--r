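#' Muscle activation level
#'
#' Normalizes a processed EMG value to the calibrated range: `MAL =
#' (EMG - Bias)/(MVE - Bias)`, clamped to `[0, 1]`.
#'
#' @param emg_value Filtered envelope value(s), signal units (vectorized).
#' @param calib A [calibration_result()].
#' @return MAL in `[0, 1]`.
#' @export
mal <- function(emg_value, calib) {
  stopifnot(inherits(calib, "calibration"))
  pmin(pmax((emg_value - calib$bias) / (calib$mve - calib$bias), 0), 1)
}

#' Mean muscle activation level over a block
#'
#' Arithmetic mean of the per-step MAL over the block's active time steps.
#'
#' @param mal_trace Numeric vector of MAL values (non-empty).
#' @return mMAL in `[0, 1]`.
#' @export
mmal <- function(mal_trace) {
  if (length(mal_trace) < 1L) stop("empty MAL trace")
  mean(mal_trace)
}

#' Block activation time from an event log
#'
#' Total time spent actively flying within a block, excluding hover time
#' between lives and anything outside the block: flight runs from the block
#' start (t = 0) or each `resume` event until the next `collision`, and to
#' the final `block_over`/`block_end` event if the log ends mid-flight.
#'
#' @param events A data.frame as from [events_df()], with at least `t` and
#'   `kind`; may also be a list of events.
#' @return Active play time, seconds.
#' @export
block_activation_time <- function(events) {
  if (is.list(events) && !is.data.frame(events)) events <- events_df(events)
  stopifnot(is.data.frame(events), all(c("t", "kind") %in% names(events)))
  bat <- 0
  flying <- TRUE
  t_start <- 0
  for (i in seq_len(nrow(events))) {
    t <- events$t[i]
    kind <- events$kind[i]
    if (kind == "collision") {
      if (!flying) stop("malformed log: collision while not flying")
      bat <- bat + (t - t_start)
      flying <- FALSE
    } else if (kind == "resume") {
      if (flying) stop("malformed log: resume while flying")
      t_start <- t
      flying <- TRUE
    } else if (kind %in% c("block_over", "block_end")) {
      if (flying) {
        bat <- bat + (t - t_start)
        flying <- FALSE
      }
    }
  }
  bat
}

#' Root-mean-square tracking error
#'
#' RMSE between the desired and actual joint-angle series.
#'
#' @param desired,actual Equal-length numeric vectors, degrees.
#' @return RMSE in degrees.
#' @export
rmse <- function(desired, actual) {
  if (length(desired) != length(actual)) stop("series lengths differ")
  if (length(desired) < 1L) stop("empty series")
  sqrt(mean((desired - actual)^2))
}

#' Cross-correlation time delay
#'
#' Lag maximizing the normalized cross-correlation of the mean-removed
#' series, searched over up to half the window; positive values mean the
#' second series lags the first.
#'
#' @param reference,delayed Equal-length numeric vectors, non-constant.
#' @param fs Sampling rate, Hz.
#' @param max_lag Maximum lag searched, samples (default: half the window).
#' @return Lag in milliseconds.
#' @export
xcorr_lag <- function(reference, delayed, fs, max_lag = NULL) {
  n <- length(reference)
  if (length(delayed) != n) stop("series lengths differ")
  stopifnot(fs > 0, n >= 2L)
  if (stats::sd(reference) == 0 || stats::sd(delayed) == 0) {
    stop("cross-correlation undefined for a constant series")
  }
  if (is.null(max_lag)) max_lag <- floor(n / 2)
  max_lag <- min(max_lag, n - 1L)
  cc <- stats::ccf(delayed, reference,
    lag.max = max_lag, plot = FALSE,
    demean = TRUE, type = "correlation"
  )
  lag_samples <- cc$lag[which.max(cc$acf)]
  1000 * lag_samples / fs
}

#' Spectral attenuation above a cutoff
#'
#' Periodogram-based noise-attenuation measure: `10 log10` of the ratio of
#' filtered to raw power summed over frequency bins above `f_cut` (up to
#' Nyquist). A filtered series with no power above the cutoff returns
#' `-Inf`.
#'
#' @param raw,filtered Equal-length numeric vectors, at least `2*fs`
#'   samples.
#' @param fs Sampling rate, Hz.
#' @param f_cut Cutoff frequency, Hz (must be below Nyquist).
#' @return Attenuation in dB (negative = the filter removed power).
#' @export
spectral_attenuation <- function(raw, filtered, fs, f_cut = 1) {
  n <- length(raw)
  if (length(filtered) != n) stop("series lengths differ")
  if (f_cut >= fs / 2) stop("f_cut must be below the Nyquist frequency")
  if (n < 2 * fs) stop("need at least 2 s of signal")
  freqs <- (seq_len(n) - 1) * fs / n
  band <- freqs > f_cut & freqs <= fs / 2
  p_raw <- sum(Mod(stats::fft(raw - mean(raw)))[band]^2)
  p_fil <- sum(Mod(stats::fft(filtered - mean(filtered)))[band]^2)
  if (p_raw == 0) stop("raw series has no power above the cutoff")
  if (p_fil == 0) {
    return(-Inf)
  }
  10 * log10(p_fil / p_raw)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal variances): between/within
#' mean-square F with (k-1, N-k) degrees of freedom and its upper-tail p.
#'
#' @param groups List of numeric vectors, >= 2 groups of >= 2 values each.
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs at least 2 values")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (stats::var(values) == 0) stop("degenerate input: all values identical")
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(
    F = unname(fit$statistic), p = unname(fit$p.value),
    df1 = unname(fit$parameter[1]), df2 = unname(fit$parameter[2])
  )
}
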