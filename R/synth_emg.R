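#' Activation profile
#'
#' A ground-truth muscle activation trace `a(t)` on `[0, 1]`, sampled at a
#' fixed rate. Activation profiles drive the synthetic EMG generator and
#' serve as the known truth against which calibration and muscle-activation
#' metrics are checked.
#'
#' @param values Numeric vector of activation levels, all in `[0, 1]`.
#' @param fs Sampling rate in Hz (> 0).
#' @return An object of class `activation_profile` with fields `values`,
#'   `fs` and `duration` (seconds).
#' @export
activation_profile <- function(values, fs) {
  stopifnot(is.numeric(values), length(values) >= 1L, is.finite(fs), fs > 0)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
    stop("activation values must be finite and in [0, 1]")
  }
  structure(
    list(values = as.numeric(values), fs = fs, duration = length(values) / fs),
    class = "activation_profile"
  )
}

#' @export
print.activation_profile <- function(x, ...) {
  cat(sprintf(
    "<activation_profile> %.3g s at %g Hz (%d samples), range [%.3g, %.3g]\n",
    x$duration, x$fs, length(x$values), min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Build a piecewise activation profile
#'
#' Constructs a piecewise-constant activation profile from a schedule of
#' `(start, end, level)` segments, with optional linear on/off ramps at the
#' segment edges; activation is 0 outside the scheduled segments.
#'
#' @param schedule List of length-3 numeric vectors `c(start_s, end_s, level)`.
#'   Segments must lie within `[0, duration]`, must not overlap, and levels
#'   must be in `[0, 1]`.
#' @param duration Total duration in seconds.
#' @param fs Sampling rate in Hz (default 200, the Myo armband rate).
#' @param ramp Linear ramp time in seconds applied inside each segment at its
#'   onset and offset (default 0: hard steps).
#' @return An [activation_profile()].
#' @examples
#' make_activation(list(c(5, 10, 1)), duration = 10, fs = 200)
#' @export
make_activation <- function(schedule, duration, fs = 200, ramp = 0) {
  stopifnot(is.list(schedule), duration > 0, fs > 0, ramp >= 0)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  a <- numeric(n)
  if (length(schedule)) {
    segs <- do.call(rbind, lapply(schedule, function(s) {
      stopifnot(is.numeric(s), length(s) == 3L)
      s
    }))
    if (any(segs[, 1] < 0) || any(segs[, 2] > duration) || any(segs[, 1] >= segs[, 2])) {
      stop("segments must satisfy 0 <= start < end <= duration")
    }
    if (any(segs[, 3] < 0) || any(segs[, 3] > 1)) {
      stop("segment levels must be in [0, 1]")
    }
    o <- order(segs[, 1])
    segs <- segs[o, , drop = FALSE]
    if (nrow(segs) > 1L && any(segs[-1L, 1] < segs[-nrow(segs), 2])) {
      stop("segments must not overlap")
    }
    for (i in seq_len(nrow(segs))) {
      s0 <- segs[i, 1]; s1 <- segs[i, 2]; lev <- segs[i, 3]
      inside <- t >= s0 & t < s1
      shape <- rep(1, sum(inside))
      if (ramp > 0) {
        ti <- t[inside]
        shape <- pmin(1, (ti - s0) / ramp, (s1 - ti) / ramp)
        shape <- pmax(shape, 0)
      }
      a[inside] <- lev * shape
    }
  }
  activation_profile(a, fs)
}

#' Maximal-effort calibration test pattern
#'
#' The activation profile used to determine the maximal-voluntary EMG: the
#' subject relaxes (a = 0), then performs a maximal isometric knee extension
#' (a = 1). Defaults follow the 5 s relax + 5 s contraction protocol.
#'
#' @param fs Sampling rate in Hz.
#' @param relax_s Relaxation duration in seconds (default 5).
#' @param contract_s Contraction duration in seconds (default 5).
#' @return An [activation_profile()] of duration `relax_s + contract_s`.
#' @export
mve_test_pattern <- function(fs = 200, relax_s = 5, contract_s = 5) {
  stopifnot(fs > 0, relax_s > 0, contract_s > 0)
  make_activation(
    list(c(relax_s, relax_s + contract_s, 1)),
    duration = relax_s + contract_s, fs = fs, ramp = 0
  )
}

#' Per-channel EMG envelope model
#'
#' Parameters of one synthetic channel: a resting baseline (`bias`), a linear
#' amplitude gain at full activation (`gain`) and additive Gaussian noise on
#' the rectified envelope (`noise_sd`), clamped at zero.
#'
#' @param bias Resting envelope level, signal units (>= 0).
#' @param gain Envelope increment at full activation, signal units (>= 0).
#' @param noise_sd Noise standard deviation, signal units (>= 0).
#' @param seed Optional integer seed for this channel's RNG stream.
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(bias = 1, gain = 4, noise_sd = 0.5, seed = NULL) {
  stopifnot(bias >= 0, gain >= 0, noise_sd >= 0)
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(
    list(bias = bias, gain = gain, noise_sd = noise_sd, seed = seed),
    class = "channel_model"
  )
}

#' Default 8-channel thigh-band model
#'
#' @param n_channels Number of channels (default 8).
#' @inheritParams channel_model
#' @return A list of [channel_model()] objects.
#' @export
default_channels <- function(n_channels = 8, bias = 1, gain = 4, noise_sd = 0.5) {
  stopifnot(n_channels >= 1)
  lapply(seq_len(n_channels), function(i) channel_model(bias, gain, noise_sd))
}

#' Multi-channel EMG trace
#'
#' Container for a rectangular multi-channel EMG time series: either the
#' `"raw"` thigh-band output (rectified, low-pass filtered, still noisy) or
#' a `"filtered"` Kalman envelope.
#'
#' @param samples Numeric matrix, time in rows and channels in columns; all
#'   values nonnegative.
#' @param fs Sampling rate in Hz (default 200).
#' @param kind `"raw"` or `"filtered"`.
#' @return An object of class `emg_trace`.
#' @export
emg_trace <- function(samples, fs = 200, kind = c("raw", "filtered")) {
  kind <- match.arg(kind)
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), nrow(samples) >= 1L, ncol(samples) >= 1L, fs > 0)
  if (any(!is.finite(samples))) stop("samples must be finite")
  if (any(samples < 0)) stop("samples must be nonnegative")
  colnames(samples) <- paste0("ch", seq_len(ncol(samples)))
  structure(list(samples = samples, fs = fs, kind = kind), class = "emg_trace")
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf(
    "<emg_trace:%s> %d channels x %d samples at %g Hz (%.3g s)\n",
    x$kind, ncol(x$samples), nrow(x$samples), x$fs, nrow(x$samples) / x$fs
  ))
  invisible(x)
}

#' @export
plot.emg_trace <- function(x, channels = seq_len(ncol(x$samples)), ...) {
  t <- (seq_len(nrow(x$samples)) - 1) / x$fs
  graphics::matplot(t, x$samples[, channels, drop = FALSE],
    type = "l", lty = 1, xlab = "time (s)",
    ylab = sprintf("EMG envelope (%s)", x$kind), ...
  )
  invisible(x)
}

#' Synthesize raw EMG from an activation profile
#'
#' Emulates the thigh-band's "raw" stream: for channel c at time t the sample
#' is `max(0, bias_c + gain_c * a(t) + noise)`, with Gaussian envelope noise
#' drawn from an independent per-channel stream. Deterministic given seeds.
#'
#' @param activation An [activation_profile()].
#' @param channels List of [channel_model()] objects (>= 1).
#' @param seed Optional master integer seed; channels without their own seed
#'   get an independent stream derived from it.
#' @return An [emg_trace()] with `kind = "raw"`.
#' @export
synthesize_raw_emg <- function(activation, channels, seed = NULL) {
  stopifnot(inherits(activation, "activation_profile"))
  if (!is.list(channels) || length(channels) < 1L) {
    stop("need at least one channel model")
  }
  n <- length(activation$values)
  if (n < 1L) stop("activation profile is empty")
  samples <- matrix(0, nrow = n, ncol = length(channels))
  for (ci in seq_along(channels)) {
    ch <- channels[[ci]]
    stopifnot(inherits(ch, "channel_model"))
    clean <- ch$bias + ch$gain * activation$values
    eps <- 0
    if (ch$noise_sd > 0) {
      ch_seed <- ch$seed
      if (is.null(ch_seed) && !is.null(seed)) {
        # independent stream per channel, derived from the master seed
        ch_seed <- (as.integer(seed) + 7919L * (ci - 1L)) %% .Machine$integer.max
      }
      if (!is.null(ch_seed)) set.seed(as.integer(ch_seed))
      eps <- stats::rnorm(n, 0, ch$noise_sd)
    }
    samples[, ci] <- pmax(0, clean + eps)
  }
  emg_trace(samples, fs = activation$fs, kind = "raw")
}

#' Write / read an EMG trace as CSV
#'
#' Plain-text interchange format: header `time_s,ch1,...,chK`, one row per
#' sample, '.' decimal separator.
#'
#' @param trace An [emg_trace()].
#' @param path File path.
#' @return `write_emg_csv` returns `path` invisibly; `read_emg_csv` returns
#'   an [emg_trace()].
#' @export
write_emg_csv <- function(trace, path) {
  stopifnot(inherits(trace, "emg_trace"))
  t <- (seq_len(nrow(trace$samples)) - 1) / trace$fs
  df <- data.frame(time_s = t, trace$samples, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @param kind Trace kind to stamp on the result (`"raw"` or `"filtered"`).
#' @export
read_emg_csv <- function(path, kind = "raw") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df) || ncol(df) < 2L) {
    stop("expected columns time_s, ch1, ...")
  }
  dt <- diff(df$time_s)
  if (length(dt) < 1L || any(dt <= 0)) stop("time_s must be strictly increasing")
  fs <- 1 / stats::median(dt)
  emg_trace(as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE]),
    fs = fs, kind = kind
  )
}
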