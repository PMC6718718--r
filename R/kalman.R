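#' Kalman filter parameters
#'
#' Constants of the scalar constant-signal Kalman filter used to extract the
#' EMG envelope. The underlying model treats the true envelope as locally
#' constant, so the prediction step carries the previous estimate forward and
#' only inflates its error by the process noise `Q`; the update step blends
#' in each new measurement with gain `KG = P/(P + R)`.
#'
#' Defaults are the values used for all subjects and channels in the study
#' this package simulates: `Q = 0.0001`, `R = 0.59948`.
#'
#' @param Q Process-noise variance (signal units squared, >= 0).
#' @param R Measurement-noise variance (signal units squared, >= 0).
#' @param X0 Initial estimate. `NULL` (default) means "seed at the first
#'   measurement of the series", which avoids a start-up transient from zero
#'   and is scale-free.
#' @param P0 Initial error variance. `NULL` (default) means `R`.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(Q = 1e-4, R = 0.59948, X0 = NULL, P0 = NULL) {
  stopifnot(is.finite(Q), is.finite(R), Q >= 0, R >= 0)
  if (!is.null(P0)) stopifnot(is.finite(P0), P0 >= 0)
  if (!is.null(X0)) stopifnot(is.finite(X0))
  if (Q == 0 && R == 0 && !is.null(P0) && P0 == 0) {
    stop("Q, R and P0 cannot all be zero")
  }
  structure(list(Q = Q, R = R, X0 = X0, P0 = P0), class = "filter_params")
}

#' One streaming Kalman update
#'
#' Advances the filter by one measurement: predict (`X_p = X_prev`,
#' `P_p = P_prev + Q`), gain (`KG = P_p/(P_p + R)`, defined as 1 at the
#' unreachable corner `P_p = R = 0`), update (`X = X_p + KG*(y - X_p)`,
#' `P = (1 - KG)*P_p`).
#'
#' @param state List with `X` (previous estimate) and `P` (previous error).
#' @param y Finite scalar measurement.
#' @param params A [filter_params()].
#' @return List with `state` (the new `(X, P)` pair), and scalars `X`, `P`,
#'   `KG`.
#' @export
kalman_step <- function(state, y, params) {
  stopifnot(inherits(params, "filter_params"), is.finite(state$X), state$P >= 0)
  if (!is.finite(y)) stop("measurement must be finite")
  Pp <- state$P + params$Q
  KG <- if (Pp == 0 && params$R == 0) 1 else Pp / (Pp + params$R)
  X <- state$X + KG * (y - state$X)
  P <- (1 - KG) * Pp
  list(state = list(X = X, P = P), X = X, P = P, KG = KG)
}

#' Run the Kalman filter over a series
#'
#' Iterates [kalman_step()] over a measurement series from the initial state
#' implied by `params` (`X0` = first measurement, `P0 = R` unless set).
#'
#' @param y Non-empty numeric vector of finite measurements.
#' @param params A [filter_params()].
#' @param full If `TRUE` return a list with `X`, `P` and `KG` vectors;
#'   otherwise (default) just the filtered series `X`.
#' @return Numeric vector of filtered values (or a list, see `full`).
#' @export
kalman_run <- function(y, params = filter_params(), full = FALSE) {
  stopifnot(inherits(params, "filter_params"))
  n <- length(y)
  if (n < 1L) stop("series is empty")
  if (any(!is.finite(y))) stop("series must be finite")
  Q <- params$Q; R <- params$R
  X <- if (is.null(params$X0)) y[1L] else params$X0
  P <- if (is.null(params$P0)) R else params$P0
  outX <- numeric(n); outP <- numeric(n); outK <- numeric(n)
  for (k in seq_len(n)) {
    Pp <- P + Q
    KG <- if (Pp == 0 && R == 0) 1 else Pp / (Pp + R)
    X <- X + KG * (y[k] - X)
    P <- (1 - KG) * Pp
    outX[k] <- X; outP[k] <- P; outK[k] <- KG
  }
  if (full) list(X = outX, P = outP, KG = outK) else outX
}

#' Filter every channel of an EMG trace
#'
#' Applies the scalar Kalman filter independently to each channel (the filter
#' is linear and time-invariant after covariance convergence, so per-channel
#' filtering followed by averaging equals averaging first; filtering first
#' matches the described control path).
#'
#' @param trace An [emg_trace()] with `kind = "raw"`.
#' @param params A [filter_params()].
#' @return An [emg_trace()] with `kind = "filtered"`.
#' @export
filter_emg <- function(trace, params = filter_params()) {
  stopifnot(inherits(trace, "emg_trace"))
  y <- trace$samples
  n <- nrow(y); nc <- ncol(y)
  Q <- params$Q; R <- params$R
  # the covariance recursion is measurement-independent, so P and KG are
  # shared across channels; the estimate update is vectorized over channels
  X <- if (is.null(params$X0)) y[1L, ] else rep(params$X0, nc)
  P <- if (is.null(params$P0)) R else params$P0
  out <- matrix(0, n, nc)
  for (k in seq_len(n)) {
    Pp <- P + Q
    KG <- if (Pp == 0 && R == 0) 1 else Pp / (Pp + R)
    X <- X + KG * (y[k, ] - X)
    P <- (1 - KG) * Pp
    out[k, ] <- X
  }
  # the filter is non-negativity preserving only approximately at start-up
  # transients with X0 > 0; clamp defensively (inputs are nonnegative)
  emg_trace(pmax(out, 0), fs = trace$fs, kind = "filtered")
}

#' Steady-state Kalman gain
#'
#' Closed-form fixed point of the covariance recursion: the predicted error
#' converges to `P_p* = (Q + sqrt(Q^2 + 4 Q R)) / 2` and the gain to
#' `KG* = P_p* / (P_p* + R)`. At steady state the filter is exactly the
#' exponential smoother `X_k = X_{k-1} + KG* (Y_k - X_{k-1})`.
#'
#' @inheritParams filter_params
#' @return Named list with `KG` (steady-state gain), `Pp` (predicted error
#'   fixed point) and `P` (updated error fixed point).
#' @export
steady_state_gain <- function(Q = 1e-4, R = 0.59948) {
  stopifnot(Q >= 0, R >= 0)
  if (Q == 0 && R == 0) stop("Q and R cannot both be zero")
  Pp <- (Q + sqrt(Q^2 + 4 * Q * R)) / 2
  KG <- if (Pp == 0 && R == 0) 1 else Pp / (Pp + R)
  list(KG = KG, Pp = Pp, P = (1 - KG) * Pp)
}

#' Magnitude response of the steady-state filter
#'
#' At steady state the filter is a single-pole exponential smoother with
#' transfer function `H(f) = g / (1 - (1-g) e^{-i 2 pi f / fs})`, `g` the
#' steady-state gain. Returns the magnitude response in dB.
#'
#' @param f Frequency (Hz), vectorized.
#' @param fs Sampling rate (Hz).
#' @inheritParams filter_params
#' @return Magnitude response in dB (0 at DC, negative above).
#' @export
kalman_response_db <- function(f, fs = 200, Q = 1e-4, R = 0.59948) {
  stopifnot(fs > 0, all(f >= 0), all(f <= fs / 2))
  g <- steady_state_gain(Q, R)$KG
  z <- exp(-1i * 2 * pi * f / fs)
  20 * log10(Mod(g / (1 - (1 - g) * z)))
}

#' Eight-channel mean control signal
#'
#' The exoskeleton control signal: the per-sample arithmetic mean over the
#' filtered channels covering the knee extensors.
#'
#' @param trace An [emg_trace()] with `kind = "filtered"`.
#' @return Numeric vector, one envelope value per sample.
#' @export
control_signal <- function(trace) {
  stopifnot(inherits(trace, "emg_trace"))
  if (trace$kind != "filtered") {
    stop("control signal is defined on the filtered trace; run filter_emg() first")
  }
  rowMeans(trace$samples)
}
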