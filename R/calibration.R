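#' Calibration protocol timings
#'
#' The maximal-effort calibration sequence: relax, then maximal isometric
#' knee extension with the exoskeleton locked; the maximal-voluntary EMG
#' (MVE) is the highest envelope level sustained for at least `hold_s`.
#'
#' @param relax_s Relaxation duration, seconds (default 5).
#' @param contract_s Contraction duration, seconds (default 5).
#' @param hold_s Minimum sustained duration defining the MVE, seconds
#'   (default 1; must not exceed `contract_s`).
#' @return An object of class `calibration_protocol`.
#' @export
calibration_protocol <- function(relax_s = 5, contract_s = 5, hold_s = 1) {
  stopifnot(relax_s > 0, contract_s > 0, hold_s > 0, hold_s <= contract_s)
  structure(
    list(relax_s = relax_s, contract_s = contract_s, hold_s = hold_s),
    class = "calibration_protocol"
  )
}

#' Calibration result
#'
#' Per-leg anchors of the EMG-to-effort normalization: the resting envelope
#' level (`bias`), the maximal-voluntary EMG (`mve`) and the effort cap used
#' during training (default 0.6: only 60% of the maximal activity is applied,
#' to avoid fatigue).
#'
#' @param bias Resting envelope level, signal units.
#' @param mve Maximal-voluntary EMG, signal units (> `bias`).
#' @param effort_cap Fraction of the bias-to-MVE range used in training,
#'   in (0, 1] (default 0.6).
#' @return An object of class `calibration`.
#' @export
calibration_result <- function(bias, mve, effort_cap = 0.6) {
  stopifnot(is.finite(bias), is.finite(mve), is.finite(effort_cap))
  if (mve <= bias) stop("mve must exceed bias")
  if (effort_cap <= 0 || effort_cap > 1) stop("effort_cap must be in (0, 1]")
  structure(
    list(bias = bias, mve = mve, effort_cap = effort_cap),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration> bias = %.4g, MVE = %.4g, effort cap = %g%%\n",
    x$bias, x$mve, 100 * x$effort_cap
  ))
  invisible(x)
}

.window_idx <- function(window, fs, n) {
  stopifnot(length(window) == 2L, window[1] >= 0, window[2] > window[1])
  i0 <- floor(window[1] * fs) + 1L
  i1 <- round(window[2] * fs)
  if (i0 < 1L || i1 > n || i1 < i0) stop("window outside signal")
  i0:i1
}

#' Estimate the resting bias
#'
#' Mean of the filtered envelope over the relaxation window.
#'
#' @param envelope Numeric vector, single-channel filtered envelope.
#' @param relax_window Length-2 numeric `(start_s, end_s)` inside the signal;
#'   at least 1 s long.
#' @param fs Sampling rate, Hz.
#' @return The bias, signal units.
#' @export
estimate_bias <- function(envelope, relax_window, fs) {
  stopifnot(is.numeric(envelope), fs > 0)
  if (diff(relax_window) < 1) stop("relax window must be at least 1 s")
  mean(envelope[.window_idx(relax_window, fs, length(envelope))])
}

#' Estimate the maximal-voluntary EMG
#'
#' The highest envelope level sustained for `hold` seconds within the
#' contraction window, operationalized as the maximum over all sliding
#' sub-windows of length `hold` of the minimum envelope inside the
#' sub-window.
#'
#' @inheritParams estimate_bias
#' @param contract_window Length-2 numeric `(start_s, end_s)`; at least
#'   `hold` seconds long.
#' @param hold Sustained duration in seconds (default 1).
#' @return The MVE, signal units.
#' @export
estimate_mve <- function(envelope, contract_window, fs, hold = 1) {
  stopifnot(is.numeric(envelope), fs > 0, hold > 0)
  idx <- .window_idx(contract_window, fs, length(envelope))
  x <- envelope[idx]
  w <- max(1L, round(hold * fs))
  if (w > length(x)) stop("contraction window shorter than the hold duration")
  n_sub <- length(x) - w + 1L
  mins <- vapply(
    seq_len(n_sub),
    function(i) min(x[i:(i + w - 1L)]),
    numeric(1)
  )
  max(mins)
}

#' Calibrate the EMG-to-effort normalization
#'
#' Runs bias and MVE estimation on a filtered envelope covering the
#' relax-then-contract protocol and validates that a usable voluntary signal
#' range exists: calibration fails with an "insufficient signal range" error
#' when `mve - bias` is non-positive or smaller than 3 resting standard
#' deviations (the safety case of a subject who cannot yet produce a
#' voluntary signal above rest).
#'
#' @param envelope Numeric vector, the 8-channel-mean filtered envelope
#'   covering at least `relax_s + contract_s` seconds.
#' @param protocol A [calibration_protocol()].
#' @param fs Sampling rate, Hz.
#' @param effort_cap Training effort cap, fraction (default 0.6).
#' @return A [calibration_result()].
#' @export
calibrate <- function(envelope, protocol = calibration_protocol(), fs = 200,
                      effort_cap = 0.6) {
  stopifnot(inherits(protocol, "calibration_protocol"), fs > 0)
  need <- round((protocol$relax_s + protocol$contract_s) * fs)
  if (length(envelope) < need) {
    stop("envelope shorter than the calibration protocol")
  }
  relax_win <- c(0, protocol$relax_s)
  contract_win <- c(protocol$relax_s, protocol$relax_s + protocol$contract_s)
  bias <- estimate_bias(envelope, relax_win, fs)
  rest_sd <- stats::sd(envelope[.window_idx(relax_win, fs, length(envelope))])
  mve <- estimate_mve(envelope, contract_win, fs, hold = protocol$hold_s)
  if (mve - bias <= 0 || mve - bias < 3 * rest_sd) {
    stop("insufficient signal range: no usable voluntary EMG above rest")
  }
  calibration_result(bias, mve, effort_cap)
}
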