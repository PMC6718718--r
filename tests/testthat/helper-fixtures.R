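# Shared fixtures and independent oracles used across test files.

# A clean calibration without running the estimation pipeline.
fixture_calibration <- function(bias = 1, mve = 5, effort_cap = 0.6) {
  calibration_result(bias, mve, effort_cap)
}

# Independent literal transcription of the scalar filter recursion
# (prediction, gain, update, state carry-over), kept deliberately separate
# from the package implementation: the oracle for kalman_run().
kalman_transcription <- function(y, Q, R, X0, P0) {
  n <- length(y)
  X <- numeric(n)
  P <- numeric(n)
  KG <- numeric(n)
  X_prev <- X0
  P_prev <- P0
  for (k in seq_len(n)) {
    X_kp <- X_prev # prediction of the state
    P_kp <- P_prev + Q # prediction of its error
    KG[k] <- P_kp / (P_kp + R) # gain
    X[k] <- X_kp + KG[k] * (y[k] - X_kp) # update
    P[k] <- (1 - KG[k]) * P_kp # updated error
    X_prev <- X[k] # current state becomes previous
    P_prev <- P[k]
  }
  list(X = X, P = P, KG = KG)
}

# Brute-force sliding-window sustained-minimum oracle for estimate_mve().
sustained_min_oracle <- function(x, w) {
  max(vapply(
    seq_len(length(x) - w + 1L),
    function(i) min(x[i:(i + w - 1L)]),
    numeric(1)
  ))
}

# Brute-force normalized cross-correlation argmax oracle for xcorr_lag().
xcorr_oracle_ms <- function(reference, delayed, fs, max_lag) {
  r0 <- reference - mean(reference)
  d0 <- delayed - mean(delayed)
  n <- length(r0)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(r0[seq_len(n - k)] * d0[seq_len(n - k) + k])
    else sum(r0[seq_len(n + k) - k] * d0[seq_len(n + k)])
  }, numeric(1))
  1000 * lags[which.max(cc)] / fs
}

# A noisy burst trace: rest / contraction bursts, the shape used for the
# filter-delay analyses.
burst_trace <- function(seed, noise_sd = 0.5, n_bursts = 3, duration = 30,
                        fs = 200, level = 1) {
  seg_len <- duration / (2 * n_bursts)
  sched <- lapply(seq_len(n_bursts), function(i) {
    s <- (2 * i - 1) * seg_len
    c(s, s + seg_len, level)
  })
  act <- make_activation(sched, duration = duration, fs = fs, ramp = 0)
  synthesize_raw_emg(act, list(channel_model(
    bias = 1, gain = 4,
    noise_sd = noise_sd
  )), seed = seed)
}

# Scripted perfect player: bird altitude centered in the next upcoming gap.
perfect_bird_input <- function(game, config) {
  bx <- config$bird_station_frac * config$screen_w
  ahead <- Filter(
    function(p) !p$scored && p$x + config$pipe_width >= bx,
    game$pipes
  )
  if (!length(ahead)) {
    return(config$screen_h / 2 - config$bird_size / 2)
  }
  xs <- vapply(ahead, `[[`, numeric(1), "x")
  ahead[[which.min(xs)]]$gap_center - config$bird_size / 2
}
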