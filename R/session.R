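#' Virtual subject parameters
#'
#' A configurable stand-in for the human player, closing the loop without
#' hardware or human data. The subject aims the bird at the center of the
#' next pipe gap, pursued with a first-order lag (`pursuit_tc`) after a
#' visuomotor `reaction_delay`, and commands its muscles with multiplicative
#' activation noise that wanders slowly (an Ornstein-Uhlenbeck process with
#' time constant `noise_tc`), so control errors persist long enough to cause
#' occasional pipe collisions - the mechanism that ends bird lives.
#'
#' Defaults emulate an attentive healthy player: ~150 ms reaction delay,
#' 200 ms pursuit lag and 15% slow-wandering activation noise, chosen so
#' that default blocks end by exhausting the four lives with scores in the
#' tens, the regime reported for healthy novices on this task.
#'
#' @param reaction_delay Visuomotor reaction delay, seconds (>= 0).
#' @param pursuit_tc First-order pursuit time constant, seconds (`Inf`
#'   freezes the activation).
#' @param activation_noise_sd Stationary SD of the multiplicative activation
#'   noise, fraction (>= 0).
#' @param noise_tc Correlation time of the activation noise, seconds.
#' @param noise_decay Per-block multiplicative decay of the noise SD (0 =
#'   no learning, the default; e.g. 0.05 shrinks the noise 5% per block).
#' @param channels List of [channel_model()] objects (default: the 8-channel
#'   thigh-band preset).
#' @return An object of class `virtual_subject`.
#' @export
virtual_subject <- function(reaction_delay = 0.15, pursuit_tc = 0.2,
                            activation_noise_sd = 0.15, noise_tc = 0.5,
                            noise_decay = 0, channels = default_channels()) {
  stopifnot(
    reaction_delay >= 0, pursuit_tc > 0, activation_noise_sd >= 0,
    noise_tc > 0, noise_decay >= 0, noise_decay < 1, length(channels) >= 1
  )
  structure(
    list(
      reaction_delay = reaction_delay, pursuit_tc = pursuit_tc,
      activation_noise_sd = activation_noise_sd, noise_tc = noise_tc,
      noise_decay = noise_decay, channels = channels
    ),
    class = "virtual_subject"
  )
}

#' Target activation implied by the game state
#'
#' Inverts the display and control maps: the activation fraction (of the
#' full bias-to-MVE range) that would center the bird in the next upcoming
#' pipe gap. With no pipe ahead the target is mid-screen.
#'
#' @param game A `game_state`.
#' @param config A [game_config()].
#' @param map A [mapping_config()].
#' @return Target activation fraction in `[0, 1]`.
#' @export
subject_target_activation <- function(game, config = game_config(),
                                      map = mapping_config()) {
  bx <- config$bird_station_frac * config$screen_w
  ahead <- Filter(function(p) !p$scored && p$x + config$pipe_width >= bx, game$pipes)
  gap_center <- if (length(ahead)) {
    xs <- vapply(ahead, `[[`, numeric(1), "x")
    ahead[[which.min(xs)]]$gap_center
  } else {
    config$screen_h / 2
  }
  bird_y_target <- gap_center - config$bird_size / 2
  bird_y_target <- min(max(bird_y_target, 0), config$screen_h - config$bird_size)
  theta_target <- bird_y_target / (config$screen_h - config$bird_size) * config$max_angle
  theta_target / (map$full_range_angle - map$min_angle)
}

#' One virtual-subject decision step
#'
#' Advances the subject's internal state by one game tick: the current gap
#' target enters a delay line of length `reaction_delay`, the delayed target
#' is pursued with a first-order lag, and multiplicative
#' Ornstein-Uhlenbeck noise perturbs the commanded activation. Draws from
#' the session RNG stream.
#'
#' @param sub_state Internal state as returned by this function, or `NULL`
#'   to start at rest.
#' @param game A `game_state`.
#' @param subject A [virtual_subject()].
#' @param config A [game_config()].
#' @param map A [mapping_config()].
#' @param dt Tick duration, seconds.
#' @param noise_scale Multiplier on the subject's noise SD (used for
#'   block-to-block learning; default 1).
#' @return List with `state` (to pass back next tick) and `activation`, the
#'   commanded activation fraction in `[0, 1]`.
#' @export
subject_policy <- function(sub_state, game, subject, config = game_config(),
                           map = mapping_config(), dt = 1 / 50,
                           noise_scale = 1) {
  stopifnot(inherits(subject, "virtual_subject"), dt > 0)
  n_delay <- round(subject$reaction_delay / dt)
  if (is.null(sub_state)) {
    sub_state <- list(a = 0, eta = 0, buffer = rep(0, max(n_delay, 0)))
  }
  target <- subject_target_activation(game, config, map)
  if (n_delay > 0) {
    sub_state$buffer <- c(sub_state$buffer, target)
    delayed <- sub_state$buffer[1L]
    sub_state$buffer <- sub_state$buffer[-1L]
  } else {
    delayed <- target
  }
  if (is.finite(subject$pursuit_tc)) {
    sub_state$a <- sub_state$a +
      (dt / subject$pursuit_tc) * (delayed - sub_state$a)
  }
  sd_eff <- subject$activation_noise_sd * noise_scale
  if (sd_eff > 0) {
    rho <- exp(-dt / subject$noise_tc)
    sub_state$eta <- rho * sub_state$eta +
      stats::rnorm(1, 0, sd_eff * sqrt(1 - rho^2))
  }
  activation <- min(max(sub_state$a * (1 + sub_state$eta), 0), 1)
  list(state = sub_state, activation = activation)
}

#' Session configuration
#'
#' The full experimental protocol: per leg, a maximal-effort calibration
#' followed by `blocks_per_leg` game blocks of `lives_per_block` lives, with
#' fixed rests between blocks; then the other leg.
#'
#' @param blocks_per_leg Blocks per leg (default 10).
#' @param lives_per_block Bird lives per block (default 4).
#' @param rest_between_blocks Interblock rest, seconds (default 30).
#' @param leg_order `"left-first"` or `"right-first"`.
#' @param hover_duration Hover pause before the automatic resume that
#'   replaces the human space-key press, seconds (default 1).
#' @param max_block_duration Guard on a single block's wall time, seconds
#'   (default 300; blocks normally end earlier by exhausting the lives).
#' @param control_fs EMG/control rate, Hz (default 200).
#' @param game A [game_config()] (its `lives_per_block` is overridden).
#' @param filter A [filter_params()].
#' @param protocol A [calibration_protocol()].
#' @param effort_cap Training effort cap (default 0.6).
#' @param gains A [controller_gains()].
#' @param plant A [plant_config()].
#' @param map A [mapping_config()].
#' @return An object of class `session_config`.
#' @export
session_config <- function(blocks_per_leg = 10, lives_per_block = 4,
                           rest_between_blocks = 30,
                           leg_order = c("left-first", "right-first"),
                           hover_duration = 1, max_block_duration = 300,
                           control_fs = 200, game = game_config(),
                           filter = filter_params(),
                           protocol = calibration_protocol(),
                           effort_cap = 0.6, gains = controller_gains(),
                           plant = plant_config(), map = mapping_config()) {
  leg_order <- match.arg(leg_order)
  stopifnot(
    blocks_per_leg >= 1, lives_per_block >= 1, rest_between_blocks >= 0,
    hover_duration >= 0, max_block_duration > 0, control_fs > 0
  )
  game$lives_per_block <- lives_per_block
  if (abs(plant$dt - 1 / control_fs) > 1e-9) {
    stop("plant dt must match the control rate")
  }
  if (control_fs %% game$tick_rate != 0) {
    stop("control rate must be an integer multiple of the game tick rate")
  }
  structure(
    list(
      blocks_per_leg = blocks_per_leg, lives_per_block = lives_per_block,
      rest_between_blocks = rest_between_blocks, leg_order = leg_order,
      hover_duration = hover_duration,
      max_block_duration = max_block_duration, control_fs = control_fs,
      game = game, filter = filter, protocol = protocol,
      effort_cap = effort_cap, gains = gains, plant = plant, map = map
    ),
    class = "session_config"
  )
}

#' Run one training block in closed loop
#'
#' Closes the full loop at matched rates: virtual subject (50 Hz game
#' ticks) -> synthetic 8-channel EMG -> streaming Kalman filter ->
#' calibrated proportional map -> PD/PID servo and plant (200 Hz) -> bird
#' altitude -> game. Lives lost hover for `hover_duration` and then
#' auto-resume; the block ends when all lives are exhausted (or at the
#' `max_duration` guard, emitting `block_end`).
#'
#' @param calib A [calibration_result()].
#' @param subject A [virtual_subject()].
#' @param config A [session_config()] (supplies game, filter, controller and
#'   plant settings).
#' @param seed Integer seed for this block's RNG stream.
#' @param noise_scale Multiplier on the subject's activation noise (for
#'   block-to-block learning).
#' @param keep_traces Keep the full per-sample traces in the result
#'   (default `TRUE`; sessions drop them to stay light).
#' @return List with `metrics` (score, mmal, bat_s, rmse_deg, lag_ms,
#'   lives_used, duration_s), `events` (data.frame) and, if kept, `traces`
#'   (time, envelope, theta_d, theta_a, active flag).
#' @export
run_block <- function(calib, subject, config = session_config(), seed = NULL,
                      noise_scale = 1, keep_traces = TRUE) {
  stopifnot(
    inherits(calib, "calibration"), inherits(subject, "virtual_subject"),
    inherits(config, "session_config")
  )
  if (!is.null(seed)) set.seed(as.integer(seed))
  gcfg <- config$game
  steps_per_tick <- config$control_fs / gcfg$tick_rate
  dt_tick <- 1 / gcfg$tick_rate
  dt_ctrl <- 1 / config$control_fs

  nch <- length(subject$channels)
  ch_bias <- vapply(subject$channels, `[[`, numeric(1), "bias")
  ch_gain <- vapply(subject$channels, `[[`, numeric(1), "gain")
  ch_sd <- vapply(subject$channels, `[[`, numeric(1), "noise_sd")

  # streaming filter state (covariance shared across channels)
  Q <- config$filter$Q; R <- config$filter$R
  X <- rep(if (is.null(config$filter$X0)) calib$bias else config$filter$X0, nch)
  P <- if (is.null(config$filter$P0)) R else config$filter$P0

  sv <- .servo_init(joint_state(theta = 0))
  game <- .ensure_lookahead(new_game(gcfg), gcfg)
  sub_state <- NULL
  activation <- 0
  hover_until <- NA_real_
  events <- list()

  n_max <- ceiling(config$max_block_duration * config$control_fs) +
    steps_per_tick
  tr_env <- numeric(n_max); tr_d <- numeric(n_max); tr_a <- numeric(n_max)
  tr_active <- logical(n_max)
  i <- 0L

  repeat {
    flying <- game$phase == "flying"
    if (flying) {
      pol <- subject_policy(sub_state, game, subject, gcfg, config$map,
        dt = dt_tick, noise_scale = noise_scale
      )
      sub_state <- pol$state
      activation <- pol$activation
    }
    # control substeps: synth EMG -> Kalman -> proportional map -> servo
    eff_lo <- calib$bias
    eff_span <- calib$mve - calib$bias
    ang_span <- config$map$full_range_angle - config$map$min_angle
    noise <- if (any(ch_sd > 0)) {
      matrix(stats::rnorm(steps_per_tick * nch, 0, 1), steps_per_tick, nch,
        byrow = TRUE
      ) * rep(ch_sd, each = steps_per_tick)
    } else {
      matrix(0, steps_per_tick, nch)
    }
    clean <- ch_bias + ch_gain * activation
    for (s in seq_len(steps_per_tick)) {
      y <- clean + noise[s, ]
      y[y < 0] <- 0
      Pp <- P + Q
      KG <- Pp / (Pp + R)
      X <- X + KG * (y - X)
      P <- (1 - KG) * Pp
      env <- mean(X)
      effort <- (env - eff_lo) / eff_span
      if (effort < 0) effort <- 0 else if (effort > calib$effort_cap) effort <- calib$effort_cap
      theta_d <- config$map$min_angle + ang_span * effort
      sv <- .servo_advance(sv, theta_d, config$gains, config$plant)
      i <- i + 1L
      tr_env[i] <- env; tr_d[i] <- theta_d; tr_a[i] <- sv$theta
      tr_active[i] <- flying
    }
    tick <- game_tick(game, angle_to_bird_y(sv$theta, gcfg),
      dt = dt_tick, config = gcfg
    )
    game <- tick$state
    events <- c(events, tick$events)
    if (game$phase == "hover" && is.na(hover_until)) {
      hover_until <- game$t + config$hover_duration
    }
    if (game$phase == "hover" && !is.na(hover_until) &&
      game$t >= hover_until - 1e-9) {
      game <- resume(game, gcfg)
      events[[length(events) + 1L]] <- .event(game$t, "resume", game$lives_left)
      hover_until <- NA_real_
    }
    if (game$phase == "over") break
    if (game$t >= config$max_block_duration - 1e-9) {
      events[[length(events) + 1L]] <- .event(game$t, "block_end", game$score)
      break
    }
  }

  idx <- seq_len(i)
  tr_env <- tr_env[idx]; tr_d <- tr_d[idx]; tr_a <- tr_a[idx]
  tr_active <- tr_active[idx]
  mal_trace <- mal(tr_env[tr_active], calib)
  lag_ms <- tryCatch(
    xcorr_lag(tr_d, tr_a,
      fs = config$control_fs,
      max_lag = round(2 * config$control_fs)
    ),
    error = function(e) NA_real_
  )
  metrics <- list(
    score = game$score,
    mmal = if (length(mal_trace)) mmal(mal_trace) else NA_real_,
    bat_s = game$elapsed_active,
    rmse_deg = rmse(tr_d, tr_a),
    lag_ms = lag_ms,
    lives_used = gcfg$lives_per_block - game$lives_left,
    duration_s = game$t
  )
  out <- list(metrics = metrics, events = events_df(events))
  if (keep_traces) {
    out$traces <- data.frame(
      time_s = (idx - 1) * dt_ctrl, envelope = tr_env,
      theta_d = tr_d, theta_a = tr_a, active = tr_active
    )
  }
  out
}

#' Calibrate one leg from a simulated maximal-effort test
#'
#' Synthesizes the relax-then-contract protocol with the subject's channel
#' models, filters it, averages the channels and calibrates.
#'
#' @inheritParams run_block
#' @return A [calibration_result()] (errors propagate, e.g. "insufficient
#'   signal range" for a subject with no usable voluntary signal).
#' @export
calibrate_leg <- function(subject, config = session_config(), seed = NULL) {
  stopifnot(inherits(subject, "virtual_subject"))
  pattern <- mve_test_pattern(
    fs = config$control_fs,
    relax_s = config$protocol$relax_s,
    contract_s = config$protocol$contract_s
  )
  raw <- synthesize_raw_emg(pattern, subject$channels, seed = seed)
  env <- control_signal(filter_emg(raw, config$filter))
  calibrate(env, config$protocol,
    fs = config$control_fs,
    effort_cap = config$effort_cap
  )
}

#' Run a full two-leg training session
#'
#' Per leg (in the configured order): maximal-effort calibration, then
#' `blocks_per_leg` game blocks separated by the interblock rest. All
#' randomness derives from the single master seed, so an identical
#' `(config, subject, seed)` triple reproduces the session log exactly.
#' A calibration failure aborts that leg with a structured error record.
#'
#' @param config A [session_config()].
#' @param subject A [virtual_subject()] used for both legs, unless
#'   `subject_right` is given.
#' @param seed Master integer seed.
#' @param subject_right Optional distinct [virtual_subject()] for the right
#'   leg.
#' @return An object of class `session_log`: per-leg calibration and block
#'   records, session timeline and total score.
#' @export
run_session <- function(config = session_config(), subject = virtual_subject(),
                        seed = 1, subject_right = NULL) {
  stopifnot(inherits(config, "session_config"))
  legs <- if (config$leg_order == "left-first") c("left", "right") else c("right", "left")
  subjects <- list(left = subject, right = if (is.null(subject_right)) subject else subject_right)
  log <- list(
    seed = as.integer(seed),
    leg_order = config$leg_order,
    blocks_per_leg = config$blocks_per_leg,
    lives_per_block = config$lives_per_block,
    rest_between_blocks = config$rest_between_blocks,
    legs = list()
  )
  t_session <- 0
  for (li in seq_along(legs)) {
    leg <- legs[li]
    leg_seed <- as.integer(seed) + 104729L * li
    sub <- subjects[[leg]]
    leg_rec <- list(leg = leg, calibration = NULL, error = NULL, blocks = list())
    calib <- tryCatch(
      calibrate_leg(sub, config, seed = leg_seed),
      error = function(e) e
    )
    if (inherits(calib, "error")) {
      leg_rec$error <- conditionMessage(calib)
      log$legs[[leg]] <- leg_rec
      next
    }
    leg_rec$calibration <- unclass(calib)
    t_session <- t_session +
      config$protocol$relax_s + config$protocol$contract_s
    for (b in seq_len(config$blocks_per_leg)) {
      noise_scale <- (1 - sub$noise_decay)^(b - 1)
      blk <- run_block(calib, sub, config,
        seed = leg_seed + b,
        noise_scale = noise_scale, keep_traces = FALSE
      )
      blk$block <- b
      blk$t_start_s <- t_session
      t_session <- t_session + blk$metrics$duration_s
      if (b < config$blocks_per_leg) {
        t_session <- t_session + config$rest_between_blocks
      }
      leg_rec$blocks[[b]] <- blk
    }
    log$legs[[leg]] <- leg_rec
  }
  log$duration_s <- t_session
  log$total_score <- session_total_score(log)
  structure(log, class = "session_log")
}

#' Total score of a session log
#'
#' @param log A `session_log` (or the underlying list).
#' @return Sum of per-block scores over both legs.
#' @export
session_total_score <- function(log) {
  sum(unlist(lapply(log$legs, function(leg) {
    vapply(leg$blocks, function(b) b$metrics$score, numeric(1))
  })), 0)
}

#' Per-block metrics of a session as a data.frame
#'
#' @param log A `session_log`.
#' @return A data.frame with one row per block: leg, block index, score,
#'   mMAL, block activation time, tracking RMSE, lag, lives used.
#' @export
session_metrics <- function(log) {
  rows <- list()
  for (leg in names(log$legs)) {
    for (b in log$legs[[leg]]$blocks) {
      m <- b$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        leg = leg, block = b$block, score = m$score, mmal = m$mmal,
        bat_s = m$bat_s, rmse_deg = m$rmse_deg, lag_ms = m$lag_ms,
        lives_used = m$lives_used, duration_s = m$duration_s,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf(
    "<session_log> seed %d, %s, %d blocks/leg, total score %d\n",
    x$seed, x$leg_order, x$blocks_per_leg, as.integer(x$total_score)
  ))
  for (leg in names(x$legs)) {
    lr <- x$legs[[leg]]
    if (!is.null(lr$error)) {
      cat(sprintf("  %s leg: calibration failed (%s)\n", leg, lr$error))
    } else {
      sc <- vapply(lr$blocks, function(b) b$metrics$score, numeric(1))
      cat(sprintf(
        "  %s leg: bias %.3f, MVE %.3f; block scores: %s\n",
        leg, lr$calibration$bias, lr$calibration$mve,
        paste(sc, collapse = " ")
      ))
    }
  }
  invisible(x)
}

#' Serialize a session log to JSON
#'
#' Stable JSON rendering of a session log (events as per-block tables,
#' numbers at full precision), suitable for archiving a session or for
#' byte-level reproducibility checks.
#'
#' @param log A `session_log`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
session_to_json <- function(log, path = NULL) {
  js <- jsonlite::toJSON(unclass(log),
    dataframe = "columns", digits = NA,
    auto_unbox = TRUE, null = "null"
  )
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
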