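#' Training-game configuration
#'
#' Geometry and rules of the headless Flappy Bird trainer. The printed study
#' constants are the defaults: 48 px bird, pipe gap shrinking from 300 px to
#' 190 px, horizontal speed growing to 2.5x, difficulty frozen once the
#' score passes 100, four bird lives per block. Screen size, pipe width and
#' spacing, base speed and tick rate are unpublished and isolated here.
#'
#' @param screen_w,screen_h Screen size, px.
#' @param bird_size Bird bounding-box side, px (default 48).
#' @param gap_start,gap_end Pipe gap at score 0 and at the difficulty cap,
#'   px (defaults 300 and 190).
#' @param speed_mult_end Horizontal speed multiplier at the cap (default 2.5).
#' @param difficulty_cap_score Score at which difficulty stops changing
#'   (default 100).
#' @param base_speed Horizontal pipe speed at score 0, px/s.
#' @param pipe_width Pipe width, px.
#' @param pipe_spacing Horizontal distance between consecutive pipe pairs, px.
#' @param lives_per_block Bird lives per block (default 4).
#' @param vertical_margin Minimum clearance between a gap edge and the
#'   screen edge, px.
#' @param tick_rate Game tick rate, Hz (default 50).
#' @param bird_station_frac Horizontal bird station as a fraction of screen
#'   width (default 0.2).
#' @param grace_distance Pipe-free distance ahead of the bird after a resume,
#'   px (default: one pipe spacing).
#' @param max_angle Knee angle mapped to the top of the screen, degrees
#'   (default 54: the effort-capped range).
#' @return An object of class `game_config`.
#' @export
game_config <- function(screen_w = 480, screen_h = 800, bird_size = 48,
                        gap_start = 300, gap_end = 190, speed_mult_end = 2.5,
                        difficulty_cap_score = 100, base_speed = 120,
                        pipe_width = 80, pipe_spacing = 320,
                        lives_per_block = 4, vertical_margin = 60,
                        tick_rate = 50, bird_station_frac = 0.2,
                        grace_distance = pipe_spacing, max_angle = 54) {
  stopifnot(
    gap_end < gap_start, bird_size < gap_end,
    gap_start + 2 * vertical_margin <= screen_h,
    lives_per_block >= 1, difficulty_cap_score > 0,
    base_speed > 0, pipe_width > 0, pipe_spacing > 0,
    tick_rate > 0, speed_mult_end >= 1, max_angle > 0,
    bird_station_frac > 0, bird_station_frac < 1
  )
  structure(
    list(
      screen_w = screen_w, screen_h = screen_h, bird_size = bird_size,
      gap_start = gap_start, gap_end = gap_end,
      speed_mult_end = speed_mult_end,
      difficulty_cap_score = difficulty_cap_score,
      base_speed = base_speed, pipe_width = pipe_width,
      pipe_spacing = pipe_spacing, lives_per_block = lives_per_block,
      vertical_margin = vertical_margin, tick_rate = tick_rate,
      bird_station_frac = bird_station_frac,
      grace_distance = grace_distance, max_angle = max_angle
    ),
    class = "game_config"
  )
}

#' Adaptive difficulty schedule
#'
#' Linear interpolation of the two difficulty dials in the score, between
#' the printed endpoints: gap 300 px and speed 1x at score 0, gap 190 px and
#' speed 2.5x at score 100; both constant once the score passes the cap.
#'
#' @param score Current score, points (>= 0, vectorized).
#' @param config A [game_config()].
#' @return List with `speed_multiplier` and `gap_px`.
#' @export
difficulty <- function(score, config = game_config()) {
  if (any(score < 0)) stop("score must be nonnegative")
  frac <- pmin(score, config$difficulty_cap_score) / config$difficulty_cap_score
  list(
    speed_multiplier = 1 + (config$speed_mult_end - 1) * frac,
    gap_px = config$gap_start - (config$gap_start - config$gap_end) * frac
  )
}

#' Map the knee angle to the bird altitude
#'
#' The bird's vertical position is proportional to the actual knee angle:
#' 0 deg puts the bird at the bottom of the screen and `max_angle` (54 deg
#' at defaults) at the top. `bird_y` is the bottom edge of the bird's box,
#' measured upward from the screen bottom.
#'
#' @param theta Knee angle, degrees (clamped to `[0, max_angle]`).
#' @param config A [game_config()].
#' @return Bird altitude, px in `[0, screen_h - bird_size]`.
#' @export
angle_to_bird_y <- function(theta, config = game_config()) {
  theta <- pmin(pmax(theta, 0), config$max_angle)
  (theta / config$max_angle) * (config$screen_h - config$bird_size)
}

#' Spawn a pipe pair
#'
#' Gap size follows the current difficulty; the gap center is uniform over
#' the feasible band left by the vertical margins (degenerate band: forced
#' to mid-screen). The pair is placed one pipe spacing beyond the current
#' rightmost pipe (or at the right screen edge if the field is empty).
#' Draws from the session RNG stream: seed the caller for reproducibility.
#'
#' @param config A [game_config()].
#' @param score Current score (sets the gap via [difficulty()]).
#' @param rightmost_x Leading-edge x of the rightmost pipe, or `NULL`.
#' @return A list with `x`, `gap_center`, `gap_size`, `scored`.
#' @export
spawn_pipe <- function(config = game_config(), score = 0, rightmost_x = NULL) {
  gap <- difficulty(score, config)$gap_px
  lo <- config$vertical_margin + gap / 2
  hi <- config$screen_h - config$vertical_margin - gap / 2
  if (hi < lo) stop("no feasible gap position: gap too large for the screen")
  center <- if (hi == lo) lo else stats::runif(1, lo, hi)
  x <- if (is.null(rightmost_x)) config$screen_w else rightmost_x + config$pipe_spacing
  list(x = x, gap_center = center, gap_size = gap, scored = FALSE)
}

#' New game state
#'
#' @param config A [game_config()].
#' @return An object of class `game_state`: phase (`flying`, `hover`,
#'   `over`), bird altitude, score, lives left, active pipes, wall-clock
#'   time `t` and active (flying) time `elapsed_active`.
#' @export
new_game <- function(config = game_config()) {
  structure(
    list(
      phase = "flying", bird_y = 0, score = 0,
      lives_left = config$lives_per_block,
      pipes = list(), t = 0, elapsed_active = 0
    ),
    class = "game_state"
  )
}

#' @export
print.game_state <- function(x, ...) {
  cat(sprintf(
    "<game_state> phase=%s score=%d lives=%d t=%.2fs active=%.2fs pipes=%d\n",
    x$phase, x$score, x$lives_left, x$t, x$elapsed_active, length(x$pipes)
  ))
  invisible(x)
}

.rightmost_x <- function(pipes) {
  if (!length(pipes)) NULL else max(vapply(pipes, `[[`, numeric(1), "x"))
}

.ensure_lookahead <- function(state, config) {
  repeat {
    rx <- .rightmost_x(state$pipes)
    if (!is.null(rx) && rx >= config$screen_w) break
    state$pipes[[length(state$pipes) + 1L]] <- spawn_pipe(config, state$score, rx)
  }
  state
}

.event <- function(t, kind, value = NA_real_) {
  list(t = t, kind = kind, value = value)
}

#' Advance the game by one tick
#'
#' In the flying phase: pipes translate left at the difficulty-scaled speed,
#' the bird (an axis-aligned square at a fixed horizontal station) is placed
#' at `bird_y_input`, pipe pairs whose trailing edge passes the bird score
#' one point, and any overlap with a pipe rectangle costs a life
#' (`collision`, `life_lost` and `haptic_pulse` events; `block_over` when it
#' was the last life). In hover or over phases only wall time advances (the
#' bird hovers and the world stops moving forward). Off-screen pipes are
#' dropped and new ones spawned to keep lookahead.
#'
#' @param state A [new_game()] state.
#' @param bird_y_input Commanded bird altitude, px (finite; clamped to the
#'   screen).
#' @param dt Tick duration, seconds (default `1/tick_rate`).
#' @param config A [game_config()].
#' @return List with `state` (the new state) and `events` (list of
#'   `(t, kind, value)` events emitted this tick, possibly empty).
#' @export
game_tick <- function(state, bird_y_input, dt = NULL, config = game_config()) {
  stopifnot(inherits(state, "game_state"))
  if (!is.finite(bird_y_input)) stop("bird altitude must be finite")
  if (is.null(dt)) dt <- 1 / config$tick_rate
  state$t <- state$t + dt
  if (state$phase != "flying") {
    return(list(state = state, events = list()))
  }
  events <- list()
  state$elapsed_active <- state$elapsed_active + dt
  state$bird_y <- min(max(bird_y_input, 0), config$screen_h - config$bird_size)

  speed <- config$base_speed * difficulty(state$score, config)$speed_multiplier
  state$pipes <- lapply(state$pipes, function(p) {
    p$x <- p$x - speed * dt
    p
  })

  bx <- config$bird_station_frac * config$screen_w
  bs <- config$bird_size
  by <- state$bird_y

  # scoring: pipe pair fully past the bird without a collision
  for (i in seq_along(state$pipes)) {
    p <- state$pipes[[i]]
    if (!p$scored && p$x + config$pipe_width < bx) {
      state$pipes[[i]]$scored <- TRUE
      state$score <- state$score + 1
      events[[length(events) + 1L]] <- .event(state$t, "point", state$score)
    }
  }

  # collision: AABB overlap with either pipe of a pair
  collided <- FALSE
  for (p in state$pipes) {
    overlap_x <- p$x < bx + bs && p$x + config$pipe_width > bx
    if (overlap_x) {
      gap_lo <- p$gap_center - p$gap_size / 2
      gap_hi <- p$gap_center + p$gap_size / 2
      if (by < gap_lo || by + bs > gap_hi) {
        collided <- TRUE
        break
      }
    }
  }
  if (collided) {
    state$lives_left <- state$lives_left - 1
    events[[length(events) + 1L]] <- .event(state$t, "collision")
    events[[length(events) + 1L]] <- .event(state$t, "life_lost", state$lives_left)
    events[[length(events) + 1L]] <- .event(state$t, "haptic_pulse")
    if (state$lives_left <= 0) {
      state$phase <- "over"
      events[[length(events) + 1L]] <- .event(state$t, "block_over", state$score)
    } else {
      state$phase <- "hover"
    }
    return(list(state = state, events = events))
  }

  state$pipes <- Filter(function(p) p$x + config$pipe_width >= 0, state$pipes)
  state <- .ensure_lookahead(state, config)
  list(state = state, events = events)
}

#' Resume flight after a life loss
#'
#' Models the space-key press starting the next bird life: the phase returns
#' to flying and the pipe field is cleared for a grace distance ahead of the
#' bird so the new life does not start inside a pipe.
#'
#' @param state A hovering `game_state` with at least one life left.
#' @param config A [game_config()].
#' @return The resumed `game_state`.
#' @export
resume <- function(state, config = game_config()) {
  stopifnot(inherits(state, "game_state"))
  if (state$phase != "hover") stop("can only resume from the hover phase")
  if (state$lives_left < 1) stop("no lives left")
  bx <- config$bird_station_frac * config$screen_w
  state$pipes <- Filter(
    function(p) p$x > bx + config$grace_distance,
    state$pipes
  )
  state$phase <- "flying"
  .ensure_lookahead(state, config)
}

#' Convert an event list to a data.frame
#'
#' @param events List of `(t, kind, value)` events.
#' @return A data.frame with columns `t`, `kind`, `value`, ordered by time.
#' @export
events_df <- function(events) {
  if (!length(events)) {
    return(data.frame(
      t = numeric(0), kind = character(0),
      value = numeric(0), stringsAsFactors = FALSE
    ))
  }
  df <- data.frame(
    t = vapply(events, `[[`, numeric(1), "t"),
    kind = vapply(events, `[[`, character(1), "kind"),
    value = vapply(events, `[[`, numeric(1), "value"),
    stringsAsFactors = FALSE
  )
  df[order(df$t), , drop = FALSE]
}
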