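cfg <- game_config()

test_that("difficulty interpolates the printed endpoints and then freezes", {
  d0 <- difficulty(0, cfg)
  expect_equal(d0$speed_multiplier, 1.0)
  expect_equal(d0$gap_px, 300)
  d100 <- difficulty(100, cfg)
  expect_equal(d100$speed_multiplier, 2.5)
  expect_equal(d100$gap_px, 190)
  expect_identical(difficulty(150, cfg), d100) # frozen past the cap
  d50 <- difficulty(50, cfg)
  expect_equal(d50$gap_px, 245)
  expect_equal(d50$speed_multiplier, 1.75)
  expect_error(difficulty(-1, cfg), "nonnegative")

  # monotone: gap non-increasing, speed non-decreasing
  s <- 0:200
  d <- difficulty(s, cfg)
  expect_true(all(diff(d$gap_px) <= 0))
  expect_true(all(diff(d$speed_multiplier) >= 0))
})

test_that("bird altitude is proportional to the knee angle", {
  expect_equal(angle_to_bird_y(0, cfg), 0)
  expect_equal(angle_to_bird_y(54, cfg), 800 - 48)
  expect_equal(angle_to_bird_y(27, cfg), 376)
  expect_equal(angle_to_bird_y(60, cfg), 752) # clamped above the range
})

test_that("pipe spawning is seeded, within bounds, and spacing-preserving", {
  set.seed(1)
  p1 <- spawn_pipe(cfg, score = 0)
  set.seed(1)
  p2 <- spawn_pipe(cfg, score = 0)
  expect_identical(p1, p2)
  expect_equal(p1$x, cfg$screen_w) # first pipe enters at the right edge
  p3 <- spawn_pipe(cfg, score = 0, rightmost_x = p1$x)
  expect_equal(p3$x, cfg$screen_w + cfg$pipe_spacing)

  # gap centers are uniform over the feasible band
  set.seed(2)
  centers <- replicate(10000, spawn_pipe(cfg, score = 0)$gap_center)
  lo <- cfg$vertical_margin + 300 / 2
  hi <- cfg$screen_h - cfg$vertical_margin - 300 / 2
  expect_true(all(centers >= lo & centers <= hi))
  expect_lt(min(centers) - lo, (hi - lo) * 0.01)
  expect_lt(hi - max(centers), (hi - lo) * 0.01)

  # degenerate band: center forced to mid-screen
  tight <- game_config(
    screen_h = 800, gap_start = 680, gap_end = 190,
    vertical_margin = 60
  )
  p <- spawn_pipe(tight, score = 0)
  expect_equal(p$gap_center, 400)
})

test_that("a bird inside the gap scores one point per pipe, no collision", {
  set.seed(3)
  state <- new_game(cfg)
  events <- list()
  for (k in 1:2000) { # 40 s of flight
    tick <- game_tick(state, perfect_bird_input(state, cfg), config = cfg)
    state <- tick$state
    events <- c(events, tick$events)
  }
  df <- events_df(events)
  expect_gt(state$score, 10)
  expect_equal(sum(df$kind == "point"), state$score)
  expect_equal(sum(df$kind == "collision"), 0)
  expect_equal(state$lives_left, 4)
  expect_identical(state$phase, "flying")
  # score counts exactly the pipes that fully passed the bird
  bx <- cfg$bird_station_frac * cfg$screen_w
  still_ahead <- vapply(state$pipes, function(p) p$x + cfg$pipe_width >= bx, logical(1))
  expect_true(all(still_ahead[!vapply(state$pipes, `[[`, logical(1), "scored")]))
})

test_that("hitting a pipe costs a life and the bird hovers", {
  set.seed(4)
  state <- new_game(cfg)
  events <- list()
  for (k in 1:2000) {
    tick <- game_tick(state, 0, config = cfg) # bird glued to the floor
    state <- tick$state
    events <- c(events, tick$events)
    if (state$phase == "hover") break
  }
  df <- events_df(events)
  expect_identical(state$phase, "hover")
  expect_equal(state$lives_left, 3)
  expect_equal(state$score, 0)
  expect_equal(df$kind[df$t == max(df$t)], c("collision", "life_lost", "haptic_pulse"))
  # hover ticks advance wall time only
  t_before <- state$t
  active_before <- state$elapsed_active
  tick <- game_tick(state, 100, config = cfg)
  expect_equal(tick$state$t, t_before + 1 / cfg$tick_rate)
  expect_equal(tick$state$elapsed_active, active_before)
  expect_length(tick$events, 0)
})

test_that("losing the last life ends the block with a block_over event", {
  set.seed(5)
  state <- new_game(cfg)
  events <- list()
  for (k in 1:20000) {
    if (state$phase == "hover") state <- resume(state, cfg)
    tick <- game_tick(state, 0, config = cfg)
    state <- tick$state
    events <- c(events, tick$events)
    if (state$phase == "over") break
  }
  df <- events_df(events)
  expect_identical(state$phase, "over")
  expect_equal(state$lives_left, 0)
  expect_equal(sum(df$kind == "collision"), 4)
  expect_equal(sum(df$kind == "block_over"), 1)
  # game over is terminal: ticks only advance time, resume errors
  expect_error(resume(state, cfg), "hover")
  expect_length(game_tick(state, 0, config = cfg)$events, 0)
})

test_that("resume clears a grace distance and restarts flight", {
  set.seed(6)
  state <- new_game(cfg)
  while (state$phase == "flying") {
    state <- game_tick(state, 0, config = cfg)$state
  }
  state <- resume(state, cfg)
  expect_identical(state$phase, "flying")
  expect_equal(state$lives_left, 3)
  bx <- cfg$bird_station_frac * cfg$screen_w
  xs <- vapply(state$pipes, `[[`, numeric(1), "x")
  expect_true(all(xs > bx + cfg$grace_distance))
  # double resume is a state-machine violation
  expect_error(resume(state, cfg), "hover")
})

test_that("identical seeds give bit-identical event logs", {
  play <- function(seed) {
    set.seed(seed)
    state <- new_game(cfg)
    events <- list()
    for (k in 1:1500) {
      if (state$phase == "hover") state <- resume(state, cfg)
      if (state$phase == "over") break
      input <- if (k %% 7 < 4) perfect_bird_input(state, cfg) else 200
      tick <- game_tick(state, input, config = cfg)
      state <- tick$state
      events <- c(events, tick$events)
    }
    events_df(events)
  }
  expect_identical(play(42), play(42))
  expect_false(identical(play(42), play(43)))
})

test_that("game_tick validates its input", {
  state <- new_game(cfg)
  expect_error(game_tick(state, NaN, config = cfg), "finite")
  expect_error(game_tick(state, Inf, config = cfg), "finite")
})

test_that("score and lives bookkeeping is conserved", {
  set.seed(9)
  state <- new_game(cfg)
  events <- list()
  scores <- integer(0)
  for (k in 1:3000) {
    if (state$phase == "hover") state <- resume(state, cfg)
    if (state$phase == "over") break
    input <- if (k %% 11 < 8) perfect_bird_input(state, cfg) else 0
    tick <- game_tick(state, input, config = cfg)
    state <- tick$state
    events <- c(events, tick$events)
    scores <- c(scores, state$score)
  }
  df <- events_df(events)
  expect_true(all(diff(scores) >= 0)) # score never decreases
  expect_equal(sum(df$kind == "point"), state$score)
  expect_equal(sum(df$kind == "life_lost"), sum(df$kind == "collision"))
  expect_equal(
    sum(df$kind == "collision"),
    cfg$lives_per_block - state$lives_left
  )
})
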