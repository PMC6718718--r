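test_that("proportional mapping anchors rest, cap and MVE correctly", {
  cal <- fixture_calibration(bias = 1, mve = 5)
  expect_equal(emg_to_angle(1, cal), 0) # rest -> seated posture
  expect_equal(emg_to_angle(1 + 0.6 * 4, cal), 54) # cap -> 54 deg
  expect_equal(emg_to_angle(5, cal), 54) # MVE clamps at the cap
  expect_equal(emg_to_angle(100, cal), 54) # anything above too
  expect_equal(emg_to_angle(0, cal), 0) # sub-bias clamps at 0
  # intermediate effort is linear: 30% of range -> 27 deg
  expect_equal(emg_to_angle(1 + 0.3 * 4, cal), 27)
  # a different calibration maps identically in effort space
  cal2 <- fixture_calibration(bias = 0.2, mve = 0.7)
  expect_equal(emg_to_angle(0.2 + 0.6 * 0.5, cal2), 54)
  # uncapped mapping reaches the full 90 deg range
  cal3 <- fixture_calibration(bias = 1, mve = 5, effort_cap = 1)
  expect_equal(emg_to_angle(5, cal3), 90)
})

test_that("PD position loop is proportional with speed clamping", {
  g <- controller_gains(pos_kp = 2, pos_kd = 0)
  expect_equal(pd_position(10, 10, 0, g), 0)
  expect_equal(pd_position(20, 10, 0, g), 20)
  expect_equal(pd_position(1000, 0, 0, g, omega_max = 120), 120)
  expect_equal(pd_position(-1000, 0, 0, g, omega_max = 120), -120)
  # derivative acts on the measured velocity
  g2 <- controller_gains(pos_kp = 2, pos_kd = 0.5)
  expect_equal(pd_position(20, 10, 4, g2), 20 - 2)
})

test_that("PID velocity loop integrates with anti-windup", {
  g <- controller_gains(vel_kp = 1, vel_ki = 0, vel_kd = 0)
  out <- pid_velocity(0, 0, g, dt = 0.01)
  expect_equal(out$omega_com, 0)
  out <- pid_velocity(5, 0, g, dt = 0.01)
  expect_equal(out$omega_com, 5) # pure P

  # constant error e: the command grows by ki*e*dt per step until the clamp
  g <- controller_gains(vel_kp = 0, vel_ki = 2, vel_kd = 0, integrator_clamp = 0.5)
  st <- NULL
  vals <- numeric(40)
  for (k in 1:40) {
    out <- pid_velocity(10, 0, g, dt = 0.01, pid_state = st)
    st <- out$pid_state
    vals[k] <- out$omega_com
  }
  expect_equal(vals[1:2], c(0.2, 0.4), tolerance = 1e-12)
  expect_equal(vals[10], 0.5) # clamped
  expect_true(all(vals <= 0.5))
})

test_that("the plant tracks velocity commands with first-order dynamics", {
  plant <- plant_config()
  st <- joint_state()
  expect_equal(plant_step(st, 0, plant)$theta, 0) # rest stays at rest

  # constant command: discrete first-order response, exact closed form
  a <- plant$dt / plant$time_constant
  st <- joint_state()
  for (k in 1:200) st <- plant_step(st, 50, plant)
  expect_equal(st$omega, 50 * (1 - (1 - a)^200), tolerance = 1e-10)
  # after >> tau the angle advances ~ command per second
  st <- joint_state()
  for (k in 1:400) st <- plant_step(st, 20, plant) # 2 s
  expect_equal(st$omega, 20, tolerance = 1e-3)
  expect_equal(st$theta, 20 * 2, tolerance = 0.5) # minus the ~tau start-up
})

test_that("software limits pin the angle and zero the velocity", {
  plant <- plant_config(theta_max = 54)
  st <- joint_state(theta = 53.8)
  for (k in 1:100) st <- plant_step(st, 120, plant)
  expect_equal(st$theta, 54)
  expect_equal(st$omega, 0)
  expect_true(st$powered) # software stop does not cut power
  st2 <- joint_state(theta = 0.1)
  for (k in 1:100) st2 <- plant_step(st2, -120, plant)
  expect_equal(st2$theta, 0)
})

test_that("overtravel past a mechanical bound cuts the power", {
  # a large step can jump past the software stop onto the limit switch
  plant <- plant_config(theta_max = 109.5, mech_max = 110, dt = 0.02)
  st <- joint_state(theta = 109, omega = 120)
  st <- plant_step(st, 120, plant)
  expect_equal(st$theta, 110)
  expect_false(st$powered)
  # powered-off joints do not move
  st2 <- plant_step(st, 120, plant)
  expect_identical(st2$theta, st$theta)
})

test_that("emergency stop freezes the joint until reset", {
  plant <- plant_config()
  st <- joint_state(theta = 20, omega = 50)
  st <- emergency_stop(st)
  expect_true(st$estop)
  expect_false(st$powered)
  expect_equal(st$omega, 0)
  expect_equal(st$theta, 20)
  st2 <- plant_step(st, 120, plant)
  expect_identical(st2, st) # no-op while latched
  st3 <- reset_joint(st)
  st3 <- plant_step(st3, 120, plant)
  expect_gt(st3$theta, 20) # motion resumes
})

test_that("the lean servo step equals the exported controller composition", {
  set.seed(12)
  gains <- controller_gains()
  plant <- plant_config()
  sv <- emgrehab:::.servo_init(joint_state())
  st <- joint_state()
  pid <- NULL
  for (k in 1:500) {
    theta_d <- runif(1, 0, 54)
    omega_d <- pd_position(theta_d, st$theta, st$omega, gains,
      omega_max = plant$omega_max
    )
    pv <- pid_velocity(omega_d, st$omega, gains,
      dt = plant$dt,
      pid_state = pid, omega_max = plant$omega_max
    )
    pid <- pv$pid_state
    st <- plant_step(st, pv$omega_com, plant)
    sv <- emgrehab:::.servo_advance(sv, theta_d, gains, plant)
    expect_equal(sv$theta, st$theta, tolerance = 1e-12)
    expect_equal(sv$omega, st$omega, tolerance = 1e-12)
  }
})

test_that("with an ideal inner loop the PD reduces to a first-order tracker", {
  # plant time constant -> 0 and pos_kd = 0: theta_{k+1} =
  # (1 - kp dt) theta_k + kp dt theta_d, a geometric approach to theta_d
  gains <- controller_gains(pos_kp = 8, pos_kd = 0)
  dt <- 0.005
  theta_d <- 40
  theta <- 0
  for (k in 1:300) {
    omega_d <- pd_position(theta_d, theta, 0, gains, omega_max = 1e6)
    theta <- theta + omega_d * dt
    closed_form <- theta_d + (1 - gains$pos_kp * dt)^k * (0 - theta_d)
    expect_equal(theta, closed_form, tolerance = 1e-10)
  }
})

test_that("closed loop holds rest, settles on a step, and respects limits", {
  cal <- fixture_calibration()
  # envelope at bias: the joint stays seated
  out <- closed_loop_run(rep(1, 400), cal)
  expect_true(all(abs(out$theta_a) < 1e-6))

  # step to the cap: settles within 1 deg of 54 in < 2 s
  env <- c(rep(1, 100), rep(1 + 0.6 * 4, 400))
  out <- closed_loop_run(env, cal)
  expect_lt(max(abs(out$theta_a[out$time_s > 2] - 54)), 1)

  # random envelopes never drive the joint outside its limits
  set.seed(33)
  plant <- plant_config()
  env <- abs(rnorm(2000, 3, 3))
  out <- closed_loop_run(env, cal, plant = plant)
  expect_true(all(out$theta_a >= plant$mech_min & out$theta_a <= plant$mech_max))
  expect_true(all(out$theta_d >= 0 & out$theta_d <= 54))
  omega <- diff(out$theta_a) / plant$dt
  expect_true(all(abs(omega) <= plant$omega_max + 1e-9))
})

test_that("the actual angle lags a sinusoidal command by a finite delay", {
  cal <- fixture_calibration()
  t <- seq(0, 10, by = 0.005)
  env <- 1 + 2 + 2 * sin(2 * pi * 0.5 * t) # mid-range 0.5 Hz sweep
  out <- closed_loop_run(env, cal)
  lag <- xcorr_lag(out$theta_d, out$theta_a, fs = 200, max_lag = 200)
  expect_gt(lag, 0)
  expect_lt(lag, 500)
})

test_that("tracking error shrinks as the position gain increases", {
  cal <- fixture_calibration()
  t <- seq(0, 10, by = 0.005)
  env <- 1 + 2 + 1.5 * sin(2 * pi * 0.4 * t)
  errs <- vapply(c(2, 4, 8, 16), function(kp) {
    out <- closed_loop_run(env, cal, gains = controller_gains(pos_kp = kp))
    rmse(out$theta_d, out$theta_a)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
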