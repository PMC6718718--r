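#' Proportional mapping configuration
#'
#' The EMG-to-angle map: the calibrated bias-to-MVE range corresponds to the
#' full knee range (0 deg = seated, 90 deg = thigh and shank in line); during
#' training the effort cap limits the commanded range (54 deg at the default
#' 60% cap).
#'
#' @param full_range_angle Knee angle at full (100%) effort, degrees
#'   (default 90).
#' @param min_angle Knee angle at rest, degrees (default 0).
#' @return An object of class `mapping_config`.
#' @export
mapping_config <- function(full_range_angle = 90, min_angle = 0) {
  stopifnot(full_range_angle > min_angle)
  structure(
    list(full_range_angle = full_range_angle, min_angle = min_angle),
    class = "mapping_config"
  )
}

#' Map an EMG envelope value to a desired knee angle
#'
#' Proportional myoelectric control: effort = `(envelope - bias)/(mve -
#' bias)` clamped to `[0, effort_cap]`, then scaled to degrees. At the
#' defaults the commanded angle spans exactly 0 to 54 degrees; any envelope
#' at or above the cap (including the MVE itself) saturates at the cap.
#'
#' @param envelope Envelope value(s), signal units (vectorized).
#' @param calib A [calibration_result()].
#' @param map A [mapping_config()].
#' @return Desired knee angle(s), degrees.
#' @export
emg_to_angle <- function(envelope, calib, map = mapping_config()) {
  stopifnot(inherits(calib, "calibration"), inherits(map, "mapping_config"))
  effort <- (envelope - calib$bias) / (calib$mve - calib$bias)
  effort <- pmin(pmax(effort, 0), calib$effort_cap)
  map$min_angle + (map$full_range_angle - map$min_angle) * effort
}

#' Cascade controller gains
#'
#' Gains of the PD position loop (outer) and PID velocity loop (inner).
#' These are artifacts of this simulation, chosen for a stable loop with a
#' desired-to-actual lag on the order of 100 ms; they are not published
#' hardware values.
#'
#' @param pos_kp Position P gain, (deg/s)/deg.
#' @param pos_kd Position D gain on measured velocity, dimensionless.
#' @param vel_kp,vel_ki,vel_kd Velocity PID gains.
#' @param integrator_clamp Anti-windup clamp on the integrator term, deg/s.
#' @return An object of class `controller_gains`.
#' @export
controller_gains <- function(pos_kp = 8, pos_kd = 0.05,
                             vel_kp = 1, vel_ki = 5, vel_kd = 0,
                             integrator_clamp = 200) {
  stopifnot(
    pos_kp >= 0, pos_kd >= 0, vel_kp >= 0, vel_ki >= 0, vel_kd >= 0,
    integrator_clamp > 0
  )
  structure(
    list(
      pos_kp = pos_kp, pos_kd = pos_kd,
      vel_kp = vel_kp, vel_ki = vel_ki, vel_kd = vel_kd,
      integrator_clamp = integrator_clamp
    ),
    class = "controller_gains"
  )
}

#' Simulated knee-joint plant configuration
#'
#' First-order velocity-tracking plant with three protection levels:
#' software range/speed limits, simulated overtravel-limit switches at the
#' mechanical bounds (power cut when reached), and the mechanical stops
#' themselves (the angle can never pass them).
#'
#' @param time_constant Velocity-loop first-order lag, seconds.
#' @param omega_max Software speed limit, deg/s.
#' @param theta_min,theta_max Software range limits, degrees.
#' @param mech_min,mech_max Limit-switch / mechanical stop positions,
#'   degrees (default -10 and 110: 110 deg flexion, 10 deg hyperextension,
#'   hyperextension negative by the seated-posture convention).
#' @param dt Integration step, seconds (default 5 ms: 200 Hz control).
#' @return An object of class `plant_config`.
#' @export
plant_config <- function(time_constant = 0.05, omega_max = 120,
                         theta_min = 0, theta_max = 54,
                         mech_min = -10, mech_max = 110, dt = 0.005) {
  stopifnot(
    time_constant > 0, omega_max > 0, dt > 0,
    mech_min < theta_min, theta_min < theta_max, theta_max < mech_max
  )
  structure(
    list(
      time_constant = time_constant, omega_max = omega_max,
      theta_min = theta_min, theta_max = theta_max,
      mech_min = mech_min, mech_max = mech_max, dt = dt
    ),
    class = "plant_config"
  )
}

#' Joint state
#'
#' @param theta Knee angle, degrees.
#' @param omega Angular velocity, deg/s.
#' @param powered Motor power flag (limit switches cut it).
#' @param estop Emergency-stop latch.
#' @return An object of class `joint_state`.
#' @export
joint_state <- function(theta = 0, omega = 0, powered = TRUE, estop = FALSE) {
  stopifnot(is.finite(theta), is.finite(omega))
  structure(
    list(theta = theta, omega = omega, powered = powered, estop = estop),
    class = "joint_state"
  )
}

#' PD position controller
#'
#' Outer loop: desired velocity from the position error, with derivative
#' action on the measured velocity, clamped to the software speed limit.
#'
#' @param theta_d Desired angle, degrees.
#' @param theta_a Actual angle, degrees.
#' @param omega_meas Measured velocity, deg/s.
#' @param gains A [controller_gains()].
#' @param omega_max Software speed limit, deg/s.
#' @return Desired velocity, deg/s.
#' @export
pd_position <- function(theta_d, theta_a, omega_meas, gains = controller_gains(),
                        omega_max = 120) {
  stopifnot(is.finite(theta_d), is.finite(theta_a), is.finite(omega_meas))
  omega_d <- gains$pos_kp * (theta_d - theta_a) - gains$pos_kd * omega_meas
  min(max(omega_d, -omega_max), omega_max)
}

#' PID velocity controller
#'
#' Inner loop: discrete PID on the velocity error with a clamped
#' (anti-windup) integrator; the command is clamped to the software speed
#' limit.
#'
#' @param omega_d Desired velocity, deg/s.
#' @param omega_meas Measured velocity, deg/s.
#' @param gains A [controller_gains()].
#' @param dt Control step, seconds.
#' @param pid_state List with `integ` (integrator, deg/s) and `prev_err`
#'   (previous error, deg/s); `NULL` starts from rest.
#' @param omega_max Software speed limit, deg/s.
#' @return List with `omega_com` (motor command, deg/s) and the updated
#'   `pid_state`.
#' @export
pid_velocity <- function(omega_d, omega_meas, gains = controller_gains(),
                         dt = 0.005, pid_state = NULL, omega_max = 120) {
  stopifnot(dt > 0)
  if (is.null(pid_state)) pid_state <- list(integ = 0, prev_err = 0)
  err <- omega_d - omega_meas
  integ <- pid_state$integ + gains$vel_ki * err * dt
  integ <- min(max(integ, -gains$integrator_clamp), gains$integrator_clamp)
  deriv <- if (gains$vel_kd > 0) gains$vel_kd * (err - pid_state$prev_err) / dt else 0
  omega_com <- gains$vel_kp * err + integ + deriv
  omega_com <- min(max(omega_com, -omega_max), omega_max)
  list(omega_com = omega_com, pid_state = list(integ = integ, prev_err = err))
}

#' Advance the simulated joint by one step
#'
#' First-order velocity tracking `domega/dt = (omega_com - omega)/tau`
#' integrated by explicit Euler. Software range limits pin the angle and
#' zero the velocity; if a step would carry the angle past a mechanical
#' bound, the overtravel-limit switch cuts power (`powered = FALSE`) and the
#' angle holds at the bound. After an emergency stop (or with power cut) the
#' step is a no-op.
#'
#' @param state A [joint_state()].
#' @param omega_com Motor velocity command, deg/s.
#' @param plant A [plant_config()].
#' @return The new [joint_state()].
#' @export
plant_step <- function(state, omega_com, plant = plant_config()) {
  stopifnot(inherits(state, "joint_state"), inherits(plant, "plant_config"))
  if (state$estop || !state$powered) return(state)
  omega <- state$omega +
    plant$dt * (omega_com - state$omega) / plant$time_constant
  omega <- min(max(omega, -plant$omega_max), plant$omega_max)
  theta <- state$theta + omega * plant$dt
  if (theta >= plant$mech_max) {
    return(joint_state(plant$mech_max, 0, powered = FALSE))
  }
  if (theta <= plant$mech_min) {
    return(joint_state(plant$mech_min, 0, powered = FALSE))
  }
  if (theta > plant$theta_max) {
    theta <- plant$theta_max; omega <- 0
  } else if (theta < plant$theta_min) {
    theta <- plant$theta_min; omega <- 0
  }
  joint_state(theta, omega)
}

#' Emergency stop and reset
#'
#' `emergency_stop` latches the estop: power off, velocity zeroed, angle
#' frozen; subsequent [plant_step()] calls are no-ops. `reset_joint` clears
#' the latch and restores power so motion can resume.
#'
#' @param state A [joint_state()].
#' @return The new [joint_state()].
#' @export
emergency_stop <- function(state) {
  stopifnot(inherits(state, "joint_state"))
  joint_state(state$theta, 0, powered = FALSE, estop = TRUE)
}

#' @rdname emergency_stop
#' @export
reset_joint <- function(state) {
  stopifnot(inherits(state, "joint_state"))
  joint_state(state$theta, state$omega, powered = TRUE, estop = FALSE)
}

# Lean one-step servo + plant advance shared by closed_loop_run() and
# run_block(); numerically identical to composing pd_position(),
# pid_velocity() and plant_step() (asserted in the test suite), without
# their per-call validation.
# sv: list(theta, omega, powered, estop, integ, prev_err)
.servo_advance <- function(sv, theta_d, gains, plant) {
  om <- plant$omega_max
  omega_d <- gains$pos_kp * (theta_d - sv$theta) - gains$pos_kd * sv$omega
  if (omega_d > om) omega_d <- om else if (omega_d < -om) omega_d <- -om
  err <- omega_d - sv$omega
  integ <- sv$integ + gains$vel_ki * err * plant$dt
  cl <- gains$integrator_clamp
  if (integ > cl) integ <- cl else if (integ < -cl) integ <- -cl
  deriv <- if (gains$vel_kd > 0) {
    gains$vel_kd * (err - sv$prev_err) / plant$dt
  } else 0
  omega_com <- gains$vel_kp * err + integ + deriv
  if (omega_com > om) omega_com <- om else if (omega_com < -om) omega_com <- -om
  sv$integ <- integ
  sv$prev_err <- err
  if (!sv$estop && sv$powered) {
    omega <- sv$omega + plant$dt * (omega_com - sv$omega) / plant$time_constant
    if (omega > om) omega <- om else if (omega < -om) omega <- -om
    theta <- sv$theta + omega * plant$dt
    if (theta >= plant$mech_max) {
      theta <- plant$mech_max; omega <- 0; sv$powered <- FALSE
    } else if (theta <= plant$mech_min) {
      theta <- plant$mech_min; omega <- 0; sv$powered <- FALSE
    } else if (theta > plant$theta_max) {
      theta <- plant$theta_max; omega <- 0
    } else if (theta < plant$theta_min) {
      theta <- plant$theta_min; omega <- 0
    }
    sv$theta <- theta
    sv$omega <- omega
  }
  sv
}

.servo_init <- function(state = joint_state()) {
  list(
    theta = state$theta, omega = state$omega, powered = state$powered,
    estop = state$estop, integ = 0, prev_err = 0
  )
}

#' Run the proportional-control loop over an envelope
#'
#' Closes mapping -> PD position -> PID velocity -> plant at every control
#' tick (the plant `dt` must match the envelope rate) and returns aligned
#' desired and actual angle traces for the tracking metrics.
#'
#' @param envelope Numeric vector, filtered control envelope at `1/dt` Hz.
#' @param calib A [calibration_result()].
#' @param gains A [controller_gains()].
#' @param plant A [plant_config()].
#' @param map A [mapping_config()].
#' @param state Initial [joint_state()] (default: at rest at 0 deg).
#' @return A data.frame with columns `time_s`, `theta_d`, `theta_a`.
#' @export
closed_loop_run <- function(envelope, calib, gains = controller_gains(),
                            plant = plant_config(), map = mapping_config(),
                            state = joint_state()) {
  stopifnot(is.numeric(envelope), length(envelope) >= 1L)
  theta_d <- emg_to_angle(envelope, calib, map)
  n <- length(envelope)
  theta_a <- numeric(n)
  sv <- .servo_init(state)
  for (k in seq_len(n)) {
    sv <- .servo_advance(sv, theta_d[k], gains, plant)
    theta_a[k] <- sv$theta
  }
  data.frame(
    time_s = (seq_len(n) - 1) * plant$dt,
    theta_d = theta_d, theta_a = theta_a
  )
}
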