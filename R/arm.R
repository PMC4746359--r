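#' Parameters of the planar two-joint virtual arm
#'
#' Simplified musculoskeletal arm: two rigid links (upper arm, forearm)
#' moving in the horizontal plane (no gravity torque), actuated by four
#' lumped muscle groups (shoulder extensor/flexor, elbow
#' extensor/flexor).  Each group has first-order Hill-type activation
#' dynamics and produces a joint torque proportional to its activation;
#' viscous damping at both joints keeps the dynamics well posed.
#'
#' Angle conventions: the shoulder angle is measured from the +x axis of
#' the shoulder frame, the elbow angle is the interior flexion angle of
#' the forearm relative to the upper arm; flexion increases the angle.
#'
#' @param l1,l2 segment lengths (cm).
#' @param m1,m2 segment masses (kg).
#' @param gain torque at full activation per group, ordered
#'   (shoulder-ext, shoulder-flex, elbow-ext, elbow-flex) (N m).  Extensors
#'   act with negative sign on their joint, flexors positive.
#' @param tau_act,tau_deact activation/deactivation time constants (ms).
#' @param damping viscous joint damping (N m s / rad).
#' @param fl_scaling linear force-length scaling: each group's torque is
#'   multiplied by its current normalized length, so that antagonist
#'   co-contraction acts as a spring with a stable equilibrium posture
#'   (equilibrium-point control).  Without it, any constant net torque
#'   drives the joints to their limits.
#' @param limits 2x2 matrix of joint angle limits (rad), rows =
#'   (shoulder, elbow), cols = (min, max).
#' @param q0 start posture (rad, shoulder then elbow).
#' @param dt integration step (ms).
#' @return A list of class `sr_arm_params`.
#' @export
arm_params <- function(l1 = 30, l2 = 33, m1 = 1.9, m2 = 1.5,
                       gain = c(20, 20, 15, 15), tau_act = 30,
                       tau_deact = 60, damping = 3.0, fl_scaling = TRUE,
                       limits = rbind(c(-30, 70), c(55, 155)) * pi / 180,
                       q0 = c(20, 105) * pi / 180, dt = 0.5) {
  stopifnot(l1 > 0, l2 > 0, m1 > 0, m2 > 0, all(gain > 0),
            tau_act > 0, tau_deact > 0, dt > 0, dt <= 1)
  L1 <- l1 / 100
  L2 <- l2 / 100
  structure(list(l1 = l1, l2 = l2, m1 = m1, m2 = m2,
                 r1 = L1 / 2, r2 = L2 / 2,
                 I1 = m1 * L1^2 / 12, I2 = m2 * L2^2 / 12,
                 gain = gain, tau_act = tau_act, tau_deact = tau_deact,
                 damping = damping, fl_scaling = fl_scaling,
                 limits = limits, q0 = q0, dt = dt),
            class = "sr_arm_params")
}

#' Initial arm state
#'
#' @param params an [arm_params()].
#' @return A list of class `sr_arm_state` with joint angles `q` (rad),
#'   velocities `qd` (rad/s), activations `act` in `[0,1]` and time (ms).
#' @export
arm_state <- function(params) {
  structure(list(q = params$q0, qd = c(0, 0), act = rep(0, 4), t = 0),
            class = "sr_arm_state")
}

#' One step of the muscle activation ODE
#'
#' First-order relaxation of activation toward excitation, with time
#' constant `tau_act` when excitation exceeds activation and `tau_deact`
#' otherwise; the result is clamped to `[0, 1]`.
#'
#' @param activation,excitation values in `[0, 1]` (clamped with a
#'   warning if outside).
#' @param dt time step (ms).
#' @param params an [arm_params()].
#' @return New activation (same length as inputs).
#' @export
activation_step <- function(activation, excitation, dt, params) {
  stopifnot(dt > 0)
  if (any(activation < 0 | activation > 1 | excitation < 0 | excitation > 1)) {
    warning("activation/excitation outside [0, 1]; clamped")
    activation <- pmin(1, pmax(0, activation))
    excitation <- pmin(1, pmax(0, excitation))
  }
  tau <- ifelse(excitation > activation, params$tau_act, params$tau_deact)
  a <- excitation + (activation - excitation) * exp(-dt / tau)
  pmin(1, pmax(0, a))
}

#' Joint torques from muscle activations
#'
#' Each lumped group actuates exactly one joint:
#' `torque_j = sum(gain * sign * activation)`.  The shoulder angle grows
#' with shoulder flexion, so its flexor acts with positive sign; the elbow
#' angle is the interior angle, which shrinks with elbow flexion, so the
#' elbow flexor acts with negative sign.
#'
#' With `fl_scaling` each group's contribution is additionally scaled by
#' its current normalized length (force grows with stretch), so
#' co-contracted antagonists behave like a spring around an equilibrium
#' posture.
#'
#' @param state an `sr_arm_state`.
#' @param params an [arm_params()].
#' @return Length-2 numeric (shoulder, elbow) in N m.
#' @export
joint_torques <- function(state, params) {
  g <- params$gain
  f <- if (isTRUE(params$fl_scaling) && !is.null(state$q)) {
    muscle_lengths(state, params)
  } else {
    rep(1, 4)
  }
  a <- state$act * f
  c(g[2] * a[2] - g[1] * a[1],
    g[3] * a[3] - g[4] * a[4])
}

# mass matrix / Coriolis terms of the planar 2-link chain (SI units)
arm_dynamics <- function(q, qd, tau, params) {
  L1 <- params$l1 / 100
  r2 <- params$r2
  m2 <- params$m2
  c2 <- cos(q[2])
  M11 <- params$I1 + params$I2 + params$m1 * params$r1^2 +
    m2 * (L1^2 + r2^2 + 2 * L1 * r2 * c2)
  M12 <- params$I2 + m2 * (r2^2 + L1 * r2 * c2)
  M22 <- params$I2 + m2 * r2^2
  h <- m2 * L1 * r2 * sin(q[2])
  C1 <- -h * (2 * qd[1] * qd[2] + qd[2]^2)
  C2 <- h * qd[1]^2
  rhs <- c(tau[1] - C1 - params$damping * qd[1],
           tau[2] - C2 - params$damping * qd[2])
  det <- M11 * M22 - M12^2
  c(M22 * rhs[1] - M12 * rhs[2], M11 * rhs[2] - M12 * rhs[1]) / det
}

#' Advance the arm by one control step
#'
#' Activations are advanced with [activation_step()], then the joint
#' accelerations follow from the planar two-link rigid-body dynamics
#' (horizontal plane, viscous damping) integrated by semi-implicit Euler
#' at the arm step `params$dt`; joint angles are clamped at their limits
#' with velocity zeroing.
#'
#' @param state an `sr_arm_state`.
#' @param excitations 4 muscle excitations in `[0, 1]`.
#' @param dt step duration (ms), a multiple of `params$dt`, at most 1 ms.
#' @param params an [arm_params()].
#' @return The next `sr_arm_state`.
#' @export
arm_step <- function(state, excitations, dt, params) {
  stopifnot(dt > 0, dt <= 1)
  n_sub <- max(1L, as.integer(round(dt / params$dt)))
  h <- dt / n_sub
  q <- state$q
  qd <- state$qd
  act <- state$act
  for (i in seq_len(n_sub)) {
    act <- activation_step(act, excitations, h, params)
    tau <- joint_torques(list(act = act, q = q), params)
    qdd <- arm_dynamics(q, qd, tau, params)
    if (any(!is.finite(qdd))) stop("numeric error: non-finite arm state")
    qd <- qd + qdd * h / 1000
    q <- q + qd * h / 1000
    for (j in 1:2) {
      if (q[j] < params$limits[j, 1]) {
        q[j] <- params$limits[j, 1]
        qd[j] <- 0
      } else if (q[j] > params$limits[j, 2]) {
        q[j] <- params$limits[j, 2]
        qd[j] <- 0
      }
    }
  }
  structure(list(q = q, qd = qd, act = act, t = state$t + dt),
            class = "sr_arm_state")
}

#' Hand position by forward kinematics
#'
#' @param state an `sr_arm_state`.
#' @param params an [arm_params()].
#' @return `(x, y)` in cm, shoulder at the origin.
#' @export
hand_position <- function(state, params) {
  q1 <- state$q[1]
  # elbow angle is interior flexion: forearm direction = q1 + (q2 - pi)
  q12 <- q1 + state$q[2] - pi
  c(params$l1 * cos(q1) + params$l2 * cos(q12),
    params$l1 * sin(q1) + params$l2 * sin(q12))
}

#' Normalized muscle-group lengths
#'
#' Affine map of each joint angle to `[0, 1]`: the flexor of a joint
#' shortens as the joint flexes, the extensor lengthens, and each
#' antagonist pair sums to 1.  At mid-range posture all lengths are 0.5.
#'
#' @param state an `sr_arm_state`.
#' @param params an [arm_params()].
#' @return Length-4 numeric, ordered (shoulder-ext, shoulder-flex,
#'   elbow-ext, elbow-flex).
#' @export
muscle_lengths <- function(state, params) {
  qn <- (state$q - params$limits[, 1]) /
    (params$limits[, 2] - params$limits[, 1])
  qn <- pmin(1, pmax(0, qn))
  c(qn[1], 1 - qn[1], 1 - qn[2], qn[2])
}

#' Reach targets of the center-out task
#'
#' Targets lie 15 cm from the start hand position: `"left"` along -x,
#' `"bottom"` along -y.  Default reach durations are 600 ms (left) and
#' 500 ms (bottom).
#'
#' @param label `"left"` or `"bottom"`.
#' @param params an [arm_params()].
#' @param distance target distance from the start position (cm).
#' @return List with `label`, `position` (cm), `duration` (ms).
#' @export
reach_target <- function(label = c("left", "bottom"), params = arm_params(),
                         distance = 15) {
  label <- match.arg(label)
  start <- hand_position(arm_state(params), params)
  if (label == "left") {
    list(label = label, position = start + c(-distance, 0), duration = 600)
  } else {
    list(label = label, position = start + c(0, -distance), duration = 500)
  }
}
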