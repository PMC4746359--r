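test_that("activation dynamics follow the first-order closed form", {
  p <- arm_params()
  expect_equal(activation_step(0.4, 0.4, 1, p), 0.4)  # fixed point
  # step response: a(t) = 1 - exp(-t / tau_act)
  a <- 0
  for (i in 1:200) a <- activation_step(a, 1, 1, p)
  expect_equal(a, 1 - exp(-200 / p$tau_act), tolerance = 1e-9)
  # decay is monotone and uses tau_deact
  a <- 0.9
  prev <- a
  for (i in 1:50) {
    a <- activation_step(a, 0, 1, p)
    expect_lte(a, prev)
    prev <- a
  }
  expect_equal(a, 0.9 * exp(-50 / p$tau_deact), tolerance = 1e-9)
  expect_warning(activation_step(1.4, 0.5, 1, p), "clamped")
})

test_that("joint torques follow the gain-sign matrix", {
  p <- arm_params(gain = c(3, 5, 2, 4), fl_scaling = FALSE)
  st <- arm_state(p)
  st$act <- c(0, 0, 0, 0)
  expect_equal(joint_torques(st, p), c(0, 0))
  st$act <- c(0.5, 0.5, 0.5, 0.5)
  p_sym <- arm_params(gain = c(3, 3, 2, 2), fl_scaling = FALSE)
  expect_equal(joint_torques(st, p_sym), c(0, 0))  # antagonist balance
  # independent matrix oracle: torque = G %*% act with signed gains
  G <- rbind(c(-3, 5, 0, 0), c(0, 0, 2, -4))
  for (i in 1:10) {
    st$act <- runif(4)
    expect_equal(joint_torques(st, p), as.numeric(G %*% st$act),
                 tolerance = 1e-12)
  }
  # with force-length scaling the gains are modulated by current length
  pfl <- arm_params(gain = c(3, 5, 2, 4), fl_scaling = TRUE)
  st$act <- c(1, 1, 0, 0)
  ml <- muscle_lengths(st, pfl)
  expect_equal(joint_torques(st, pfl)[1], 5 * ml[2] - 3 * ml[1],
               tolerance = 1e-12)
})

test_that("with force-length scaling, constant co-contraction settles at its equilibrium posture", {
  p <- arm_params()
  st <- arm_state(p)
  exc <- c(0.3, 0.6, 0.5, 0.4)
  for (i in 1:3000) st <- arm_step(st, exc, 1, p)
  # equilibrium: act_ext * len_ext = act_flex * len_flex per joint
  ml <- muscle_lengths(st, p)
  expect_equal(st$act, exc, tolerance = 1e-3)
  expect_equal(p$gain[1] * exc[1] * ml[1], p$gain[2] * exc[2] * ml[2],
               tolerance = 0.02)
  expect_equal(p$gain[3] * exc[3] * ml[3], p$gain[4] * exc[4] * ml[4],
               tolerance = 0.02)
  expect_lt(sum(st$qd^2), 1e-4)
})

test_that("arm dynamics match a high-accuracy deSolve oracle under constant torque", {
  p <- arm_params(fl_scaling = FALSE)
  # drive with constant excitations; compare joint angles after 10 ms
  exc <- c(0.1, 0.6, 0.2, 0.7)
  st <- arm_state(p)
  for (i in 1:10) st <- arm_step(st, exc, 1, p)

  deriv <- function(t, y, parms) {
    q <- y[1:2]; qd <- y[3:4]; act <- y[5:8]
    tau_a <- ifelse(exc > act, p$tau_act, p$tau_deact)
    dact <- (exc - act) / tau_a                       # per ms
    g <- p$gain
    tau <- c(g[2] * act[2] - g[1] * act[1], g[3] * act[3] - g[4] * act[4])
    L1 <- p$l1 / 100; r2 <- p$r2; m2 <- p$m2; c2 <- cos(q[2])
    M11 <- p$I1 + p$I2 + p$m1 * p$r1^2 +
      m2 * (L1^2 + r2^2 + 2 * L1 * r2 * c2)
    M12 <- p$I2 + m2 * (r2^2 + L1 * r2 * c2)
    M22 <- p$I2 + m2 * r2^2
    h <- m2 * L1 * r2 * sin(q[2])
    rhs <- c(tau[1] + h * (2 * qd[1] * qd[2] + qd[2]^2) - p$damping * qd[1],
             tau[2] - h * qd[1]^2 - p$damping * qd[2])
    det <- M11 * M22 - M12^2
    qdd <- c(M22 * rhs[1] - M12 * rhs[2], M11 * rhs[2] - M12 * rhs[1]) / det
    # time in ms; mechanics in SI seconds
    list(c(qd / 1000, qdd / 1000, dact))
  }
  y0 <- c(p$q0, 0, 0, rep(0, 4))
  sol <- deSolve::ode(y0, times = c(0, 10), func = deriv, parms = NULL,
                      method = "ode45", atol = 1e-10, rtol = 1e-10)
  expect_equal(st$q, unname(sol[2, 2:3]), tolerance = 1e-4)
})

test_that("equilibrium, energy dissipation and step-size convergence hold", {
  p <- arm_params()
  st <- arm_state(p)
  st2 <- arm_step(st, c(0, 0, 0, 0), 1, p)
  expect_equal(st2$q, st$q)           # zero torque, zero velocity
  expect_equal(st2$qd, c(0, 0))

  # kinetic energy non-increasing once excitation is zero
  st <- arm_state(p)
  for (i in 1:150) st <- arm_step(st, c(0.8, 0, 0, 0.8), 1, p)
  ke <- function(s) sum(s$qd^2)
  for (i in 1:300) {
    # wait until activations have decayed, then check decay of motion
    st <- arm_step(st, c(0, 0, 0, 0), 1, p)
  }
  e1 <- ke(st)
  for (i in 1:100) st <- arm_step(st, c(0, 0, 0, 0), 1, p)
  expect_lte(ke(st), e1)

  # halving dt changes a 600 ms trajectory by < 0.1 cm
  run <- function(dt) {
    pp <- arm_params(dt = dt)
    s <- arm_state(pp)
    for (i in 1:600) s <- arm_step(s, c(0.1, 0.5, 0.1, 0.5), 1, pp)
    hand_position(s, pp)
  }
  expect_lt(sqrt(sum((run(0.5) - run(0.25))^2)), 0.1)
})

test_that("hand kinematics and muscle lengths follow the geometry", {
  p <- arm_params()
  st <- arm_state(p)
  st$q <- c(pi / 3, pi)  # elbow fully extended
  expect_equal(sqrt(sum(hand_position(st, p)^2)), p$l1 + p$l2,
               tolerance = 1e-9)
  st$q <- c(pi / 2, pi / 2)
  # shoulder up, elbow interior 90 degrees: forearm points along +x
  expect_equal(hand_position(st, p), c(p$l2, p$l1), tolerance = 1e-9)

  # mid-range posture: all normalized lengths 0.5; antagonists sum to 1
  st$q <- rowMeans(p$limits)
  expect_equal(muscle_lengths(st, p), rep(0.5, 4))
  for (i in 1:10) {
    st$q <- p$limits[, 1] + runif(2) * (p$limits[, 2] - p$limits[, 1])
    ml <- muscle_lengths(st, p)
    expect_equal(ml[1] + ml[2], 1)
    expect_equal(ml[3] + ml[4], 1)
    qn <- (st$q - p$limits[, 1]) / (p$limits[, 2] - p$limits[, 1])
    expect_equal(ml, c(qn[1], 1 - qn[1], 1 - qn[2], qn[2]))
  }
  # flexing the elbow (decreasing interior angle) shortens the flexor
  st$q <- c(pi / 4, pi / 2)
  l_a <- muscle_lengths(st, p)[4]
  st$q[2] <- st$q[2] - 0.3
  expect_lt(muscle_lengths(st, p)[4], l_a)

  # both targets lie inside the reachable annulus
  for (lab in c("left", "bottom")) {
    tg <- reach_target(lab, p)
    d <- sqrt(sum(tg$position^2))
    expect_lt(d, p$l1 + p$l2)
    expect_gt(d, abs(p$l1 - p$l2))
    expect_equal(sqrt(sum((tg$position -
                             hand_position(arm_state(p), p))^2)), 15)
  }
  expect_equal(reach_target("left", p)$duration, 600)
  expect_equal(reach_target("bottom", p)$duration, 500)
})
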