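# Compensation model: desired minimum-jerk trajectory, inverse-dynamics
# feedforward, elastic feedback along the desired trajectory, and adaptation
# as a state-dependent compensation torque.

#' Minimum-jerk position profile
#'
#' Standard fifth-order polynomial `x(t) = D (10u^3 - 15u^4 + 6u^5)`,
#' `u = t/T`, with zero velocity and acceleration at both ends; `t` outside
#' `[0, T]` is clamped to the endpoints. Peak speed is `1.875 D / T`.
#'
#' @param D movement amplitude (m)
#' @param T movement duration (s)
#' @param t time (s); vectorized
#' @param deriv 0 (position), 1 (velocity) or 2 (acceleration)
#' @return profile value(s)
#' @export
minimumJerk <- function(D, T, t, deriv = 0) {
  u <- pmin(pmax(t / T, 0), 1)
  switch(as.character(deriv),
         "0" = D * (10 * u^3 - 15 * u^4 + 6 * u^5),
         "1" = D / T * (30 * u^2 - 60 * u^3 + 30 * u^4),
         "2" = D / T^2 * (60 * u - 180 * u^2 + 120 * u^3),
         stop("deriv must be 0, 1 or 2"))
}

# time derivative of the Jacobian (analytic)
armJacobianDot <- function(theta, thetadot, p) {
  s1 <- sin(theta[1]); c1 <- cos(theta[1])
  s12 <- sin(theta[1] + theta[2]); c12 <- cos(theta[1] + theta[2])
  w1 <- thetadot[1]; w12 <- thetadot[1] + thetadot[2]
  matrix(c(-p$l_sh * c1 * w1 - p$l_el * c12 * w12,
           -p$l_sh * s1 * w1 - p$l_el * s12 * w12,
           -p$l_el * c12 * w12,
           -p$l_el * s12 * w12), 2, 2)
}

#' Desired trajectory of the compensation model
#'
#' A 0.5-s, 0.1-m minimum-jerk hand transport along the straight line to the
#' target, followed by a 0.5-s stationary posture (1 s total). Joint
#' kinematics are obtained analytically through the inverse kinematics and
#' the (inverse) Jacobian; the feedforward torque is the inverse dynamics
#' `tau* = M(theta*) thetaddot* + C(theta*, thetadot*)`.
#'
#' @param p [armParams()]
#' @param geom reach geometry (see [runClosedLoop()] for the default reach)
#' @param T transport duration (s)
#' @param total total duration (s)
#' @return list of functions of time: `theta`, `thetadot`, `thetaddot`,
#'   `tau`, plus `hand(t)` and the durations
#' @export
desiredTrajectory <- function(p = armParams(), geom = reachGeometry(p),
                              T = 0.5, total = 1.0) {
  thetaFn <- function(t) {
    s <- minimumJerk(geom$amplitude, T, t)
    inverseKinematics(geom$start + s * geom$dir, p)
  }
  thetadotFn <- function(t) {
    v <- minimumJerk(geom$amplitude, T, t, 1) * geom$dir
    drop(solve(armJacobian(thetaFn(t), p), v))
  }
  thetaddotFn <- function(t) {
    th <- thetaFn(t); thd <- thetadotFn(t)
    a <- minimumJerk(geom$amplitude, T, t, 2) * geom$dir
    drop(solve(armJacobian(th, p),
               a - armJacobianDot(th, thd, p) %*% thd))
  }
  list(theta = thetaFn, thetadot = thetadotFn, thetaddot = thetaddotFn,
       tau = function(t) inverseDynamics(thetaFn(t), thetadotFn(t),
                                         thetaddotFn(t), p),
       hand = function(t) geom$start + minimumJerk(geom$amplitude, T, t) *
         geom$dir,
       T = T, total = total, geom = geom)
}

#' Inverse dynamics of the arm
#'
#' `tau = M(theta) thetaddot + C(theta, thetadot)` (no gravity in the planar
#' model).
#'
#' @param theta,thetadot,thetaddot desired joint kinematics (rad, rad/s,
#'   rad/s^2)
#' @param p [armParams()]
#' @return 2-vector of joint torques (N m)
#' @export
inverseDynamics <- function(theta, thetadot, thetaddot, p = armParams()) {
  drop(inertiaMatrix(theta, p) %*% thetaddot) +
    coriolisVector(theta, thetadot, p)
}

#' Simulate the compensation model
#'
#' Closed loop `thetaddot = M^-1 (tau* + tau_e + tau_c - B (theta - theta*)
#' - C)` where `tau*` is the inverse-dynamics feedforward along the desired
#' trajectory, `B` an elastic feedback gain along it, `tau_e` the force-field
#' torque and `tau_c` the adapted compensation torque. The four conditions:
#' baseline (`tau_e = tau_c = 0`), before-effect (`tau_e = tau_e^phi`,
#' `tau_c = 0`), adapted (`tau_e = tau_e^phi`, `tau_c = -tau_e^phi`),
#' after-effect (`tau_e = 0`, `tau_c = -tau_e^phi`). The compensation torque
#' is evaluated on the current state (a learned state-to-force mapping), not
#' replayed.
#'
#' @param condition one of `"baseline"`, `"before_effect"`, `"adapted"`,
#'   `"after_effect"`
#' @param f [fieldSpec()] (the field adapted to and/or applied)
#' @param p [armParams()]
#' @param B feedback gain (N m / rad), applied as `B * I_2` when scalar
#' @param delta output sample step (s)
#' @param substeps integration substeps per output sample
#' @return a [reachTrial()] of the hand path with the joint states in
#'   attribute `states`
#' @export
simulateCompensation <- function(condition = c("baseline", "before_effect",
                                               "adapted", "after_effect"),
                                 f = fieldSpec(), p = armParams(),
                                 B = 20, delta = 0.01, substeps = 10) {
  condition <- match.arg(condition)
  if (length(B) == 1) B <- diag(2) * B
  des <- desiredTrajectory(p)
  hasField <- condition %in% c("before_effect", "adapted")
  hasComp <- condition %in% c("adapted", "after_effect")
  Dfield <- fieldMatrix(f)
  deriv <- function(t, s) {
    th <- s[1:2]; w <- s[3:4]
    J <- armJacobian(th, p)
    tau <- des$tau(t) - drop(B %*% (th - des$theta(t))) -
      coriolisVector(th, w, p)
    JDJ <- t(J) %*% Dfield %*% J
    if (hasField) tau <- tau + drop(JDJ %*% w)
    if (hasComp) tau <- tau - drop(JDJ %*% w)
    c(w, solve(inertiaMatrix(th, p), tau))
  }
  n <- round(des$total / delta)
  h <- delta / substeps
  s <- c(des$theta(0), 0, 0)
  states <- matrix(NA_real_, n + 1, 4)
  states[1, ] <- s
  for (k in seq_len(n)) {
    t0 <- (k - 1) * delta
    for (j in seq_len(substeps)) {
      tj <- t0 + (j - 1) * h
      k1 <- deriv(tj, s)
      k2 <- deriv(tj + h / 2, s + h / 2 * k1)
      k3 <- deriv(tj + h / 2, s + h / 2 * k2)
      k4 <- deriv(tj + h, s + h * k3)
      s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (sqrt(sum((s[1:2] - des$theta(k * delta))^2)) > pi / 2)
      stop("compensation simulation diverged from the desired trajectory")
    states[k + 1, ] <- s
  }
  hand <- t(apply(states[, 1:2], 1, forwardKinematics, p = p))
  fieldSign <- if (f$phi > 0) "CCW" else if (f$phi < 0) "CW" else "none"
  trial <- reachTrial((0:n) * delta, hand[, 1], hand[, 2], fs = 1 / delta,
                      category = condition, fieldSign = fieldSign,
                      id = paste0("compensation_", condition))
  attr(trial, "start") <- des$geom$start
  attr(trial, "target") <- des$geom$target
  attr(trial, "states") <- states
  trial
}
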