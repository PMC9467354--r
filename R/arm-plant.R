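#' Two-link planar arm parameters
#'
#' Rigid-body parameters of the simulated planar arm (shoulder at the origin,
#' no gravity). Defaults are anthropomorphic values for an adult arm. The
#' derived constants are `d1 = I_sh + I_el + m_el * l_sh^2`,
#' `d2 = m_el * l_sh * s_el` and `d3 = I_el`.
#'
#' @param m_sh,m_el link masses (kg)
#' @param l_sh,l_el link lengths (m)
#' @param s_sh,s_el joint-to-centre-of-mass distances (m)
#' @param I_sh,I_el link moments of inertia (kg m^2)
#' @param nu muscle time constant (s)
#' @param g_sh,g_el muscle gains (N m per unit activation)
#' @return an object of class `armParams`
#' @export
#' @examples
#' p <- armParams()
#' p$d1  # 0.169 with the default parameters
armParams <- function(m_sh = 1.4, m_el = 1.1, l_sh = 0.3, l_el = 0.33,
                      s_sh = 0.11, s_el = 0.16, I_sh = 0.025, I_el = 0.045,
                      nu = 0.05, g_sh = 2, g_el = 1) {
  vals <- c(m_sh, m_el, l_sh, l_el, s_sh, s_el, I_sh, I_el, nu, g_sh, g_el)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all arm and muscle parameters must be finite and strictly positive")
  p <- list(m_sh = m_sh, m_el = m_el, l_sh = l_sh, l_el = l_el,
            s_sh = s_sh, s_el = s_el, I_sh = I_sh, I_el = I_el,
            nu = nu, g_sh = g_sh, g_el = g_el,
            d1 = I_sh + I_el + m_el * l_sh^2,
            d2 = m_el * l_sh * s_el,
            d3 = I_el)
  class(p) <- "armParams"
  p
}

#' @export
print.armParams <- function(x, ...) {
  cat("Two-link planar arm\n")
  cat(sprintf("  masses   : %.3f, %.3f kg\n", x$m_sh, x$m_el))
  cat(sprintf("  lengths  : %.3f, %.3f m\n", x$l_sh, x$l_el))
  cat(sprintf("  d1,d2,d3 : %.4f, %.4f, %.4f kg m^2\n", x$d1, x$d2, x$d3))
  cat(sprintf("  muscles  : nu = %.3f s, gains = %.2f, %.2f\n",
              x$nu, x$g_sh, x$g_el))
  invisible(x)
}

# parameter vector handed to the compiled core
parVec <- function(p) c(p$d1, p$d2, p$d3, p$nu, p$g_sh, p$g_el, p$l_sh, p$l_el)

#' Arm inertia matrix
#'
#' @param theta joint angles `c(theta_sh, theta_el)` in radians
#' @param p [armParams()]
#' @return symmetric 2x2 inertia matrix (kg m^2)
#' @export
inertiaMatrix <- function(theta, p = armParams()) {
  c2 <- cos(theta[2])
  matrix(c(p$d1 + 2 * p$d2 * c2, p$d3 + p$d2 * c2,
           p$d3 + p$d2 * c2, p$d3), 2, 2)
}

#' Velocity-dependent (Coriolis/centripetal) joint torques
#'
#' @param theta joint angles (rad)
#' @param thetadot joint velocities (rad/s)
#' @param p [armParams()]
#' @return 2-vector of torques (N m)
#' @export
coriolisVector <- function(theta, thetadot, p = armParams()) {
  p$d2 * c(2 * thetadot[1] * thetadot[2] + thetadot[2]^2,
           -thetadot[1]^2) * sin(theta[2])
}

#' Jacobian of the hand kinematics
#'
#' Maps joint velocities to hand velocities.
#'
#' @inheritParams inertiaMatrix
#' @return 2x2 Jacobian (m)
#' @export
armJacobian <- function(theta, p = armParams()) {
  s1 <- sin(theta[1]); c1 <- cos(theta[1])
  s12 <- sin(theta[1] + theta[2]); c12 <- cos(theta[1] + theta[2])
  matrix(c(-p$l_sh * s1 - p$l_el * s12, p$l_sh * c1 + p$l_el * c12,
           -p$l_el * s12, p$l_el * c12), 2, 2)
}

#' Forward kinematics of the hand
#'
#' @inheritParams inertiaMatrix
#' @return hand position `c(x, y)` in metres, shoulder at the origin
#' @export
forwardKinematics <- function(theta, p = armParams()) {
  c(p$l_sh * cos(theta[1]) + p$l_el * cos(theta[1] + theta[2]),
    p$l_sh * sin(theta[1]) + p$l_el * sin(theta[1] + theta[2]))
}

#' Inverse kinematics of the hand
#'
#' Returns the elbow-up solution (`theta_el > 0`) by default, consistent with
#' the initial configuration `[45, 90]` degrees used throughout.
#'
#' @param pos hand position `c(x, y)` (m)
#' @param p [armParams()]
#' @param elbowUp logical; choose the positive-elbow branch
#' @return joint angles (rad)
#' @export
#' @examples
#' th <- inverseKinematics(forwardKinematics(deg2rad(c(45, 90))) + c(0, 0.1))
#' round(th * 180 / pi, 1)  # 60.7 60.0
inverseKinematics <- function(pos, p = armParams(), elbowUp = TRUE) {
  r2 <- sum(pos^2)
  r <- sqrt(r2)
  if (r > p$l_sh + p$l_el + 1e-12 || r < abs(p$l_sh - p$l_el) - 1e-12)
    stop("unreachable target: |pos| outside the arm workspace")
  ce <- (r2 - p$l_sh^2 - p$l_el^2) / (2 * p$l_sh * p$l_el)
  ce <- min(1, max(-1, ce))
  th_el <- acos(ce)
  if (!elbowUp) th_el <- -th_el
  th_sh <- atan2(pos[2], pos[1]) -
    atan2(p$l_el * sin(th_el), p$l_sh + p$l_el * cos(th_el))
  c(th_sh, th_el)
}

#' Degree/radian conversion
#'
#' @param x angle(s)
#' @return converted angle(s)
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * 180 / pi

#' Curl force-field specification
#'
#' A velocity-dependent force field producing a force proportional to the hand
#' velocity along the movement direction `psi` and perpendicular to it.
#' `phi > 0` is a counterclockwise perturbation, `phi < 0` clockwise.
#'
#' @param phi field level (N s/m)
#' @param psi movement direction in degrees (0 is rightward, measured from the
#'   initial hand position)
#' @return an object of class `fieldSpec`
#' @export
fieldSpec <- function(phi = 2, psi = 90) {
  stopifnot(is.finite(phi), is.finite(psi))
  structure(list(phi = phi, psi = psi), class = "fieldSpec")
}

#' @export
print.fieldSpec <- function(x, ...) {
  cat(sprintf("curl field: phi = %g N s/m (%s), psi = %g deg\n", x$phi,
              if (x$phi >= 0) "CCW" else "CW", x$psi))
  invisible(x)
}

#' Hand-space force-field matrix
#'
#' `D = R(psi)^-1 [[0, 0], [phi, 0]] R(psi)` so that a hand velocity exactly
#' along `psi` yields a force perpendicular to it with magnitude
#' `|phi| * speed`.
#'
#' @param f a [fieldSpec()]
#' @return 2x2 matrix (N s/m)
#' @export
fieldMatrix <- function(f) {
  a <- deg2rad(f$psi)
  R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
  solve(R) %*% matrix(c(0, f$phi, 0, 0), 2, 2) %*% R
}

zeroField <- function() matrix(0, 2, 2)

#' Perturbation torque of the force field
#'
#' `tau_e = J(theta)^T D J(theta) thetadot`.
#'
#' @param theta joint angles (rad)
#' @param thetadot joint velocities (rad/s)
#' @param f a [fieldSpec()]
#' @param p [armParams()]
#' @return 2-vector of joint torques (N m)
#' @export
fieldTorque <- function(theta, thetadot, f, p = armParams()) {
  J <- armJacobian(theta, p)
  drop(t(J) %*% fieldMatrix(f) %*% J %*% thetadot)
}

#' Joint accelerations of the arm
#'
#' `thetaddot = M(theta)^-1 (tau_u + tau_e - C(theta, thetadot))`; the planar
#' model has no gravity term.
#'
#' @param theta,thetadot joint state (rad, rad/s)
#' @param tau_u control torque (N m)
#' @param tau_e external (perturbation) torque (N m)
#' @param p [armParams()]
#' @return 2-vector of joint accelerations (rad/s^2)
#' @export
armAccel <- function(theta, thetadot, tau_u = c(0, 0), tau_e = c(0, 0),
                     p = armParams()) {
  M <- inertiaMatrix(theta, p)
  drop(solve(M, tau_u + tau_e - coriolisVector(theta, thetadot, p)))
}

# initial joint configuration and the standard reach geometry
reachGeometry <- function(p = armParams(), amplitude = 0.1, psi = 90,
                          theta0deg = c(45, 90)) {
  theta0 <- deg2rad(theta0deg)
  start <- forwardKinematics(theta0, p)
  dir <- c(cos(deg2rad(psi)), sin(deg2rad(psi)))
  target <- start + amplitude * dir
  list(theta0 = theta0, start = start, target = target, dir = dir,
       amplitude = amplitude, psi = psi)
}
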