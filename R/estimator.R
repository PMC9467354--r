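# Delay-aware optimal state estimation: forward model + delayed sensory
# feedback + Kalman gain. Two treatments of the delay are provided:
#  - "literal": the innovation compares the delayed observation y(t - Delta)
#    with the *current* estimate H X^(t);
#  - "delay" (default): a filter runs at lag Delta, assimilating each
#    observation against the time-matched estimate, and the current estimate
#    is obtained by forward-predicting over the delay with buffered controls.

#' Noise specification of the estimator
#'
#' Sensory covariance `Omega_w = sigma_w * diag(1, 1, 10, 10)` (position and
#' velocity observed) and motor covariance
#' `Omega_xi = sigma_xi * diag(1, 1, 10, 10, 100, 100, 1000, 1000)`. With
#' `units = "deg"` (the default) the kinematic diagonal entries are read in
#' degree units and converted to the radian state internally, i.e. a 1-deg
#' position standard deviation and a sqrt(10) deg/s velocity standard
#' deviation at `sigma_w = 1` -- physiologically plausible sensory noise.
#' With `units = "rad"` the entries are taken in radian units verbatim
#' (a 57-deg position standard deviation), which makes the filter nearly
#' ignore its sensors.
#'
#' @param sigma_w sensory noise variance scale (> 0)
#' @param sigma_xi motor noise variance scale (>= 0)
#' @param units unit of the kinematic covariance entries
#' @return object of class `noiseSpec`
#' @export
noiseSpec <- function(sigma_w = 1, sigma_xi = 1,
                      units = c("deg", "rad")) {
  units <- match.arg(units)
  if (sigma_w <= 0) stop("sigma_w must be > 0 (the gain inverts it)")
  if (sigma_xi < 0) stop("sigma_xi must be >= 0")
  sc <- if (units == "deg") (pi / 180)^2 else 1
  structure(list(sigma_w = sigma_w, sigma_xi = sigma_xi, units = units,
                 Omega_w = sigma_w * sc * diag(c(1, 1, 10, 10)),
                 Omega_xi = sigma_xi * diag(c(sc * c(1, 1, 10, 10),
                                              100, 100, 1000, 1000))),
            class = "noiseSpec")
}

#' Observe position and velocity of the full state
#'
#' `y = H X + n_obs` with `H = [I_4 O_4]`: only joint positions and
#' velocities are observed. With `noise = NULL` (the deterministic mode used
#' for model predictions) the observation is exact.
#'
#' @param X full state (8-vector)
#' @param noise a [noiseSpec()] or `NULL` for the zero-noise mode
#' @return 4-vector observation
#' @export
observeState <- function(X, noise = NULL) {
  y <- X[1:4]
  if (!is.null(noise))
    y <- y + rnorm(4, sd = sqrt(diag(noise$Omega_w)))
  y
}

#' Create (and prime) an estimator
#'
#' Movements start from rest, so the delay buffers are primed with the
#' resting observation and zero control: during the first `Delta` seconds
#' the filter sees a stationary history and the innovation vanishes.
#'
#' @param x0 initial full state
#' @param Fhat internal model from [assembleDynamics()]
#' @param delay feedback delay (s)
#' @param delta control step (s)
#' @param mode `"delay"` or `"literal"`
#' @param noise [noiseSpec()] providing the covariances of the gain
#' @return object of class `stateEstimator`
#' @export
estimatorInit <- function(x0, Fhat, delay = 0.12, delta = 0.01,
                          mode = c("delay", "literal"),
                          noise = noiseSpec()) {
  mode <- match.arg(mode)
  d <- round(delay / delta)
  est <- list(Xhat = x0, Xlag = x0, P = noise$Omega_xi,
              Plag = noise$Omega_xi, mode = mode, d = d, delta = delta,
              par = attr(Fhat, "par"), D = attr(Fhat, "D"), noise = noise,
              ybuf = NULL, ubuf = NULL)
  class(est) <- "stateEstimator"
  primeDelayBuffer(est, x0)
}

#' Prime the delay buffers with a resting history
#'
#' Fills the observation and control buffers (length `round(Delta/delta)`)
#' with the resting observation of `x0` and zero control.
#'
#' @param est a `stateEstimator`
#' @param x0 resting state
#' @return the primed estimator
#' @export
primeDelayBuffer <- function(est, x0) {
  est$ybuf <- matrix(rep(x0[1:4], max(est$d, 0)), nrow = 4)
  est$ubuf <- matrix(0, 2, max(est$d, 0))
  est
}

# discrete gain/covariance recursion: K = A P H' (H P H' + Omega_w)^-1,
# P <- Omega_xi + (A - K H) P A', then symmetrized; A is the Jacobian of the
# one-step flow, so the recursion is the standard discrete Riccati iteration
kalmanUpdate <- function(X, P, u, par, D, noise, delta) {
  A <- .linearizeCpp(X, u, par, D, delta)$A
  PH <- P[, 1:4, drop = FALSE]
  S <- PH[1:4, ] + noise$Omega_w
  K <- A %*% PH %*% solve(S)
  AmKH <- A
  AmKH[, 1:4] <- AmKH[, 1:4] - K
  Pn <- noise$Omega_xi + AmKH %*% P %*% t(A)
  Pn <- (Pn + t(Pn)) / 2
  if (!all(is.finite(Pn)))
    stop("estimator covariance became non-finite")
  list(K = K, P = Pn, A = A)
}

#' Advance the estimator by one control step
#'
#' Consumes the control applied at the current step and the current
#' observation, and returns the estimator holding the state estimate for the
#' next step. The estimate advances by the internal forward model plus the
#' Kalman innovation correction (delayed per the configured mode).
#'
#' @param est a `stateEstimator`
#' @param u control applied at this step (2-vector)
#' @param y current observation (4-vector)
#' @return the advanced estimator (field `Xhat` is the new estimate)
#' @export
estimatorStep <- function(est, u, y) {
  delta <- est$delta
  stepF <- function(X, uu) as.numeric(
    .stepDynamicsCpp(X, uu, est$par, est$D, delta, 1L))
  if (est$mode == "literal") {
    ydel <- if (est$d > 0) est$ybuf[, 1] else y
    up <- kalmanUpdate(est$Xhat, est$P, u, est$par, est$D, est$noise, delta)
    innov <- ydel - est$Xhat[1:4]
    est$Xhat <- stepF(est$Xhat, u) + as.numeric(up$K %*% innov)
    est$P <- up$P
    if (est$d > 0)
      est$ybuf <- cbind(est$ybuf[, -1, drop = FALSE], y)
  } else {
    if (est$d > 0) {
      uold <- est$ubuf[, 1]
      ydel <- est$ybuf[, 1]
      up <- kalmanUpdate(est$Xlag, est$Plag, uold, est$par, est$D, est$noise,
                         delta)
      innov <- ydel - est$Xlag[1:4]
      est$Xlag <- stepF(est$Xlag, uold) + as.numeric(up$K %*% innov)
      est$Plag <- up$P
      # slide the buffers and forward-predict across the delay
      est$ubuf <- cbind(est$ubuf[, -1, drop = FALSE], u)
      est$ybuf <- cbind(est$ybuf[, -1, drop = FALSE], y)
      Xp <- est$Xlag
      for (j in seq_len(est$d)) Xp <- stepF(Xp, est$ubuf[, j])
      est$Xhat <- Xp
    } else {
      up <- kalmanUpdate(est$Xhat, est$P, u, est$par, est$D, est$noise,
                         delta)
      innov <- y - est$Xhat[1:4]
      est$Xhat <- stepF(est$Xhat, u) + as.numeric(up$K %*% innov)
      est$P <- up$P
    }
  }
  est
}
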