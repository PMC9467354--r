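# Receding-horizon optimal feedback control: second-order muscle model,
# via-point goal scheduling, iLQR in regulator form, closed loop.

#' One step of the linear second-order muscle model
#'
#' Integrates `nu * dalpha = -alpha + epsilon`, `nu * depsilon = -epsilon + u`
#' exactly over `delta` (zero-order-hold input) and returns the produced
#' torques `tau_i = g_i * alpha_i`.
#'
#' @param alpha,epsilon activation and excitation (2-vectors)
#' @param u control input (2-vector)
#' @param p [armParams()] (supplies `nu` and the gains)
#' @param delta timestep (s)
#' @return list with `alpha`, `epsilon`, `tau`
#' @export
muscleStep <- function(alpha, epsilon, u, p = armParams(), delta = 0.01) {
  stopifnot(delta > 0)
  e <- exp(-delta / p$nu)
  alpha1 <- u + e * (alpha - u) + (delta / p$nu) * e * (epsilon - u)
  epsilon1 <- u + e * (epsilon - u)
  list(alpha = alpha1, epsilon = epsilon1,
       tau = c(p$g_sh, p$g_el) * alpha1)
}

#' Assemble the full-state dynamics
#'
#' Stacks the arm dynamics over the muscle model into the 8-state derivative
#' `Xdot = F(X, u)`, `X = [theta, thetadot, alpha, epsilon]`, either
#' unperturbed (`F_0`) or with the force-field torque included (`F_phi`).
#' The returned function is deterministic; the models are simulated without
#' noise.
#'
#' @param model `"F0"` or `"Fphi"`
#' @param p [armParams()]
#' @param f [fieldSpec()] used when `model = "Fphi"`
#' @return a function `(X, u) -> Xdot` carrying attributes `par` and `D`
#'   consumed by [linearizeDynamics()] and [ilqrSolve()]
#' @export
assembleDynamics <- function(model = c("F0", "Fphi"), p = armParams(),
                             f = fieldSpec()) {
  model <- match.arg(model)
  D <- if (model == "Fphi") fieldMatrix(f) else zeroField()
  par <- parVec(p)
  fn <- function(X, u) as.numeric(.armDynamicsCpp(X, u, par, D))
  attr(fn, "par") <- par
  attr(fn, "D") <- D
  attr(fn, "model") <- model
  class(fn) <- c("armDynamics", "function")
  fn
}

#' Discrete linearization of the dynamics
#'
#' Central finite-difference Jacobians of the one-step (`delta`) RK4 flow:
#' `A_d = I + delta * dF/dX + O(delta^2)`.
#'
#' @param F dynamics from [assembleDynamics()]
#' @param X,u linearization point
#' @param delta timestep (s)
#' @return list with `A` (8x8) and `B` (8x2)
#' @export
linearizeDynamics <- function(F, X, u = c(0, 0), delta = 0.01) {
  out <- .linearizeCpp(X, u, attr(F, "par"), attr(F, "D"), delta)
  if (!all(is.finite(out$A)) || !all(is.finite(out$B)))
    stop("non-finite Jacobian entries in linearization")
  out
}

#' Via-point goal series
#'
#' An ordered series of goal states ending at the final goal. Intermediate
#' via-points sit at fractions of the movement amplitude along the target
#' direction, optionally displaced laterally (`offsets`, metres,
#' counterclockwise side of the target direction positive); the active goal
#' at time `t` is element `min(floor(t / T_G), n)`.
#'
#' @param fractions fractions of the distance to the target for the
#'   intermediate via-points
#' @param offsets lateral offsets of the intermediate via-points (m)
#' @param T_G goal switch period (s)
#' @param p [armParams()]
#' @param geom reach geometry (start, target, direction); defaults to the
#'   standard 0.1-m forward reach from `[45, 90]` degrees
#' @return object of class `viaPointSeries`: joint-space goal matrix
#'   (8 x nGoals, final goal last), hand positions, `T_G`
#' @export
viaPointSeries <- function(fractions = c(0.32, 0.64, 0.96),
                           offsets = rep(0, length(fractions)),
                           T_G = 0.13, p = armParams(),
                           geom = reachGeometry(p)) {
  stopifnot(length(offsets) == length(fractions), T_G > 0)
  perp <- c(-geom$dir[2], geom$dir[1])
  pts <- cbind(
    sapply(seq_along(fractions), function(i)
      geom$start + fractions[i] * geom$amplitude * geom$dir +
        offsets[i] * perp),
    geom$target)
  goals <- apply(pts, 2, function(pos)
    c(inverseKinematics(pos, p), rep(0, 6)))
  structure(list(goals = goals, positions = pts, T_G = T_G,
                 fractions = fractions, offsets = offsets, geom = geom),
            class = "viaPointSeries")
}

#' @export
print.viaPointSeries <- function(x, ...) {
  cat(sprintf("via-point series: %d intermediate + final, T_G = %g s\n",
              ncol(x$goals) - 1, x$T_G))
  cat("  lateral offsets (mm):",
      paste(sprintf("%.1f", 1000 * x$offsets), collapse = ", "), "\n")
  invisible(x)
}

#' Controller and estimator parameters
#'
#' Defaults are the standard operating point of the reoptimization model:
#' planning horizon 0.28 s, goal switch period 0.13 s, control step 0.01 s,
#' control weight 1e-5, final-goal weights 10 (position), 0.1 (velocity),
#' 0.01 (activation and excitation), position-only constraints at
#' intermediate via-points, sensory delay 0.12 s, unit noise variances.
#'
#' @param T_H planning horizon (s)
#' @param T_G goal switch period (s)
#' @param delta control step (s)
#' @param w_u control weight
#' @param boundary via-point boundary-condition preset: `"p"` constrains
#'   position only, `"pv"` adds velocity, `"pva"` activation, `"pvae"`
#'   excitation
#' @param delay sensory feedback delay (s)
#' @param sigma_w,sigma_xi sensory and motor noise variance scales used by
#'   the estimator's covariances
#' @param noiseUnits unit convention of the kinematic covariance entries
#'   (see [noiseSpec()])
#' @param estMode `"delay"` (delay-compensated; default), `"literal"`
#'   (delayed innovation against the current estimate, the letter of the
#'   printed filter) or `"perfect"` (true-state feedback)
#' @param goalSchedule `"deadline"` (each goal designated at `j * T_G` has a
#'   fixed arrival deadline `j * T_G + T_H`; every pending deadline inside
#'   the horizon is penalized, and the final goal keeps a receding
#'   horizon-end cost once designated, so movement duration is
#'   `n * T_G + T_H` with flexible time under perturbations), `"current"`
#'   (only the currently scheduled goal, penalized at the horizon end,
#'   which recedes at every step) or `"fixed_arrival"` (only the current
#'   goal, with its arrival time frozen when it is designated)
#' @param duration simulated duration (s)
#' @param replanEvery re-solve the iLQR every this many control steps
#' @param maxit,tol iLQR iteration cap and relative-improvement tolerance
#' @param plantSubsteps plant integration substeps per control step (10
#'   emulates 1000-Hz recordings)
#' @return object of class `ofcParams`
#' @export
ofcParams <- function(T_H = 0.28, T_G = 0.13, delta = 0.01, w_u = 1e-5,
                      boundary = c("p", "pv", "pva", "pvae"), delay = 0.12,
                      sigma_w = 1, sigma_xi = 1,
                      noiseUnits = c("deg", "rad"),
                      estMode = c("delay", "literal", "perfect"),
                      goalSchedule = c("fixed_arrival", "deadline",
                                       "current"),
                      duration = 1.0, replanEvery = 1L, maxit = 100L,
                      tol = 1e-8, plantSubsteps = 1L) {
  boundary <- match.arg(boundary)
  estMode <- match.arg(estMode)
  goalSchedule <- match.arg(goalSchedule)
  noiseUnits <- match.arg(noiseUnits)
  if (!(T_H > T_G && T_G > delta && delta > 0))
    stop("need T_H > T_G > delta > 0")
  if (sigma_w <= 0) stop("sigma_w must be positive (gain inversion)")
  if (sigma_xi < 0) stop("sigma_xi must be non-negative")
  wFinal <- c(10, 10, 0.1, 0.1, 0.01, 0.01, 0.01, 0.01)
  wVia <- c(10, 10, 0, 0, 0, 0, 0, 0)
  if (boundary %in% c("pv", "pva", "pvae")) wVia[3:4] <- 0.1
  if (boundary %in% c("pva", "pvae")) wVia[5:6] <- 0.01
  if (boundary == "pvae") wVia[7:8] <- 0.01
  structure(list(T_H = T_H, T_G = T_G, delta = delta, w_u = w_u,
                 boundary = boundary, wVia = wVia, wFinal = wFinal,
                 delay = delay, sigma_w = sigma_w, sigma_xi = sigma_xi,
                 noiseUnits = noiseUnits,
                 estMode = estMode, goalSchedule = goalSchedule,
                 duration = duration,
                 replanEvery = as.integer(replanEvery),
                 maxit = as.integer(maxit), tol = tol,
                 plantSubsteps = as.integer(plantSubsteps)),
            class = "ofcParams")
}

restState <- function(theta) c(theta, rep(0, 6))

#' Solve one finite-horizon optimal control problem by iLQR
#'
#' Minimizes `sum w_u * |u|^2 * delta` plus a terminal quadratic penalty
#' `(X_N - goal)' diag(w) (X_N - goal)` for the nonlinear arm + muscle
#' dynamics, using iterative LQR with Levenberg-style regularization and a
#' backtracking line search; accepted iterations have non-increasing cost.
#'
#' @param x0 initial full state (8-vector)
#' @param goal goal state (8-vector)
#' @param w terminal weights (8-vector)
#' @param horizon number of control steps
#' @param F dynamics from [assembleDynamics()]
#' @param w_u control weight
#' @param delta control step (s)
#' @param Uinit optional warm-start control sequence (2 x horizon)
#' @param maxit,tol iteration cap and relative cost-improvement tolerance
#' @return object of class `controlPolicy`: nominal states `X`
#'   ((horizon+1) x 8), controls `U` (horizon x 2), feedback gains `K`,
#'   `cost`, `iters`, `converged`
#' @export
ilqrSolve <- function(x0, goal, w, horizon, F, w_u = 1e-5, delta = 0.01,
                      Uinit = NULL, maxit = 100, tol = 1e-8) {
  stopifnot(horizon >= 1)
  if (is.null(Uinit)) Uinit <- matrix(0, 2, horizon)
  r <- .ilqrCpp(x0, goal, w, w_u, as.integer(horizon), delta,
                attr(F, "par"), attr(F, "D"), Uinit,
                as.integer(maxit), tol)
  if (!r$converged)
    warning("iLQR did not converge within ", maxit,
            " iterations; returning best solution found")
  r$X <- t(r$X)
  r$U <- t(r$U)
  class(r) <- "controlPolicy"
  r
}

#' @export
print.controlPolicy <- function(x, ...) {
  cat(sprintf("iLQR policy: %d steps, cost %.6g, %d iterations%s\n",
              nrow(x$U), x$cost, x$iters,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Run the receding-horizon closed loop
#'
#' At every control step the current goal is read from the via-point series,
#' the iLQR problem is re-solved from the estimated state over the planning
#' horizon using the controller's internal model, the first control is
#' applied to the plant, and the delayed estimator advances. The horizon
#' persists past the last goal switch, so perturbations mid-movement still
#' end near the final goal (time flexibility).
#'
#' @param S [viaPointSeries()]
#' @param params [ofcParams()]
#' @param p [armParams()]
#' @param phiPlant,phiCtrl,phiEst force-field level (N s/m) of the true
#'   plant, the controller's internal model and the estimator's internal
#'   model respectively
#' @param psi movement direction (deg)
#' @param x0 initial full state; defaults to rest at the series' start
#'   configuration
#' @return list with `trial` (a [reachTrial()] of the hand path), `t`,
#'   `states`, `estimates`, `controls`, `goalIndex` and solver diagnostics
#' @export
runClosedLoop <- function(S, params = ofcParams(), p = armParams(),
                          phiPlant = 0, phiCtrl = 0, phiEst = 0, psi = 90,
                          x0 = NULL) {
  geom <- S$geom
  if (is.null(x0)) x0 <- restState(geom$theta0)
  nGoals <- ncol(S$goals)
  if (params$duration < nGoals * S$T_G)
    stop("duration must cover every goal switch ((n+1) * T_G)")
  stepsPerGoal <- round(S$T_G / params$delta)
  NH <- round(params$T_H / params$delta)
  nSteps <- round(params$duration / params$delta)
  delaySteps <- round(params$delay / params$delta)
  estMode <- match(params$estMode, c("perfect", "literal", "delay")) - 1L
  Dm <- function(phi) if (phi == 0) zeroField()
                      else fieldMatrix(fieldSpec(phi, psi))
  ns <- noiseSpec(params$sigma_w, params$sigma_xi, params$noiseUnits)
  r <- .closedLoopCpp(x0, S$goals, params$wVia, params$wFinal, params$w_u,
                      as.integer(stepsPerGoal), as.integer(NH), params$delta,
                      as.integer(nSteps), parVec(p), Dm(phiPlant),
                      Dm(phiCtrl), Dm(phiEst), estMode,
                      as.integer(delaySteps), diag(ns$Omega_w),
                      diag(ns$Omega_xi), params$replanEvery, params$maxit,
                      params$tol, params$plantSubsteps,
                      match(params$goalSchedule,
                            c("deadline", "current", "fixed_arrival")) - 1L)
  fieldSign <- if (phiPlant > 0 || (phiPlant == 0 && phiCtrl > 0)) "CCW"
               else if (phiPlant < 0 || phiCtrl < 0) "CW"
               else "none"
  trial <- reachTrial(r$handT, r$handX, r$handY,
                      fs = params$plantSubsteps / params$delta,
                      fieldSign = fieldSign)
  attr(trial, "start") <- geom$start
  attr(trial, "target") <- geom$target
  list(trial = trial, t = as.numeric(r$t), states = r$X, estimates = r$Xhat,
       controls = r$U, goalIndex = as.integer(r$goalIndex),
       ilqrIters = r$ilqrIters, notConverged = r$notConverged)
}
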