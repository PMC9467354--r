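# Orchestration of the twelve model x condition combinations, via-point
# refitting for the redirection model, ensembles, predicted metrics and
# parameter sweeps.

conditionLevels <- c("baseline", "before_effect", "adapted", "after_effect")

#' Specify a model/condition combination
#'
#' Exactly twelve combinations are legal: each of the three models in each of
#' the four conditions. The wiring (which of the plant, the controller's cost
#' model and the estimator's internal model see the field, and which
#' via-point series is used) is derived here:
#' \describe{
#'   \item{compensation}{desired-trajectory controller;
#'     adaptation = compensation torque.}
#'   \item{reoptimization}{baseline: all unperturbed; before-effect:
#'     perturbed plant, unperturbed controller and estimator; adapted:
#'     everything tuned to the field; after-effect: unperturbed plant,
#'     controller and estimator still tuned to the field. The same via-point
#'     series `S` in all conditions.}
#'   \item{redirection}{baseline and before-effect as reoptimization;
#'     adapted and after-effect keep controller and estimator unaware of the
#'     field but replace `S` by the remapped series `S'`.}
#' }
#'
#' @param model `"compensation"`, `"reoptimization"` or `"redirection"`
#' @param condition `"baseline"`, `"before_effect"`, `"adapted"` or
#'   `"after_effect"`
#' @param phi field level (N s/m); sign gives the perturbation direction
#' @param psi movement direction (deg)
#' @param S via-point series used for baseline/before-effect (and all
#'   reoptimization conditions)
#' @param Sprime remapped series for the redirection model's adapted and
#'   after-effect conditions (required there)
#' @return object of class `conditionSpec`
#' @export
conditionSpec <- function(model = c("reoptimization", "compensation",
                                    "redirection"),
                          condition = conditionLevels, phi = 2, psi = 90,
                          S = viaPointSeries(), Sprime = NULL) {
  model <- match.arg(model)
  condition <- match.arg(condition)
  spec <- list(model = model, condition = condition, phi = phi, psi = psi,
               S = S, Sprime = Sprime)
  if (model == "redirection" &&
      condition %in% c("adapted", "after_effect") && is.null(Sprime))
    stop("redirection ", condition, " requires the remapped series Sprime")
  wire <- switch(model,
    compensation = NULL,
    reoptimization = switch(condition,
      baseline = list(plant = 0, ctrl = 0, est = 0, series = "S"),
      before_effect = list(plant = phi, ctrl = 0, est = 0, series = "S"),
      adapted = list(plant = phi, ctrl = phi, est = phi, series = "S"),
      after_effect = list(plant = 0, ctrl = phi, est = phi, series = "S")),
    redirection = switch(condition,
      baseline = list(plant = 0, ctrl = 0, est = 0, series = "S"),
      before_effect = list(plant = phi, ctrl = 0, est = 0, series = "S"),
      adapted = list(plant = phi, ctrl = 0, est = 0, series = "Sprime"),
      after_effect = list(plant = 0, ctrl = 0, est = 0, series = "Sprime")))
  spec$wiring <- wire
  class(spec) <- "conditionSpec"
  spec
}

#' @export
print.conditionSpec <- function(x, ...) {
  cat(sprintf("%s / %s, phi = %g N s/m, psi = %g deg\n", x$model,
              x$condition, x$phi, x$psi))
  invisible(x)
}

#' Simulate one model/condition combination
#'
#' Dispatches to [simulateCompensation()] or [runClosedLoop()] with the
#' wiring implied by the specification; the returned trial is tagged with
#' the condition category and the participant-level field direction.
#'
#' @param spec a [conditionSpec()]
#' @param params [ofcParams()] (ignored by the compensation model)
#' @param p [armParams()]
#' @return a [reachTrial()]; closed-loop runs attach the full result in
#'   attribute `loop`
#' @export
runCondition <- function(spec, params = ofcParams(), p = armParams()) {
  stopifnot(inherits(spec, "conditionSpec"))
  fieldSign <- if (spec$phi > 0) "CCW" else if (spec$phi < 0) "CW" else "none"
  if (spec$model == "compensation") {
    trial <- simulateCompensation(spec$condition,
                                  fieldSpec(spec$phi, spec$psi), p)
    attr(trial, "fieldSign") <- fieldSign
    return(trial)
  }
  S <- if (spec$wiring$series == "S") spec$S else spec$Sprime
  r <- runClosedLoop(S, params, p, phiPlant = spec$wiring$plant,
                     phiCtrl = spec$wiring$ctrl, phiEst = spec$wiring$est,
                     psi = spec$psi)
  trial <- r$trial
  attr(trial, "category") <- spec$condition
  attr(trial, "fieldSign") <- fieldSign
  attr(trial, "id") <- paste(spec$model, spec$condition, sep = "_")
  attr(trial, "loop") <- r[setdiff(names(r), "trial")]
  trial
}

#' Fit a remapped via-point series to a reference trajectory
#'
#' Greedy deterministic grid search, one via-point at a time from proximal to
#' distal: each intermediate via-point's lateral offset is chosen on a fixed
#' grid to minimize the summed hand-path distance between the simulated
#' trajectory (under the given wiring) and the reference trajectory.
#' Fitting the adapted condition (perturbed plant, unaware controller)
#' against the simulated baseline yields the redirection model's `S'`.
#'
#' @param reference a [reachTrial()] to match (e.g. the simulated baseline)
#' @param spec a [conditionSpec()] whose via-point series is refitted (its
#'   `S` provides fractions and `T_G`; offsets are searched)
#' @param grid candidate lateral offsets (m)
#' @param params,p simulation parameters
#' @return the fitted [viaPointSeries()] with attribute `objective`
#' @export
fitViaPoints <- function(reference, spec,
                         grid = seq(-0.03, 0.03, by = 0.001),
                         params = ofcParams(), p = armParams()) {
  if (!length(grid)) stop("empty candidate grid")
  nVia <- length(spec$S$fractions)
  offsets <- rep(0, nVia)
  objective <- function(off) {
    S2 <- viaPointSeries(spec$S$fractions, off, spec$S$T_G, p,
                         spec$S$geom)
    spec2 <- spec
    if (spec$wiring$series == "S") spec2$S <- S2 else spec2$Sprime <- S2
    sim <- runCondition(spec2, params, p)
    nn <- min(nrow(sim), nrow(reference))
    sum(sqrt((sim$x[1:nn] - reference$x[1:nn])^2 +
             (sim$y[1:nn] - reference$y[1:nn])^2))
  }
  best <- Inf
  for (j in seq_len(nVia)) {
    vals <- vapply(grid, function(g) {
      off <- offsets; off[j] <- g; objective(off)
    }, numeric(1))
    offsets[j] <- grid[which.min(vals)]
    best <- min(vals)
  }
  out <- viaPointSeries(spec$S$fractions, offsets, spec$S$T_G, p,
                        spec$S$geom)
  attr(out, "objective") <- best
  out
}

#' Generate an ensemble of trials with via-point jitter
#'
#' Runs the specified condition `n` times with independent Gaussian jitter
#' (standard deviation `sigma_vp`, both coordinates) added to the
#' intermediate via-point hand positions; seeded and reproducible.
#'
#' @param spec a [conditionSpec()]
#' @param sigma_vp via-point jitter standard deviation (m)
#' @param n number of trials
#' @param seed RNG seed
#' @param params,p simulation parameters
#' @return list of [reachTrial()] objects
#' @export
ensembleTrials <- function(spec, sigma_vp = 0.003, n = 20, seed = 1,
                           params = ofcParams(), p = armParams()) {
  stopifnot(n >= 1)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    spec2 <- spec
    slot <- if (!is.null(spec$wiring) && spec$wiring$series == "Sprime")
      "Sprime" else "S"
    S <- spec2[[slot]]
    nVia <- length(S$fractions)
    jx <- rnorm(nVia, sd = sigma_vp)
    jy <- rnorm(nVia, sd = sigma_vp)
    spec2[[slot]] <- jitterViaSeries(S, jx, jy, p)
    tr <- runCondition(spec2, params, p)
    attr(tr, "id") <- paste0(attr(tr, "id"), "_", i)
    tr
  })
}

# displace the intermediate via-point hand positions and rebuild the joint
# goals; the final goal is left untouched
jitterViaSeries <- function(S, jx, jy, p = armParams()) {
  pts <- S$positions
  nVia <- ncol(pts) - 1
  pts[1, seq_len(nVia)] <- pts[1, seq_len(nVia)] + jx
  pts[2, seq_len(nVia)] <- pts[2, seq_len(nVia)] + jy
  goals <- apply(pts, 2, function(pos) c(inverseKinematics(pos, p),
                                         rep(0, 6)))
  S$goals <- goals
  S$positions <- pts
  S
}

#' Predicted metrics of a simulated trajectory
#'
#' Mirrors the trial to the display convention (clockwise deviation), computes
#' the trajectory-angle derivative, and reports the first sign change of the
#' derivative together with the fraction of the analysis window spent
#' negative and positive.
#'
#' A sign change is only scored when the opposite sign persists for at least
#' `minRun` consecutive samples, so single-sample numerical dips near zero
#' do not register as crossings.
#'
#' @param trial a [reachTrial()]
#' @param window analysis window from movement onset (s)
#' @param cutoff low-pass cutoff (Hz)
#' @param minRun persistence (samples) required to score a sign change
#' @return list with `tSignChange` (s; `NA` when the derivative never
#'   changes sign), `initialSign`, `pctNegative`, `pctPositive` (% of window
#'   timesteps), and the angle series
#' @export
predictedMetrics <- function(trial, window = 0.4, cutoff = 10, minRun = 3) {
  disp <- mirrorCcw(trial)
  a <- trajectoryAngle(disp, cutoff = cutoff)
  if (max(a$t) < window)
    warning("trial shorter than the analysis window; truncating")
  win <- a$dangle[a$t < window - 1e-9]
  nW <- length(win)
  tol <- 1
  nz <- which(abs(a$dangle) > tol)
  initialSign <- if (length(nz)) sign(a$dangle[nz[1]]) else 0
  tSign <- NA_real_
  if (initialSign != 0) {
    opp <- sign(a$dangle) == -initialSign
    runEnd <- seq_along(opp) + minRun - 1
    persist <- vapply(seq_along(opp), function(i)
      runEnd[i] <= length(opp) && all(opp[i:runEnd[i]]), logical(1))
    flip <- which(persist)
    flip <- flip[flip > nz[1]]
    if (length(flip)) tSign <- a$t[flip[1]]
  }
  list(tSignChange = tSign, initialSign = initialSign,
       pctNegative = 100 * sum(win < 0) / nW,
       pctPositive = 100 * sum(win > 0) / nW,
       angleSeries = a)
}

#' Parameter sweep of the reoptimization predictions
#'
#' Runs the before-effect and after-effect conditions over grids of feedback
#' delay, motor-to-sensory noise ratio, muscle gain ratio and via-point
#' boundary presets, and tabulates the predicted metrics. Individual run
#' failures are recorded per row and the sweep continues.
#'
#' @param delays feedback delays (s)
#' @param noiseRatios motor/sensory variance ratios `sigma_xi / sigma_w`
#' @param gainRatios shoulder/elbow muscle gain ratios
#' @param boundaries via-point boundary presets
#' @param phi field level (N s/m)
#' @param params,p base parameters (one factor varied at a time)
#' @return long-format data frame: one row per (parameter, value, condition)
#' @export
parameterSweep <- function(delays = c(0, 0.05, 0.12, 0.15),
                           noiseRatios = c(0.1, 1, 10, 100),
                           gainRatios = c(1, 2, 5, 10),
                           boundaries = c("p", "pv", "pva", "pvae"),
                           phi = 2, params = ofcParams(), p = armParams()) {
  fam <- function(name, values) {
    if (!length(values)) return(NULL)
    data.frame(parameter = name, value = values, stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, Filter(Negate(is.null), list(
    fam("delay", delays),
    fam("noise_ratio", noiseRatios),
    fam("gain_ratio", gainRatios),
    fam("boundary", match(boundaries, c("p", "pv", "pva", "pvae"))))))
  if (is.null(grid) || !nrow(grid)) stop("empty sweep grid")
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    par_i <- params
    p_i <- p
    lab <- grid$value[i]
    switch(grid$parameter[i],
      delay = { par_i$delay <- grid$value[i] },
      noise_ratio = { par_i$sigma_xi <- grid$value[i]; par_i$sigma_w <- 1 },
      gain_ratio = {
        p_i <- armParams(g_sh = grid$value[i], g_el = 1)
      },
      boundary = {
        par_i <- ofcParams(boundary = c("p", "pv", "pva",
                                        "pvae")[grid$value[i]])
        lab <- grid$value[i]
      })
    for (cond in c("before_effect", "after_effect")) {
      row <- tryCatch({
        tr <- runCondition(conditionSpec("reoptimization", cond, phi = phi),
                           par_i, p_i)
        m <- predictedMetrics(tr)
        data.frame(parameter = grid$parameter[i], value = lab,
                   condition = cond, tSignChange = m$tSignChange,
                   pctNegative = m$pctNegative, pctPositive = m$pctPositive,
                   error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(parameter = grid$parameter[i], value = lab,
                   condition = cond, tSignChange = NA_real_,
                   pctNegative = NA_real_, pctPositive = NA_real_,
                   error = conditionMessage(e), stringsAsFactors = FALSE))
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}
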