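# Seeded generator of synthetic participants. Human-like variability is
# modeled as trial-to-trial via-point jitter plus additive sensor noise on
# the recorded hand path (1000 Hz); adaptation across training trials is an
# exponential interpolation of the via-point offsets toward the remapped
# series S'.

.reachadaptCache <- new.env(parent = emptyenv())

#' Remapped via-point series used by the cohort generator
#'
#' The series `S'` obtained by the deterministic grid fit of the adapted
#' condition (perturbed plant, unaware controller) against the simulated
#' baseline under a `phi` N s/m field (see [fitViaPoints()]). The result is
#' cached per session.
#'
#' @param phi field level (N s/m)
#' @param params,p simulation parameters
#' @return a [viaPointSeries()]
#' @export
cohortViaPrime <- function(phi = 2, params = ofcParams(), p = armParams()) {
  key <- sprintf("Sprime_%g", phi)
  if (!is.null(.reachadaptCache[[key]])) return(.reachadaptCache[[key]])
  base <- runCondition(conditionSpec("reoptimization", "baseline",
                                     phi = phi), params, p)
  spec <- conditionSpec("redirection", "adapted", phi = phi,
                        Sprime = viaPointSeries())
  Sp <- fitViaPoints(base, spec, params = params, p = p)
  .reachadaptCache[[key]] <- Sp
  Sp
}

#' Synthetic participant profile
#'
#' Three behavioral profiles mirror the groups observed in force-field
#' adaptation cohorts:
#' \describe{
#'   \item{mirror_absent}{adapts by redirection toward the fitted `S'`;
#'     after-effects are re-aimed from the start, giving a flat-then-negative
#'     displayed angle derivative (no mirror organization).}
#'   \item{mirror_present}{adapts toward an `S'` whose first via-point stays
#'     on the straight line (only the distal via-points are remapped);
#'     after-effects rotate away mid-movement, producing a sustained positive
#'     derivative epoch (a partial mirror).}
#'   \item{non_adapter}{no adaptation (`k0 = 0`); training trials keep the
#'     original series.}
#' }
#'
#' @param profile profile name
#' @param fieldSign `"CCW"` or `"CW"` perturbation for this participant
#' @param counts trials per category (baseline, before-effect, adapted,
#'   after-effect)
#' @param sigma_vp via-point jitter standard deviation (m)
#' @param sigma_xy sensor noise standard deviation on the recorded hand
#'   path (m); encoder-grade by default, so that the unfiltered kinematic
#'   spectra keep most of their power below 10 Hz as in real recordings
#' @param k0 adaptation decay rate per training trial
#' @param speedScale movement-vigor factor: the planning horizon is divided
#'   by it, leaving the goal update period (and hence the ~8 Hz submovement
#'   pacing) untouched. The default `NA` calibrates the factor automatically
#'   per condition so that the peak forward speed lands mid-window (0.30
#'   m/s), emulating participants regulating their vigor from the speed
#'   feedback; the calibration is deterministic and cached
#' @param phi field magnitude (N s/m)
#' @return object of class `participantProfile`
#' @export
participantProfile <- function(profile = c("mirror_absent", "mirror_present",
                                           "non_adapter"),
                               fieldSign = "CCW",
                               counts = c(baseline = 17, before_effect = 19,
                                          adapted = 107, after_effect = 34),
                               sigma_vp = 0.004, sigma_xy = 2e-5,
                               k0 = 0.05, speedScale = NA, phi = 2) {
  profile <- match.arg(profile)
  stopifnot(fieldSign %in% c("CW", "CCW"), all(counts >= 5),
            sigma_vp >= 0, sigma_xy >= 0,
            is.na(speedScale) || speedScale > 0)
  if (profile == "non_adapter") k0 <- 0
  structure(list(profile = profile, fieldSign = fieldSign, counts = counts,
                 sigma_vp = sigma_vp, sigma_xy = sigma_xy, k0 = k0,
                 speedScale = speedScale, phi = phi),
            class = "participantProfile")
}

# profile-specific fully-adapted offsets (CCW-field convention; negated for
# CW participants). The grid fit sets the overall remap scale; the shape
# differs by profile: mirror_absent re-aims along a constant bearing
# (offsets proportional to the distance covered, so the after-effect angle
# is flat and then falls), mirror_present leaves the proximal via-point on
# the line (the after-effect rotates away mid-movement: a partial mirror).
profileOffsets <- function(prof, p = armParams()) {
  # always the canonical remap, fitted at the standard operating point
  Sp <- cohortViaPrime(abs(prof$phi), ofcParams(), p)
  off <- switch(prof$profile,
    mirror_absent = -abs(Sp$offsets[length(Sp$offsets)]) /
      max(Sp$fractions) * Sp$fractions,
    mirror_present = c(0, Sp$offsets[-1]),
    non_adapter = rep(0, length(Sp$offsets)))
  if (prof$fieldSign == "CW") off <- -off
  off
}

# per-condition vigor: secant iteration on the planning-horizon divisor so
# that the deterministic peak forward speed hits mid-window (0.30 m/s);
# deterministic, cached by (profile, field, category, adaptation bucket)
vigorScale <- function(prof, category, w, p = armParams()) {
  if (is.finite(prof$speedScale)) return(prof$speedScale)
  wb <- round(w * 4) / 4
  key <- sprintf("vigor_%s_%s_%s_%.2f_%g", prof$profile, prof$fieldSign,
                 category, wb, prof$phi)
  if (!is.null(.reachadaptCache[[key]])) return(.reachadaptCache[[key]])
  offsets <- (1 - wb) * profileOffsets(prof, p)
  phi <- if (category %in% c("before_effect", "adapted")) {
    if (prof$fieldSign == "CCW") abs(prof$phi) else -abs(prof$phi)
  } else 0
  peakAt <- function(ss) {
    tr <- runClosedLoop(viaPointSeries(offsets = offsets, p = p),
                        ofcParams(T_H = 0.28 / ss), p, phiPlant = phi)$trial
    pr <- processTrial(tr)
    g <- trialGeometry(tr)
    max(pr$vx * g$dir[1] + pr$vy * g$dir[2])
  }
  clamp <- function(ss) min(2.05, max(0.7, ss))
  target <- 0.30
  ss1 <- 1.4; v1 <- peakAt(ss1); ss <- ss1
  if (abs(v1 - target) > 0.01) {
    ss2 <- clamp(ss1 + (target - v1) / 0.27)
    v2 <- peakAt(ss2); ss <- ss2
    if (abs(v2 - target) > 0.015 && abs(v2 - v1) > 1e-6)
      ss <- clamp(ss2 + (target - v2) * (ss2 - ss1) / (v2 - v1))
  }
  .reachadaptCache[[key]] <- ss
  ss
}

trialParams <- function(prof, category, w, p = armParams()) {
  ofcParams(T_H = 0.28 / vigorScale(prof, category, w, p),
            plantSubsteps = 10L)
}

#' Generate one synthetic trial
#'
#' Runs the closed-loop model for the category's condition with jittered
#' via-points, records the hand path at 1000 Hz and adds sensor noise.
#' Training trials (before-effect and adapted, one combined index) move
#' their via-point offsets from the original series toward the profile's
#' remapped series with weight `exp(-k0 * (index - 1))`, so the lateral
#' deviation decays exponentially across training.
#'
#' @param prof a [participantProfile()]
#' @param category trial category
#' @param index trial index within the category (training trials continue
#'   the before-effect count)
#' @param seed RNG seed for this trial (deterministic per trial)
#' @param params,p simulation parameters; `params` defaults to the
#'   profile's pacing with 1000-Hz plant recording
#' @return a [reachTrial()]
#' @export
generateTrial <- function(prof, category = conditionLevels, index = 1,
                          seed = 1, params = NULL, p = armParams()) {
  category <- match.arg(category)
  phi <- if (prof$fieldSign == "CCW") abs(prof$phi) else -abs(prof$phi)
  offFull <- profileOffsets(prof, p)
  trainIdx <- switch(category,
    baseline = NA_integer_, after_effect = NA_integer_,
    before_effect = index,
    adapted = prof$counts[["before_effect"]] + index)
  w <- switch(category,
    baseline = 1, before_effect = exp(-prof$k0 * (trainIdx - 1)),
    adapted = exp(-prof$k0 * (trainIdx - 1)), after_effect = 0)
  offsets <- (1 - w) * offFull
  perturbed <- category %in% c("before_effect", "adapted")
  if (is.null(params)) params <- trialParams(prof, category, w, p)
  set.seed(as.integer((as.numeric(seed) * 10007 +
                         match(category, conditionLevels) * 1009 +
                         index * 101) %% 2147483647))
  S <- viaPointSeries(offsets = offsets, T_G = params$T_G, p = p)
  nVia <- length(S$fractions)
  S <- jitterViaSeries(S, rnorm(nVia, sd = prof$sigma_vp),
                       rnorm(nVia, sd = prof$sigma_vp), p)
  r <- runClosedLoop(S, params, p, phiPlant = if (perturbed) phi else 0,
                     phiCtrl = 0, phiEst = 0)
  tr <- r$trial
  if (prof$sigma_xy > 0) {
    tr$x <- tr$x + rnorm(nrow(tr), sd = prof$sigma_xy)
    tr$y <- tr$y + rnorm(nrow(tr), sd = prof$sigma_xy)
  }
  attr(tr, "category") <- category
  attr(tr, "fieldSign") <- prof$fieldSign
  attr(tr, "id") <- sprintf("%s_%03d", category, index)
  tr
}

#' Generate a full synthetic participant
#'
#' All four categories at the profile's trial counts. When `dir` is given
#' the trials are written as `trials.csv` plus a `manifest.json` (counts,
#' field direction, profile, seed).
#'
#' @param prof a [participantProfile()]
#' @param seed participant seed
#' @param dir optional output directory
#' @param categories categories to generate (all four by default)
#' @param p [armParams()]
#' @return named list of trial lists by category (invisibly when writing)
#' @export
generateParticipant <- function(prof, seed = 1, dir = NULL,
                                categories = conditionLevels,
                                p = armParams()) {
  out <- lapply(categories, function(cat) {
    lapply(seq_len(prof$counts[[cat]]), function(i)
      generateTrial(prof, cat, i, seed = seed, p = p))
  })
  names(out) <- categories
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeTrials(unlist(out, recursive = FALSE),
                file.path(dir, "trials.csv"))
    jsonlite::write_json(
      list(profile = prof$profile, field = prof$fieldSign,
           counts = as.list(prof$counts[categories]), seed = seed,
           handedness = NA),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, null = "null")
    return(invisible(out))
  }
  out
}
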