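# Trajectory processing pipeline: filtering, differentiation, movement
# extraction, mirroring, trajectory angle, lateral deviation, peak frequency,
# category means and the exponential adaptation fit.
#
# Fixed pipeline order: filter positions -> differentiate -> filter each
# derivative in turn -> extract the movement -> angle.

#' Zero-phase Butterworth low-pass filter
#'
#' Fourth-order Butterworth applied forward and backward (zero phase, unit DC
#' gain), the standard choice for offline kinematic data.
#'
#' @param series numeric vector
#' @param fs sample rate (Hz)
#' @param cutoff cutoff frequency (Hz)
#' @param order filter order (per pass)
#' @return filtered vector of the same length
#' @export
butterLowpass <- function(series, fs, cutoff = 10, order = 4) {
  if (fs <= 2 * cutoff) stop("sample rate must exceed twice the cutoff")
  if (length(series) < 8 * (order + 1))
    stop("series too short for stable zero-phase filtering")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- length(series)
  # remove the line through the endpoints and odd-reflect both ends so the
  # forward-backward passes see a signal near zero at the boundaries (the
  # underlying filter starts from zero initial conditions)
  trend <- series[1] + (series[n] - series[1]) * (seq_len(n) - 1) / (n - 1)
  z <- series - trend
  L <- min(n - 1, ceiling(3 * fs / cutoff))
  zp <- c(2 * z[1] - z[(L + 1):2], z, 2 * z[n] - z[(n - 1):(n - L)])
  zf <- as.numeric(signal::filtfilt(bf, zp))
  zf[(L + 1):(L + n)] + trend
}

#' Two-sample (central) numerical differentiation
#'
#' Central difference over two samples in the interior, one-sided at the
#' endpoints; exact on polynomials up to degree 2 at interior points.
#'
#' @param series numeric vector (>= 3 samples)
#' @param fs sample rate (Hz)
#' @return derivative, same length as `series`
#' @export
differentiateSeries <- function(series, fs) {
  n <- length(series)
  if (n < 3) stop("need at least 3 samples to differentiate")
  d <- numeric(n)
  d[2:(n - 1)] <- (series[3:n] - series[1:(n - 2)]) * fs / 2
  d[1] <- (series[2] - series[1]) * fs
  d[n] <- (series[n] - series[n - 1]) * fs
  d
}

# onset = speed first above threshold; offset = first below threshold after
# the peak (last sample, flagged, if never)
detectOnsetOffset <- function(speed, threshold = 0.01) {
  above <- which(speed > threshold)
  if (!length(above))
    stop("no movement detected (speed never exceeds threshold)")
  onset <- above[1]
  ipk <- max(which.max(speed), onset)
  after <- which(speed[(ipk + 1):length(speed)] < threshold)
  if (length(after)) list(onset = onset, offset = ipk + after[1],
                          flagged = FALSE)
  else list(onset = onset, offset = length(speed), flagged = TRUE)
}

# geometry of a trial: start/target attached by the simulators, otherwise the
# standard 0.1-m forward reach from the first sample
trialGeometry <- function(trial) {
  start <- attr(trial, "start")
  target <- attr(trial, "target")
  if (is.null(start)) start <- c(trial$x[1], trial$y[1])
  if (is.null(target)) target <- start + c(0, 0.1)
  dir <- target - start
  dir <- dir / sqrt(sum(dir^2))
  list(start = start, target = target, dir = dir)
}

#' Filter and differentiate a trial
#'
#' Runs the fixed processing order (filter positions, then differentiate and
#' filter velocity, acceleration and jerk) and returns all derivatives.
#'
#' @param trial a [reachTrial()]
#' @param cutoff low-pass cutoff (Hz); `NA` skips filtering
#' @return a data frame with columns `t, x, y, vx, vy, speed, ax, ay, jx, jy`
#' @export
processTrial <- function(trial, cutoff = 10) {
  fs <- attr(trial, "fs")
  filt <- function(z) if (is.na(cutoff)) z else butterLowpass(z, fs, cutoff)
  x <- filt(trial$x); y <- filt(trial$y)
  vx <- filt(differentiateSeries(x, fs))
  vy <- filt(differentiateSeries(y, fs))
  ax <- filt(differentiateSeries(vx, fs))
  ay <- filt(differentiateSeries(vy, fs))
  jx <- filt(differentiateSeries(ax, fs))
  jy <- filt(differentiateSeries(ay, fs))
  data.frame(t = trial$t, x = x, y = y, vx = vx, vy = vy,
             speed = sqrt(vx^2 + vy^2), ax = ax, ay = ay, jx = jx, jy = jy)
}

#' Is a trial valid?
#'
#' A trial is valid when its peak velocity along the target direction falls in
#' the instructed speed window (0.25 to 0.35 m/s by default) during the
#' forward movement.
#'
#' @param trial a [reachTrial()]
#' @param speedWindow allowed peak forward velocity (m/s)
#' @param cutoff low-pass cutoff used in processing (Hz)
#' @return logical
#' @export
validTrial <- function(trial, speedWindow = c(0.25, 0.35), cutoff = 10) {
  pr <- processTrial(trial, cutoff)
  g <- trialGeometry(trial)
  vfwd <- pr$vx * g$dir[1] + pr$vy * g$dir[2]
  pk <- max(vfwd)
  pk >= speedWindow[1] && pk <= speedWindow[2]
}

#' Extract the forward movement from a trial
#'
#' Crops the trial from movement onset (speed first exceeds the threshold) to
#' offset (speed first falls below the threshold after the peak). If the speed
#' never falls below the threshold after the peak, the trial ends at the last
#' sample and the result carries the attribute `offsetFlagged = TRUE`.
#'
#' @param trial a [reachTrial()]
#' @param threshold speed threshold (m/s)
#' @param cutoff low-pass cutoff for the speed used in detection (Hz)
#' @return cropped [reachTrial()] with time restarted at onset
#' @export
extractForward <- function(trial, threshold = 0.01, cutoff = 10) {
  pr <- processTrial(trial, cutoff)
  oo <- detectOnsetOffset(pr$speed, threshold)
  onset <- oo$onset; offset <- oo$offset; flagged <- oo$flagged
  m <- trialMeta(trial)
  out <- reachTrial(trial$t[onset:offset] - trial$t[onset],
                    trial$x[onset:offset], trial$y[onset:offset],
                    fs = m$fs, category = m$category, fieldSign = m$fieldSign,
                    id = m$id)
  attr(out, "start") <- attr(trial, "start")
  attr(out, "target") <- attr(trial, "target")
  attr(out, "offsetFlagged") <- flagged
  attr(out, "extracted") <- TRUE
  out
}

#' Mirror counterclockwise-field trials
#'
#' Reflects the hand path about the start-position/target-position line for
#' participants who received a counterclockwise perturbation, so that all
#' trajectories are displayed with a clockwise deviation. Clockwise-field
#' trials are returned unchanged. Applying the function twice (after toggling
#' the field sign) restores the original.
#'
#' @param trial a [reachTrial()] whose `fieldSign` attribute gives the
#'   participant's perturbation direction
#' @return a [reachTrial()]
#' @export
mirrorCcw <- function(trial) {
  sgn <- attr(trial, "fieldSign")
  if (is.null(sgn) || is.na(sgn) || !sgn %in% c("CW", "CCW", "none"))
    stop("unknown field sign; cannot decide mirroring")
  if (sgn %in% c("CW", "none")) return(trial)
  g <- trialGeometry(trial)
  perp <- c(-g$dir[2], g$dir[1])
  rx <- trial$x - g$start[1]
  ry <- trial$y - g$start[2]
  along <- rx * g$dir[1] + ry * g$dir[2]
  across <- rx * perp[1] + ry * perp[2]
  m <- trialMeta(trial)
  out <- reachTrial(trial$t,
                    g$start[1] + along * g$dir[1] - across * perp[1],
                    g$start[2] + along * g$dir[2] - across * perp[2],
                    fs = m$fs, category = m$category, fieldSign = "CW",
                    id = m$id)
  attr(out, "start") <- attr(trial, "start")
  attr(out, "target") <- attr(trial, "target")
  attr(out, "extracted") <- attr(trial, "extracted")
  out
}

#' Trajectory angle and its derivative
#'
#' The signed angle (degrees, counterclockwise positive) between the
#' start-to-target direction and the tangent (velocity) of the hand path,
#' unwrapped to avoid jumps at +/-180 degrees, together with its time
#' derivative. The angle is defined where the speed exceeds `minSpeed`;
#' below it, the last defined value is carried forward and flagged.
#'
#' If the trial has not been cropped with [extractForward()], the angle is
#' computed on the full filtered record and then cropped to the movement, so
#' that filter transients never touch the analysis window; time is reported
#' from movement onset.
#'
#' @param trial a [reachTrial()]
#' @param cutoff low-pass cutoff (Hz)
#' @param minSpeed speed below which the tangent is undefined (m/s)
#' @return data frame with columns `t, angle, dangle, speed, defined`
#'   (degrees and degrees/s), class `angleSeries`
#' @export
trajectoryAngle <- function(trial, cutoff = 10, minSpeed = 0.01) {
  fs <- attr(trial, "fs")
  pr <- processTrial(trial, cutoff)
  g <- trialGeometry(trial)
  raw <- atan2(g$dir[1] * pr$vy - g$dir[2] * pr$vx,
               g$dir[1] * pr$vx + g$dir[2] * pr$vy)
  defined <- pr$speed > minSpeed
  if (!any(defined)) stop("angle undefined everywhere (speed too low)")
  # carry the last defined value forward (and the first defined value
  # backward), then unwrap across consecutive defined samples only, so the
  # meaningless tangent spin at near-zero speed cannot wind full turns into
  # the series
  idx <- seq_along(raw)
  lastdef <- cummax(ifelse(defined, idx, 0L))
  firstdef <- which(defined)[1]
  lastdef[lastdef == 0L] <- firstdef
  held <- raw[lastdef]
  dw <- c(0, diff(held))
  dw <- dw - 2 * pi * round(dw / (2 * pi))
  cs <- cumsum(dw)
  ang <- held[firstdef] + cs - cs[firstdef]
  dang <- differentiateSeries(rad2deg(ang), fs)
  keep <- seq_along(ang)
  t0 <- pr$t[1]
  if (is.null(attr(trial, "extracted"))) {
    oo <- detectOnsetOffset(pr$speed, minSpeed)
    keep <- oo$onset:oo$offset
    t0 <- pr$t[oo$onset]
  }
  out <- data.frame(t = pr$t[keep] - t0, angle = rad2deg(ang[keep]),
                    dangle = dang[keep], speed = pr$speed[keep],
                    defined = defined[keep])
  class(out) <- c("angleSeries", "data.frame")
  out
}

#' Signed lateral deviation of a trial
#'
#' Maximum-magnitude perpendicular distance of the hand path from the
#' start-position/target-position line, signed (counterclockwise side of the
#' target direction positive).
#'
#' @param trial a [reachTrial()]
#' @return scalar deviation (m)
#' @export
lateralDeviation <- function(trial) {
  g <- trialGeometry(trial)
  perp <- c(-g$dir[2], g$dir[1])
  across <- (trial$x - g$start[1]) * perp[1] + (trial$y - g$start[2]) * perp[2]
  across[which.max(abs(across))]
}

#' Discrete peak frequency of a series
#'
#' `(number of strict local minima + number of strict local maxima) /
#' (2 * duration)`: a sinusoid of frequency f over an integer number of
#' periods scores f.
#'
#' @param series numeric vector
#' @param duration duration of the series (s)
#' @return frequency (Hz)
#' @export
peakFrequency <- function(series, duration) {
  stopifnot(duration > 0)
  d <- diff(series)
  d <- d[d != 0]  # flat-topped extrema (sampling ties) count once
  if (length(d) < 2) return(0)
  s <- sign(d)
  flips <- sum(s[-1] != s[-length(s)])
  flips / (2 * duration)
}

#' Per-timestep category means of the trajectory angle
#'
#' Aligns extracted trials at movement onset on a common time grid and
#' computes the per-timestep mean angle, mean angle derivative and 95%
#' confidence intervals across trials. Shorter trials contribute up to their
#' own length; the per-timestep trial count is reported.
#'
#' @param trials list of [reachTrial()] objects (same sample rate)
#' @param window analysis window from onset (s)
#' @param cutoff low-pass cutoff (Hz)
#' @return data frame with columns `t, n, angle, angleLo, angleHi, dangle,
#'   dangleLo, dangleHi, dangleSd` plus attribute `series` (the per-trial
#'   angle-derivative matrix)
#' @export
categoryMean <- function(trials, window = 0.4, cutoff = 10) {
  if (length(trials) < 2) stop("need at least 2 trials in a category")
  fs <- attr(trials[[1]], "fs")
  aser <- lapply(trials, trajectoryAngle, cutoff = cutoff)
  nT <- floor(window * fs) + 1
  tgrid <- (seq_len(nT) - 1) / fs
  angM <- sapply(aser, function(a) c(a$angle, rep(NA, nT))[seq_len(nT)])
  derM <- sapply(aser, function(a) c(a$dangle, rep(NA, nT))[seq_len(nT)])
  summ <- function(M) {
    n <- rowSums(!is.na(M))
    mu <- rowMeans(M, na.rm = TRUE)
    se <- apply(M, 1, sd, na.rm = TRUE) / sqrt(pmax(n, 1))
    tcrit <- qt(0.975, pmax(n - 1, 1))
    list(n = n, mu = mu, lo = mu - tcrit * se, hi = mu + tcrit * se,
         sd = apply(M, 1, sd, na.rm = TRUE))
  }
  sa <- summ(angM); sd_ <- summ(derM)
  out <- data.frame(t = tgrid, n = sa$n, angle = sa$mu, angleLo = sa$lo,
                    angleHi = sa$hi, dangle = sd_$mu, dangleLo = sd_$lo,
                    dangleHi = sd_$hi, dangleSd = sd_$sd)
  attr(out, "series") <- derM
  attr(out, "angleSeries") <- angM
  out
}

#' Exponential decay fit of lateral deviations across trials
#'
#' Least-squares fit of `a * exp(-k * trial) + c` with `k >= 0` over the
#' trial index, used to quantify adaptation.
#'
#' @param dev numeric vector of per-trial lateral deviations (m), in trial
#'   order
#' @return list with `a`, `k`, `c`, `r2`, `pDecay` (F-test of the decay
#'   against a constant model) and the fitted values; on non-convergence
#'   `r2` is `NaN`
#' @export
expDecayFit <- function(dev) {
  if (length(dev) < 5) stop("need at least 5 trials for the decay fit")
  dev <- unname(dev)
  i <- seq_along(dev) - 1
  a0 <- dev[1] - mean(tail(dev, 5))
  fit <- tryCatch(
    minpack.lm::nlsLM(dev ~ a * exp(-k * i) + c,
                      start = list(a = a0, k = 0.05, c = mean(tail(dev, 5))),
                      lower = c(a = -Inf, k = 0, c = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(a = NA_real_, k = NA_real_, c = NA_real_, r2 = NaN,
                pDecay = NA_real_, fitted = rep(NA_real_, length(dev))))
  cf <- stats::coef(fit)
  fv <- stats::fitted(fit)
  ssr <- sum((dev - fv)^2)
  sst <- sum((dev - mean(dev))^2)
  n <- length(dev)
  # F-test of the 3-parameter decay against the constant model
  Fstat <- if (ssr > 0) ((sst - ssr) / 2) / (ssr / (n - 3)) else Inf
  list(a = unname(cf["a"]), k = unname(cf["k"]), c = unname(cf["c"]),
       r2 = if (sst > 0) 1 - ssr / sst else 0,
       pDecay = stats::pf(Fstat, 2, n - 3, lower.tail = FALSE),
       fitted = as.numeric(fv))
}

#' Periodogram power spectrum
#'
#' Mean-removed, tapered periodogram; used for the sanity check that most of
#' the kinematic power lies below 10 Hz.
#'
#' @param series numeric vector (length >= 32)
#' @param fs sample rate (Hz)
#' @return data frame with columns `freq` (Hz) and `power`
#' @export
powerSpectrum <- function(series, fs) {
  if (length(series) < 32) stop("series too short for a spectrum")
  sp <- spec.pgram(stats::ts(series - mean(series), frequency = fs),
                   taper = 0.1, detrend = TRUE, plot = FALSE)
  data.frame(freq = sp$freq, power = sp$spec)
}
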