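test_that("zero-phase Butterworth has unit DC gain and a sharp rolloff", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  expect_equal(butterLowpass(rep(3.3, length(t)), fs), rep(3.3, length(t)))

  s2 <- sin(2 * pi * 2 * t)
  s50 <- sin(2 * pi * 50 * t)
  mid <- t > 0.5 & t < 1.5
  expect_gt(max(abs(butterLowpass(s2, fs)[mid])), 0.99)
  expect_lt(max(abs(butterLowpass(s50, fs)[mid])), 0.1)

  # cascading stays stable and only sharpens the response
  twice <- butterLowpass(butterLowpass(s2, fs), fs)
  expect_true(all(is.finite(twice)))
  expect_lte(max(abs(twice[mid])), max(abs(butterLowpass(s2, fs)[mid])) + 1e-9)

  expect_error(butterLowpass(s2, fs = 15), "cutoff")
})

test_that("central differencing is exact on polynomials", {
  fs <- 100
  t <- seq(0, 1, by = 1 / fs)
  expect_equal(differentiateSeries(3 * t, fs), rep(3, length(t)),
               tolerance = 1e-10)
  third <- differentiateSeries(differentiateSeries(
    differentiateSeries(t^3, fs), fs), fs)
  expect_equal(third[4:(length(t) - 3)], rep(6, length(t) - 6),
               tolerance = 1e-8)

  # velocity -> acceleration -> jerk chain on a minimum-jerk profile
  T <- 0.5; D <- 0.1
  tt <- seq(0, T, by = 1 / fs)
  pos <- minimumJerk(D, T, tt)
  vel <- differentiateSeries(pos, fs)
  acc <- differentiateSeries(vel, fs)
  velTrue <- minimumJerk(D, T, tt, 1)
  accTrue <- minimumJerk(D, T, tt, 2)
  interior <- 5:(length(tt) - 5)
  expect_lt(max(abs(vel - velTrue)[interior]) / max(velTrue), 0.02)
  expect_lt(max(abs(acc - accTrue)[interior]) / max(abs(accTrue)), 0.02)
})

test_that("trial validity depends on the peak forward velocity", {
  expect_true(validTrial(mjTrial(peak = 0.30)))
  expect_false(validTrial(mjTrial(peak = 0.20)))
  expect_false(validTrial(mjTrial(peak = 0.40)))
})

test_that("movement extraction crops rest padding and keeps the interior", {
  tr <- mjTrial(peak = 0.3, pad = 0.3)
  ex <- extractForward(tr)
  expect_lt(nrow(ex), nrow(tr))
  expect_equal(ex$t[1], 0)
  expect_false(attr(ex, "offsetFlagged"))
  # onset precedes the velocity peak
  pr <- processTrial(ex)
  expect_gt(which.max(pr$speed), 1)
  # interior positions untouched by cropping
  expect_true(all(ex$y %in% tr$y))

  # speed that never falls back below threshold: offset flagged
  t <- seq(0, 1, by = 0.01)
  ramp <- reachTrial(t, rep(0, length(t)), 0.4 + 0.05 * t^2, fs = 100)
  expect_true(attr(extractForward(ramp), "offsetFlagged"))
})

test_that("mirroring is an involution that negates the trajectory angle", {
  tr <- mjTrial(peak = 0.3)
  tr$x <- tr$x + 0.01 * sin(2 * pi * tr$t)  # lateral bulge
  attr(tr, "fieldSign") <- "CW"
  expect_identical(mirrorCcw(tr)$x, tr$x)

  attr(tr, "fieldSign") <- "CCW"
  mt <- mirrorCcw(tr)
  expect_equal(mt$y, tr$y)
  a <- trajectoryAngle(tr)
  am <- trajectoryAngle(mt)
  expect_equal(am$angle, -a$angle, tolerance = 1e-9)

  # double application (after restoring the flag) recovers the original
  attr(mt, "fieldSign") <- "CCW"
  back <- mirrorCcw(mt)
  expect_equal(back$x, tr$x, tolerance = 1e-12)

  attr(tr, "fieldSign") <- "mystery"
  expect_error(mirrorCcw(tr), "field sign")
})

test_that("trajectory angle matches its geometric definition", {
  straight <- mjTrial(peak = 0.3)
  a <- trajectoryAngle(straight)
  expect_lt(max(abs(a$angle)), 1e-6)
  expect_lt(max(abs(a$dangle)), 1e-3)

  # velocity rotated 45 degrees counterclockwise from the target direction
  tilt <- straight
  rot <- sqrt(2) / 2
  dy <- c(0, diff(straight$y))
  tilt$x <- straight$x[1] + cumsum(-rot * dy)
  tilt$y <- straight$y[1] + cumsum(rot * dy)
  at <- trajectoryAngle(tilt, cutoff = NA)
  mid <- at$speed > 0.05
  expect_equal(median(at$angle[mid]), 45, tolerance = 0.5)

  # constant-speed circular arc: dangle = v / r
  arc <- arcTrial(v = 0.3, r = 0.15)
  aa <- trajectoryAngle(arc, cutoff = NA)
  mid <- seq(10, nrow(aa) - 10)
  expect_equal(median(aa$dangle[mid]), rad2deg(0.3 / 0.15),
               tolerance = 0.01 * rad2deg(2))
})

test_that("lateral deviation is signed and mirror-consistent", {
  straight <- mjTrial(peak = 0.3)
  expect_equal(lateralDeviation(straight), 0, tolerance = 1e-12)

  bulge <- straight
  bulge$x <- bulge$x - 0.02 * sin(pi * pmin(pmax((bulge$y - 0.4) / 0.1, 0), 1))
  dev <- lateralDeviation(bulge)
  expect_equal(abs(dev), 0.02, tolerance = 1e-3)  # sampled peak
  attr(bulge, "fieldSign") <- "CCW"
  expect_equal(lateralDeviation(mirrorCcw(bulge)), -dev, tolerance = 1e-12)
})

test_that("peak frequency counts extrema over duration", {
  fs <- 100
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  expect_equal(peakFrequency(sin(2 * pi * 5 * t), 1), 5)
  expect_equal(peakFrequency(seq(0, 1, length.out = 50), 1), 0)
  tt <- seq(0, 0.5, by = 1 / fs)
  expect_equal(peakFrequency(minimumJerk(0.1, 0.5, tt, 1), 0.5), 1)
})

test_that("category means aggregate aligned trials", {
  trs <- list(mjTrial(peak = 0.3), mjTrial(peak = 0.3))
  cm <- categoryMean(trs)
  expect_true(all(cm$n[1:30] == 2))
  expect_equal(cm$angleHi[5] - cm$angleLo[5], 0, tolerance = 1e-9)

  # opposite bulges average to zero
  plus <- mjTrial(peak = 0.3); minus <- mjTrial(peak = 0.3)
  bump <- 0.01 * sin(pi * pmin(pmax((plus$y - 0.4) / 0.1, 0), 1))
  plus$x <- plus$x + bump
  minus$x <- minus$x - bump
  cm2 <- categoryMean(list(plus, minus))
  expect_lt(max(abs(cm2$angle), na.rm = TRUE), 1e-6)

  expect_error(categoryMean(list(plus)), "at least 2")
})

test_that("exponential decay fits recover generating parameters", {
  i <- 0:119
  dev <- 0.02 * exp(-0.05 * i) + 0.004
  f <- expDecayFit(dev)
  expect_gt(f$r2, 0.999)
  expect_equal(f$a, 0.02, tolerance = 0.01)
  expect_equal(f$k, 0.05, tolerance = 0.01 * 0.05 + 1e-6)

  set.seed(7)
  noisy <- 0.02 * exp(-0.05 * i) + 0.004 + rnorm(120, sd = 0.002)
  fn <- expDecayFit(noisy)
  expect_lt(abs(fn$k - 0.05) / 0.05, 0.25)
  expect_lt(fn$pDecay, 1e-6)

  # constant series: no decay signal
  fc <- expDecayFit(rep(0.01, 30))
  expect_true(is.nan(fc$r2) || fc$r2 < 0.05 || abs(fc$a) < 1e-6)

  expect_error(expDecayFit(c(1, 2)), "at least 5")
})

test_that("periodogram finds tones and is flat on white noise", {
  fs <- 100
  t <- seq(0, 2, by = 1 / fs)
  ps <- powerSpectrum(sin(2 * pi * 5 * t), fs)
  expect_equal(ps$freq[which.max(ps$power)], 5, tolerance = 0.3)

  set.seed(21)
  ratios <- replicate(30, {
    ps <- powerSpectrum(rnorm(256), fs)
    max(ps$power) / median(ps$power)
  })
  expect_lt(mean(ratios), 10)
})

test_that("filtering leaves a smooth model trajectory's angle unchanged", {
  tr <- fxCondition("reoptimization", "before_effect", phi = 2)
  aF <- trajectoryAngle(tr, cutoff = 10)
  aN <- trajectoryAngle(tr, cutoff = NA)
  nn <- min(sum(aF$t < 0.5), sum(aN$t < 0.5))
  expect_lt(max(abs(aF$angle[1:nn] - aN$angle[1:nn])), 0.5)
})
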