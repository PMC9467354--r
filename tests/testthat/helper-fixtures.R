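# shared fixtures, memoized across test files within one session
.fx <- new.env(parent = emptyenv())

fx <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

fxParams <- function(...) ofcParams(...)

fxCondition <- function(model, condition, phi = 2, ...) {
  key <- paste("cond", model, condition, phi, sep = "_")
  fx(key, function() runCondition(conditionSpec(model, condition, phi = phi),
                                  fxParams(), armParams()))
}

# analytic minimum-jerk hand trial along +y, used as a known-shape fixture
mjTrial <- function(D = 0.1, T = 0.5, fs = 100, peak = NULL, pad = 0.25,
                    fieldSign = "none") {
  if (!is.null(peak)) T <- 1.875 * D / peak
  t <- seq(0, T + 2 * pad, by = 1 / fs)
  s <- minimumJerk(D, T, t - pad)
  tr <- reachTrial(t, rep(0, length(t)), 0.4 + s, fs = fs,
                   fieldSign = fieldSign)
  attr(tr, "start") <- c(0, 0.4)
  attr(tr, "target") <- c(0, 0.4 + D)
  tr
}

# constant-speed circular-arc trial (radius r, speed v), CCW, starting
# heading along +y
arcTrial <- function(v = 0.3, r = 0.15, dur = 0.6, fs = 100) {
  t <- seq(0, dur, by = 1 / fs)
  w <- v / r
  x <- -r + r * cos(w * t)
  y <- 0.4 + r * sin(w * t)
  tr <- reachTrial(t, x, y, fs = fs, fieldSign = "none")
  attr(tr, "start") <- c(0, 0.4)
  attr(tr, "target") <- c(0, 0.5)
  tr
}

# independent quadrature oracle for the JZS Bayes factor: trapezoid rule on
# the log-transformed mixing variable (a different integration route from
# the package's adaptive quadrature on the natural scale)
bf10Oracle <- function(t, n, rscale = sqrt(2) / 2) {
  nu <- n - 1
  z <- seq(-15, 15, length.out = 40001)   # g = exp(z)
  g <- exp(z)
  logInt <- -0.5 * log1p(n * g) -
    (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) +
    0.5 * log(rscale^2 / (2 * pi)) - 1.5 * log(g) - rscale^2 / (2 * g) +
    z  # Jacobian of g = exp(z)
  num <- sum(exp(logInt)) * (z[2] - z[1])
  den <- exp(-(nu + 1) / 2 * log1p(t^2 / nu))
  num / den
}
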