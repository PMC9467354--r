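# Per-timestep hypothesis testing on the angle-derivative sign, JZS Bayes
# factors, and the percent-time classification of participants.

#' One-sample t-test against zero
#'
#' Classical two-sided Student t-test of mean = 0.
#'
#' @param samples numeric vector (n >= 2)
#' @return list with `t`, `p`, `mean`, `n`, `flagged` (`TRUE` when the
#'   variance is zero and the test is undefined)
#' @export
ttestZero <- function(samples) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples")
  if (var(samples) == 0)
    return(list(t = NA_real_, p = NA_real_, mean = mean(samples), n = n,
                flagged = TRUE))
  ht <- t.test(samples, mu = 0)
  list(t = unname(ht$statistic), p = ht$p.value, mean = mean(samples),
       n = n, flagged = FALSE)
}

# JZS Bayes factor from a t statistic: Zellner-Siow mixture-of-g prior,
# g ~ InverseGamma(1/2, r^2/2), marginal likelihood by adaptive quadrature
jzsBF10 <- function(t, n, rscale = sqrt(2) / 2) {
  nu <- n - 1
  logLikH0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  f <- function(g) {
    # integrand of the H1 marginal over g, relative to exp(logLikH0)
    exp(-0.5 * log1p(n * g) -
          (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) -
          logLikH0 +
          0.5 * log(rscale^2 / (2 * pi)) - 1.5 * log(g) -
          rscale^2 / (2 * g))
  }
  q <- integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 0)
  q$value
}

#' JZS Bayes factor for a one-sample test
#'
#' Bayes factor of H1 (nonzero mean, Cauchy prior on the standardized effect
#' with scale `rscale = sqrt(2)/2`) over the point null H0, computed by the
#' standard single-integral formula over the mixing variable of the
#' Zellner-Siow prior. `BF10 > 1` favours H1.
#'
#' @param samples numeric vector (n >= 2); alternatively supply `t` and `n`
#' @param t,n t statistic and sample size (used when `samples` is missing)
#' @param rscale Cauchy prior scale
#' @return BF10 (positive scalar); `NA` with a warning for zero-variance
#'   samples
#' @export
bayesFactorBF10 <- function(samples = NULL, t = NULL, n = NULL,
                            rscale = sqrt(2) / 2) {
  if (!is.null(samples)) {
    samples <- samples[is.finite(samples)]
    n <- length(samples)
    if (n < 2) stop("need at least 2 samples")
    if (var(samples) == 0) {
      warning("zero variance: Bayes factor undefined")
      return(NA_real_)
    }
    t <- mean(samples) / (sd(samples) / sqrt(n))
  }
  jzsBF10(t, n, rscale)
}

#' Interpret a Bayes factor
#'
#' Bands: `1 < BF10 < 3` anecdotal evidence for H1, `BF10 > 3` substantial;
#' reciprocal bands for H0.
#'
#' @param bf10 Bayes factor(s)
#' @return character vector of labels
#' @export
bfInterpretation <- function(bf10) {
  vapply(bf10, function(b) {
    if (!is.finite(b)) return(NA_character_)
    if (b > 3) "substantial H1"
    else if (b > 1) "anecdotal H1"
    else if (b > 1 / 3) "anecdotal H0"
    else "substantial H0"
  }, character(1))
}

#' Per-timestep statistics of the angle derivative
#'
#' For each timestep of the analysis window, tests whether the mean
#' trajectory-angle derivative across trials differs from zero (t-test and
#' JZS Bayes factor). Trials are mirrored to the display convention first.
#'
#' @param trials list of [reachTrial()] objects of one category
#' @param window analysis window (s)
#' @param cutoff low-pass cutoff (Hz)
#' @param mirror mirror CCW-field trials before analysis
#' @return data frame of class `timepointStats`: `t, n, mean, tstat, p,
#'   bf10`
#' @export
timepointStats <- function(trials, window = 0.4, cutoff = 10,
                           mirror = TRUE) {
  if (mirror) trials <- lapply(trials, mirrorCcw)
  cm <- categoryMean(trials, window = window, cutoff = cutoff)
  derM <- attr(cm, "series")
  res <- lapply(seq_len(nrow(cm)), function(i) {
    x <- derM[i, ]
    x <- x[is.finite(x)]
    if (length(x) < 2 || var(x) == 0)
      return(data.frame(t = cm$t[i], n = length(x), mean = mean(x),
                        tstat = NA_real_, p = NA_real_, bf10 = NA_real_))
    tt <- ttestZero(x)
    data.frame(t = cm$t[i], n = tt$n, mean = tt$mean, tstat = tt$t,
               p = tt$p, bf10 = jzsBF10(tt$t, tt$n))
  })
  out <- do.call(rbind, res)
  class(out) <- c("timepointStats", "data.frame")
  out
}

#' Percent of the window with a statistically null or negative derivative
#'
#' In `pvalue` mode a timestep counts when `p > 0.05`, or when `p <= 0.05`
#' with a negative mean; in `bf` mode when `BF10 < 3`, or `BF10 >= 3` with a
#' negative mean. The complementary sign is obtained with
#' `direction = "positive"`.
#'
#' @param stats a [timepointStats()] data frame covering the window
#' @param mode `"pvalue"` or `"bf"`
#' @param direction sign counted together with the null timesteps
#' @param alpha significance level for the p-value mode
#' @param bfThreshold substantial-evidence threshold for the BF mode
#' @return percentage in `[0, 100]`
#' @export
percentNullOrNegative <- function(stats, mode = c("pvalue", "bf"),
                                  direction = c("negative", "positive"),
                                  alpha = 0.05, bfThreshold = 3) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  sgn <- if (direction == "negative") -1 else 1
  ok <- if (mode == "pvalue") {
    is.na(stats$p) | stats$p > alpha |
      (stats$p <= alpha & sign(stats$mean) == sgn)
  } else {
    is.na(stats$bf10) | stats$bf10 < bfThreshold |
      (stats$bf10 >= bfThreshold & sign(stats$mean) == sgn)
  }
  100 * sum(ok) / nrow(stats)
}

#' Classify a participant against the mirror prediction
#'
#' Order of decision:
#' \enumerate{
#'   \item `no_training_effect` when the exponential decay fit of lateral
#'     deviation across training shows no decrease (non-positive amplitude,
#'     `k` below `kMin`, or decay not significant against a constant model
#'     at `trainAlpha`);
#'   \item `partially_compatible` when the after-effect angle derivative has
#'     a sustained (longer than `sustained` seconds) contiguous window of
#'     significantly positive values beginning after the movement-onset
#'     transient (`startAfter` seconds);
#'   \item `incompatible` otherwise.
#' }
#'
#' @param stats after-effect [timepointStats()]
#' @param decayFit result of [expDecayFit()] on the before-effect + adapted
#'   lateral deviations
#' @param alpha significance level of the per-timestep test
#' @param sustained minimum duration of a significant positive epoch (s);
#'   a genuine partial mirror shows an epoch of order 0.1-0.3 s
#' @param startAfter epochs beginning before this time are onset-convergence
#'   transients (the tangent settling onto its initial bearing), not mirror
#'   organization, and are ignored
#' @param kMin minimum decay rate counted as adaptation (per trial)
#' @param trainAlpha significance level of the decay F-test
#' @return list with `label` and the intermediate quantities
#' @export
classifyParticipant <- function(stats, decayFit, alpha = 0.05,
                                sustained = 0.1, startAfter = 0.08,
                                kMin = 0.005, trainAlpha = 0.001) {
  trained <- is.finite(decayFit$pDecay) && decayFit$pDecay < trainAlpha &&
    is.finite(decayFit$k) && decayFit$k >= kMin &&
    is.finite(decayFit$a) && decayFit$a > 0
  if (!trained)
    return(list(label = "no_training_effect", trained = FALSE,
                posEpoch = NA_real_))
  sigPos <- !is.na(stats$p) & stats$p <= alpha & stats$mean > 0
  r <- rle(sigPos)
  dt <- stats$t[2] - stats$t[1]
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & stats$t[starts] >= startAfter
  longest <- if (any(keep)) max(r$lengths[keep]) * dt else 0
  label <- if (longest > sustained) "partially_compatible" else "incompatible"
  list(label = label, trained = TRUE, posEpoch = longest)
}

#' Full statistical analysis of one participant
#'
#' Splits trials by category, keeps valid trials, computes the after-effect
#' per-timestep statistics, the percent-time summaries in both modes, the
#' exponential adaptation fit over the before-effect + adapted lateral
#' deviations (display convention), and the classification label.
#'
#' @param trials list of [reachTrial()] objects with category attributes, or
#'   a directory containing `trials.csv` written by [writeTrials()]
#' @param window analysis window (s)
#' @param cutoff low-pass cutoff (Hz)
#' @param filterValid drop trials failing [validTrial()]
#' @return list with `stats`, `percentP`, `percentBF`, `decayFit`,
#'   `classification`, `counts`
#' @export
participantStats <- function(trials, window = 0.4, cutoff = 10,
                             filterValid = TRUE) {
  if (is.character(trials))
    trials <- readTrials(file.path(trials, "trials.csv"))
  cats <- vapply(trials, function(tr) as.character(attr(tr, "category")),
                 character(1))
  if (filterValid) {
    keep <- vapply(trials, validTrial, logical(1))
    trials <- trials[keep]
    cats <- cats[keep]
  }
  counts <- table(factor(cats, levels = conditionLevels))
  aft <- trials[cats == "after_effect"]
  if (length(aft) < 2) stop("need at least 2 valid after-effect trials")
  stats <- timepointStats(aft, window = window, cutoff = cutoff)
  training <- trials[cats %in% c("before_effect", "adapted")]
  training <- training[order(match(cats[cats %in% c("before_effect",
                                                    "adapted")],
                                   c("before_effect", "adapted")))]
  dev <- vapply(training, function(tr)
    lateralDeviation(mirrorCcw(extractForward(tr))), numeric(1))
  # display convention: deviation with the field is negative (clockwise);
  # adaptation shrinks its magnitude
  fit <- expDecayFit(-dev)
  cls <- classifyParticipant(stats, fit)
  list(stats = stats,
       percentP = percentNullOrNegative(stats, "pvalue"),
       percentBF = percentNullOrNegative(stats, "bf"),
       decayFit = fit, classification = cls, counts = counts)
}
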