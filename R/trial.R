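#' Construct a reach trial
#'
#' A trial is one forward reach: a uniformly sampled planar hand path plus
#' metadata (sample rate, condition category, field direction, identifier).
#'
#' @param t time (s), strictly increasing with a uniform step
#' @param x,y hand position (m)
#' @param fs sample rate (Hz); inferred from `t` when `NULL`
#' @param category one of `"baseline"`, `"before_effect"`, `"adapted"`,
#'   `"after_effect"` (or `NA` for untagged simulations)
#' @param fieldSign `"CW"`, `"CCW"` or `"none"`
#' @param id trial identifier
#' @return an object of class `reachTrial` (a data frame with columns
#'   `t`, `x`, `y`)
#' @export
reachTrial <- function(t, x, y, fs = NULL, category = NA_character_,
                       fieldSign = "none", id = "trial") {
  if (length(t) < 2 || length(x) != length(t) || length(y) != length(t))
    stop("t, x, y must have equal length >= 2")
  dtv <- diff(t)
  if (any(dtv <= 0)) stop("time must be strictly increasing")
  if (diff(range(dtv)) > 1e-6 * mean(dtv))
    stop("time must be uniformly sampled")
  if (is.null(fs)) fs <- 1 / mean(dtv)
  out <- data.frame(t = t, x = x, y = y)
  attr(out, "fs") <- fs
  attr(out, "category") <- category
  attr(out, "fieldSign") <- fieldSign
  attr(out, "id") <- id
  class(out) <- c("reachTrial", "data.frame")
  out
}

trialMeta <- function(trial) {
  list(fs = attr(trial, "fs"), category = attr(trial, "category"),
       fieldSign = attr(trial, "fieldSign"), id = attr(trial, "id"))
}

withTrialMeta <- function(df, meta) {
  reachTrial(df$t, df$x, df$y, fs = meta$fs, category = meta$category,
             fieldSign = meta$fieldSign, id = meta$id)
}

#' @export
print.reachTrial <- function(x, ...) {
  m <- trialMeta(x)
  cat(sprintf("reach trial '%s': %d samples at %g Hz, %.3f s, category %s, field %s\n",
              m$id, nrow(x), m$fs, x$t[nrow(x)] - x$t[1],
              as.character(m$category), m$fieldSign))
  invisible(x)
}

#' Write trials to a tidy CSV file
#'
#' Columns are `trial_id, category, field_sign, t_s, x_m, y_m`; one row per
#' sample, all trials stacked.
#'
#' @param trials a list of [reachTrial()] objects (or a single trial)
#' @param path output file
#' @return `path`, invisibly
#' @export
writeTrials <- function(trials, path) {
  if (inherits(trials, "reachTrial")) trials <- list(trials)
  rows <- lapply(trials, function(tr) {
    m <- trialMeta(tr)
    data.frame(trial_id = m$id, category = as.character(m$category),
               field_sign = m$fieldSign, t_s = tr$t, x_m = tr$x, y_m = tr$y)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read trials from a tidy CSV file
#'
#' @param path file written by [writeTrials()] (columns `trial_id, category,
#'   field_sign, t_s, x_m, y_m`)
#' @return list of [reachTrial()] objects
#' @export
readTrials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "category", "field_sign", "t_s", "x_m", "y_m")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("no trials in file ", path)
  ids <- unique(df$trial_id)
  lapply(ids, function(id) {
    d <- df[df$trial_id == id, ]
    if (any(diff(d$t_s) <= 0))
      stop("non-increasing time in trial ", id)
    reachTrial(d$t_s, d$x_m, d$y_m, category = d$category[1],
               fieldSign = d$field_sign[1], id = id)
  })
}
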