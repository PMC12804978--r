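#' Bud-break timing heterogeneity
#'
#' Mean, sample variance (n - 1 denominator, appropriate for the small
#' cohorts of 10-15 plants typical of bud-break assays) and coefficient of
#' variation (standard deviation / mean, dimensionless) of the
#' days-to-bud-break of one condition. The CV is the heterogeneity measure:
#' a synchronized cohort has CV near 0, a bet-hedging cohort a large CV.
#'
#' @param sample a [TimingSample-class].
#' @param cv_percent report the CV as a percentage instead of a ratio.
#' @return named numeric: `mean`, `variance`, `cv`.
#' @export
heterogeneity <- function(sample, cv_percent = FALSE) {
  stopifnot(is(sample, "TimingSample"))
  d <- budBreakDays(sample)
  if (length(d) < 2)
    stop("insufficient events: at least 2 bud-break days required")
  m <- mean(d)
  v <- stats::var(d)
  cv <- sqrt(v) / m
  c(mean = m, variance = v, cv = if (cv_percent) 100 * cv else cv)
}

#' Percent bud break
#'
#' Fraction of assayed plants that broke bud, as a percentage.
#'
#' @param sample a [TimingSample-class].
#' @return numeric percentage in 0..100.
#' @export
percentBudbreak <- function(sample) {
  stopifnot(is(sample, "TimingSample"))
  if (nTotal(sample) < 1) stop("no plants assayed")
  100 * length(budBreakDays(sample)) / nTotal(sample)
}

#' Histogram of bud-break days
#'
#' Left-closed, right-open bins of the given width spanning
#' `floor(min(days))` to at least `ceiling(max(days))`. Counts always sum to
#' the number of bud-break events.
#'
#' @param sample a [TimingSample-class].
#' @param bin_width bin width in days (> 0).
#' @return data.frame: `bin_start`, `bin_end`, `count`.
#' @export
timingHistogram <- function(sample, bin_width = 1) {
  stopifnot(is(sample, "TimingSample"), bin_width > 0)
  d <- budBreakDays(sample)
  if (!length(d)) stop("no bud-break events to bin")
  lo <- floor(min(d))
  hi <- ceiling(max(d))
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  idx <- findInterval(d, breaks, rightmost.closed = FALSE)
  cnt <- tabulate(idx, nbins = length(breaks) - 1)
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             count = cnt)
}

#' Read per-plant bud-break records
#'
#' Reads a CSV with columns `plant_id`, `label`, `day_of_budbreak` (blank =
#' the plant never broke bud) and groups it into one [TimingSample-class]
#' per label.
#'
#' @param path CSV file path.
#' @return named list of [TimingSample-class] objects, one per label.
#' @export
readBudbreakCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "label", "day_of_budbreak")
  if (!all(need %in% names(df)))
    stop(sprintf("bud-break CSV must have columns: %s",
                 paste(need, collapse = ", ")))
  out <- lapply(split(df, df$label), function(g) {
    days <- suppressWarnings(as.numeric(g$day_of_budbreak))
    TimingSample(label = g$label[1], days = days[!is.na(days)],
                 nTotal = nrow(g))
  })
  out[order(names(out))]
}

#' Summarize bud-break cohorts
#'
#' One row per condition with counts, percent bud break, mean, sample
#' variance and CV (variance and CV reported side by side; the CV column is
#' the dimensionless ratio).
#'
#' @param samples list of [TimingSample-class] objects.
#' @param path optional CSV path to write the summary to.
#' @return data.frame: label, n_total, n_broken, percent, mean, variance, cv.
#' @export
summarizeBudbreak <- function(samples, path = NULL) {
  rows <- lapply(samples, function(s) {
    h <- if (length(budBreakDays(s)) >= 2) heterogeneity(s) else
      c(mean = if (length(budBreakDays(s))) mean(budBreakDays(s)) else NA_real_,
        variance = NA_real_, cv = NA_real_)
    data.frame(label = sampleLabel(s), n_total = nTotal(s),
               n_broken = length(budBreakDays(s)),
               percent = if (nTotal(s) >= 1) percentBudbreak(s) else NA_real_,
               mean = unname(h["mean"]), variance = unname(h["variance"]),
               cv = unname(h["cv"]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
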