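# Agreement analysis between exposure metrics: Bland-Altman with a
# difference-vs-mean regression line, R-squared with verbal agreement
# categories, distribution summary tables, and the mean-of-50 vs
# single-random-realization experiment.

#' Bland-Altman agreement analysis
#'
#' For paired exposures, computes differences `x - y` and pair means
#' `(x + y) / 2`, the mean difference (bias), the SD of differences, the 95%
#' limits of agreement `mean_diff +/- 1.96 * sd_diff`, and an ordinary
#' least-squares regression of the difference on the pair mean (slope,
#' intercept, R-squared) — the proportional-bias diagnostic. Pairs with any
#' missing value are dropped listwise.
#'
#' @param x,y equal-length numeric vectors of paired exposures; the
#'   difference is oriented `x - y`.
#' @param labels length-2 character naming the pair (for printing).
#' @return An object of class `bland_altman`: n_pairs, mean_diff, sd_diff,
#'   loa_low, loa_high, slope, intercept, r2_diff_vs_mean, plus the retained
#'   diffs/means.
#' @export
bland_altman <- function(x, y, labels = c("x", "y")) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("at least 3 complete pairs are required", call. = FALSE)
  d <- x - y
  m <- (x + y) / 2
  if (stats::var(m) == 0)
    stop("zero variance of pair means: regression slope undefined",
         call. = FALSE)
  fit <- stats::lm(d ~ m)
  sd_d <- stats::sd(d)
  r2 <- if (stats::var(d) == 0) 0 else summary(fit)$r.squared
  structure(list(
    n_pairs = length(x), labels = labels,
    mean_diff = mean(d), sd_diff = sd_d,
    loa_low = mean(d) - 1.96 * sd_d, loa_high = mean(d) + 1.96 * sd_d,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2_diff_vs_mean = r2,
    diffs = d, means = m), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> %s - %s, n = %d\n",
              x$labels[1], x$labels[2], x$n_pairs))
  cat(sprintf("  mean diff %.3f (LoA %.3f to %.3f)\n",
              x$mean_diff, x$loa_low, x$loa_high))
  cat(sprintf("  diff ~ mean: slope %.3f, intercept %.3f, R2 %.3f\n",
              x$slope, x$intercept, x$r2_diff_vs_mean))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences against pair means with the mean-difference line, the 95%
#' limits of agreement and the difference-vs-mean regression line.
#'
#' @param x a [bland_altman()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs,
                 xlab = sprintf("(%s + %s) / 2", x$labels[1], x$labels[2]),
                 ylab = sprintf("%s - %s", x$labels[1], x$labels[2]),
                 pch = 16, col = grDevices::grey(0.3, 0.6), ...)
  graphics::abline(h = x$mean_diff, col = "blue", lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "red", lty = 3)
  graphics::abline(x$intercept, x$slope, col = "goldenrod", lwd = 2)
  invisible(x)
}

#' Coefficient of determination of paired exposures
#'
#' Squared Pearson correlation; sign-blind (anti-correlation also gives 1).
#' Missing pairs are dropped listwise.
#'
#' @param x,y equal-length numeric vectors.
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("at least 3 complete pairs are required", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("R-squared undefined: zero variance", call. = FALSE)
  stats::cor(x, y)^2
}

#' Verbal agreement category of an R-squared value
#'
#' Bands: weak (< 0.16), moderate (0.16-0.36), moderately strong
#' (> 0.36-0.64), strong (> 0.64-0.81), very strong (> 0.81). Each band is
#' closed at its upper bound, and 0.16 itself counts as moderate.
#'
#' @param r2 numeric in `[0, 1]` (vectorised).
#' @return Character vector of categories.
#' @export
classify_agreement <- function(r2) {
  if (any(r2 < 0 | r2 > 1))
    stop("r2 must lie in [0, 1]", call. = FALSE)
  ifelse(r2 < 0.16, "weak",
    ifelse(r2 <= 0.36, "moderate",
      ifelse(r2 <= 0.64, "moderately strong",
        ifelse(r2 <= 0.81, "strong", "very strong"))))
}

#' Exposure distribution summary table
#'
#' Per (metric, pollutant): n of non-missing records, mean, sample SD, 25th /
#' 50th / 75th percentiles (linear-interpolation quantiles, type 7) and IQR.
#' Cells with no non-missing record are omitted with a message.
#'
#' @param records exposure-record data frame (e.g. [cohort_exposures()]).
#' @return Data frame with one row per (metric, pollutant).
#' @export
exposure_summary <- function(records) {
  rows <- list()
  for (pol in unique(records$pollutant)) {
    for (met in unique(records$metric[records$pollutant == pol])) {
      v <- records$mean[records$pollutant == pol & records$metric == met]
      v <- v[!is.na(v)]
      if (length(v) == 0L) {
        message("no non-missing records for ", met, "/", pol, "; row omitted")
        next
      }
      q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = met, pollutant = pol, n = length(v),
        mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
        per25 = q[1], median = q[2], per75 = q[3], iqr = q[3] - q[1],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean-of-50 versus single-random-realization experiment
#'
#' Compares the agreement of residential exposure with (a) the mean over all
#' Monte Carlo realizations and (b) one uniformly drawn realization per
#' agent. Averaging over realizations removes work-location noise, so (a) is
#' expected to correlate more strongly with RES than (b).
#'
#' @param res numeric vector of RES exposures (one per agent).
#' @param realization_matrix agents x realizations matrix of per-realization
#'   exposures (rows aligned with `res`); agents with any `NA` are skipped.
#' @param seed integer seed for the uniform draw.
#' @return List with `r2_mean50`, `r2_single`, `drawn_idx` (per retained
#'   agent) and `n_agents`.
#' @export
single_draw_experiment <- function(res, realization_matrix, seed = 1L) {
  stopifnot(length(res) == nrow(realization_matrix))
  keep <- !is.na(res) & !apply(realization_matrix, 1, anyNA)
  if (sum(!keep) > 0)
    message(sum(!keep), " agent(s) without complete realization sets skipped")
  res <- res[keep]
  rm_mat <- realization_matrix[keep, , drop = FALSE]
  mean50 <- rowMeans(rm_mat)
  drawn <- with_seed(derive_seed(seed, "single-draw"), {
    sample.int(ncol(rm_mat), nrow(rm_mat), replace = TRUE)
  })
  single <- rm_mat[cbind(seq_len(nrow(rm_mat)), drawn)]
  list(r2_mean50 = r_squared(res, mean50),
       r2_single = r_squared(res, single),
       drawn_idx = drawn, n_agents = length(res))
}
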