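#' Relative difference between two measurements
#'
#' `|a - b| * 100 / mean(a, b)`, in percent — the symmetric, scale-free
#' difference used to summarize intra- and interobserver variability of
#' repeated area measurements.
#'
#' @param a,b numeric measurements (vectorized pairwise).
#' @return relative difference(s) in percent (always >= 0).
#' @examples
#' relative_difference(0.88, 0.98)  # 10.75...%
#' @export
relative_difference <- function(a, b) {
  m <- (a + b) / 2
  if (any(m == 0))
    ava_stop("relative difference undefined: mean of the pair is zero",
             "ava_input_error")
  abs(a - b) * 100 / m
}

#' Bland-Altman agreement between two measurement methods
#'
#' Pairwise differences `x - y` are summarized by their mean (the bias),
#' SD (n - 1 denominator) and 95% limits of agreement
#' `mean ± 1.96 * SD`, together with a two-sided one-sample t test of zero
#' mean difference and the 95% confidence interval *of the mean
#' difference* — a much narrower interval than the limits of agreement,
#' reported separately to keep the two apart. With zero-variance
#' differences the t test degenerates: `bias_p` is 1 when the constant
#' difference is 0 and 0 otherwise.
#'
#' @param x,y equal-length numeric vectors of paired measurements
#'   (n >= 3).
#' @return An object of class `ava_agreement`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `bias_p`, `ci_low`, `ci_high` (95% CI of the
#'   mean difference), `n`, plus `means` and `diffs` for plotting.
#' @seealso [plot.ava_agreement()]
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y))
    ava_stop("x and y must have the same length", "ava_input_error")
  if (length(x) < 3L)
    ava_stop("at least 3 pairs are required", "ava_input_error")
  diffs <- x - y
  means <- (x + y) / 2
  m <- mean(diffs)
  s <- stats::sd(diffs)
  n <- length(diffs)
  if (s == 0) {
    p <- if (m == 0) 1 else 0
    ci <- c(m, m)
  } else {
    tt <- stats::t.test(diffs, mu = 0)
    p <- tt$p.value
    ci <- as.numeric(tt$conf.int)
  }
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 bias_p = p, ci_low = ci[1], ci_high = ci[2], n = n,
                 means = means, diffs = diffs),
            class = "ava_agreement")
}

#' @export
print.ava_agreement <- function(x, ...) {
  cat(sprintf("<ava_agreement> n = %d pairs\n", x$n))
  cat(sprintf("  mean difference %.3f (95%% CI of mean: %.3f to %.3f), p = %.4g\n",
              x$mean_diff, x$ci_low, x$ci_high, x$bias_p))
  cat(sprintf("  limits of agreement %.3f to %.3f (mean +/- 1.96 SD, SD = %.3f)\n",
              x$loa_low, x$loa_high, x$sd_diff))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences against pair means, with the bias and 95% limits of
#' agreement as horizontal lines.
#'
#' @param x an `ava_agreement` from [bland_altman()].
#' @param xlab,ylab,main usual plot labels.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ava_agreement <- function(x, xlab = "Mean of methods",
                               ylab = "Difference between methods",
                               main = "Bland-Altman agreement", ...) {
  graphics::plot(x$means, x$diffs, xlab = xlab, ylab = ylab, main = main,
                 pch = 19, col = "grey30", ...)
  graphics::abline(h = x$mean_diff, lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Observer variability from paired repeated measurements
#'
#' Per-pair relative differences (see [relative_difference()]) summarized
#' as mean ± SD percent — the intra-/interobserver variability statistic.
#' Pairs with zero mean are excluded with a warning.
#'
#' @param m1,m2 equal-length numeric vectors of repeated measurements.
#' @return list of class `ava_variability`: `per_pair_relative_diff` (%),
#'   `mean_rd`, `sd_rd`, `n` (pairs used).
#' @export
observer_variability <- function(m1, m2) {
  if (length(m1) != length(m2))
    ava_stop("m1 and m2 must have the same length", "ava_input_error")
  meanv <- (m1 + m2) / 2
  bad <- meanv == 0
  if (any(bad)) {
    warning(sprintf("%d pair(s) with zero mean excluded", sum(bad)),
            call. = FALSE)
    m1 <- m1[!bad]; m2 <- m2[!bad]
  }
  rd <- relative_difference(m1, m2)
  structure(list(per_pair_relative_diff = rd,
                 mean_rd = mean(rd),
                 sd_rd = if (length(rd) > 1L) stats::sd(rd) else 0,
                 n = length(rd)),
            class = "ava_variability")
}

#' @export
print.ava_variability <- function(x, ...) {
  cat(sprintf("<ava_variability> %.2f +/- %.2f %% over %d pairs\n",
              x$mean_rd, x$sd_rd, x$n))
  invisible(x)
}
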