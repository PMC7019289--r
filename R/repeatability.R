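#' Bundle paired test-retest measurements
#'
#' Holds one measurement per session for each participant. Pairs in which
#' either member is missing are excluded up front (only measurements with
#' data from both sessions enter the analysis); the number of dropped pairs
#' is kept as an attribute and reported via `message()`.
#'
#' @param test,retest Numeric vectors of equal length (first and second
#'   session).
#' @param id Optional identifiers.
#' @param units Unit label (e.g. `"log10 mM"`).
#' @param scale `"raw"` or `"log10"`.
#' @return An object of class `paired_measurements`.
#' @export
paired_measurements <- function(test, retest, id = NULL, units = "",
                                scale = c("raw", "log10")) {
  scale <- match.arg(scale)
  if (length(test) != length(retest)) {
    stop("test and retest must have equal length")
  }
  if (is.null(id)) id <- seq_along(test)
  keep <- is.finite(test) & is.finite(retest)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " incomplete pair(s) dropped (data from both sessions required)")
  }
  structure(
    list(id = id[keep], test = test[keep], retest = retest[keep],
         units = units, scale = scale),
    class = "paired_measurements", n_dropped = n_dropped
  )
}

#' Spearman rank correlation between sessions
#'
#' Rank correlation (Pearson correlation of midranks; ties receive average
#' ranks) quantifying the monotonic relationship between test and retest
#' measurements. Note that a high correlation does not by itself establish
#' repeatability — it ignores systematic offsets — which is why it is
#' complemented by the Bland-Altman statistics of [agreement()].
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for constant input")
  }
  stats::cor(x, y, method = "spearman")
}

# z-score for the 95% limits; kept as the conventional literal so that
# CR = 1.96 * sd holds exactly
.Z95 <- 1.96

#' Bland-Altman agreement statistics for paired measurements
#'
#' Computes the difference-based repeatability summary for test-retest data:
#' differences `d = test - retest`, their mean `d_bar` and sample SD `sd`
#' (n-1 denominator), the coefficient of repeatability `CR = 1.96 * sd`
#' (95% of absolute repeat differences are expected below it), the 95%
#' limits of agreement `LoA = d_bar +/- CR`, and 95% confidence intervals:
#' for the mean difference `d_bar +/- 1.96 * sd / sqrt(n)`, and for the LoAs
#' either the exact-paired method (noncentral-t construction, default) or a
#' labeled normal approximation `LoA +/- 1.96 * sd * sqrt(3/n)`.
#' The alternative within-participant-SD pathway is also reported:
#' `sw = sqrt(mean((test - retest)^2 / 2))` and `CR' = 1.96 * sqrt(2) * sw`.
#'
#' @param pairs A [paired_measurements()] object.
#' @param loa_ci_method `"exact"` (noncentral t) or `"approx"`.
#' @return An object of class `agreement_stats`: `n`, `mean_diff`, `sd_diff`,
#'   `cr`, `loa_low`, `loa_high`, `ci_mean_diff`, `ci_loa_low`, `ci_loa_high`
#'   (each a length-2 vector), `sw`, `cr_sw`, `scale`, `units`,
#'   `loa_ci_method`.
#' @export
agreement <- function(pairs, loa_ci_method = c("exact", "approx")) {
  stopifnot(inherits(pairs, "paired_measurements"))
  loa_ci_method <- match.arg(loa_ci_method)
  n <- length(pairs$test)
  if (n < 2) stop("need at least 2 complete pairs")
  d <- pairs$test - pairs$retest
  d_bar <- mean(d)
  sd_d <- stats::sd(d)
  cr <- .Z95 * sd_d
  se_mean <- sd_d / sqrt(n)
  ci_mean <- d_bar + c(-1, 1) * .Z95 * se_mean
  if (loa_ci_method == "exact") {
    # exact paired method: bounds d_bar + (t'/sqrt(n)) * sd with t' the
    # 2.5%/97.5% quantiles of the noncentral t, df = n-1, ncp = 1.96*sqrt(n)
    # qt warns that noncentral quantiles reach ~1e-6 precision only; ample here
    tq <- suppressWarnings(
      stats::qt(c(0.025, 0.975), df = n - 1, ncp = .Z95 * sqrt(n)))
    ci_hi <- d_bar + tq / sqrt(n) * sd_d
    ci_lo <- d_bar - rev(tq) / sqrt(n) * sd_d
  } else {
    half <- .Z95 * sd_d * sqrt(3 / n)
    ci_hi <- (d_bar + cr) + c(-1, 1) * half
    ci_lo <- (d_bar - cr) + c(-1, 1) * half
  }
  sw <- sqrt(mean(d^2 / 2))
  structure(
    list(n = n, mean_diff = d_bar, sd_diff = sd_d, cr = cr,
         loa_low = d_bar - cr, loa_high = d_bar + cr,
         ci_mean_diff = ci_mean, ci_loa_low = ci_lo, ci_loa_high = ci_hi,
         sw = sw, cr_sw = .Z95 * sqrt(2) * sw,
         scale = pairs$scale, units = pairs$units,
         loa_ci_method = loa_ci_method),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d pairs, %s scale%s)\n",
              x$n, x$scale,
              if (nzchar(x$units)) paste0(", ", x$units) else ""))
  cat(sprintf("  mean difference  %.4f  [%.4f, %.4f]\n",
              x$mean_diff, x$ci_mean_diff[1], x$ci_mean_diff[2]))
  cat(sprintf("  SD of differences %.4f\n", x$sd_diff))
  cat(sprintf("  CR = 1.96 x sd   %.4f   (sw pathway: %.4f)\n", x$cr, x$cr_sw))
  cat(sprintf("  LoA              [%.4f, %.4f]\n", x$loa_low, x$loa_high))
  cat(sprintf("  LoA CIs (%s)  low [%.4f, %.4f]  high [%.4f, %.4f]\n",
              x$loa_ci_method, x$ci_loa_low[1], x$ci_loa_low[2],
              x$ci_loa_high[1], x$ci_loa_high[2]))
  invisible(x)
}

#' Agreement statistics on the log10 scale
#'
#' For quantities whose between-session differences scale with their
#' magnitude (false-alarm rates, notably), the Bland-Altman machinery is
#' applied after a decadic log transform: both sessions are log10-ed, then
#' [agreement()] runs unchanged. Results live on the log10 scale; use
#' [back_transform()] to express them in the original coordinate system.
#'
#' @inheritParams agreement
#' @return An `agreement_stats` object with `scale = "log10"`.
#' @export
log_agreement <- function(pairs, loa_ci_method = c("exact", "approx")) {
  stopifnot(inherits(pairs, "paired_measurements"))
  if (any(pairs$test <= 0 | pairs$retest <= 0)) {
    stop("log10 pathway requires strictly positive measurements")
  }
  lp <- paired_measurements(log10(pairs$test), log10(pairs$retest),
                            id = pairs$id,
                            units = paste0("log10 ", pairs$units),
                            scale = "log10")
  agreement(lp, loa_ci_method = loa_ci_method)
}

#' Back-transform a log10-scale agreement quantity to the original scale
#'
#' A quantity `ylog` computed on log10-transformed data (a mean difference,
#' CR, or LoA bound) maps back to the original coordinate system as
#' `2 * M * (10^ylog - 1) / (10^ylog + 1)`, where `M` is a session mean on
#' the original scale. The back-transformed quantity is therefore a line
#' through the origin as a function of `M`, not a single value, and it is odd
#' in `ylog`.
#'
#' @param ylog Quantity on the log10 scale. Vectorized.
#' @param M Session mean(s) on the original scale.
#' @return Original-scale quantity (same shape as `ylog * M`).
#' @export
back_transform <- function(ylog, M) {
  2 * M * (10^ylog - 1) / (10^ylog + 1)
}

#' Express a coefficient of repeatability in concentration steps
#'
#' Divides a CR measured in log10 mM by the ladder's log10 step width, giving
#' the expected between-session difference in units of physical concentration
#' steps — comparable across tastants with different ranges.
#'
#' @param cr_log10 CR in log10 mM.
#' @param grid A [build_log_grid()] ladder.
#' @return CR in concentration steps.
#' @export
cr_in_steps <- function(cr_log10, grid) {
  stopifnot(inherits(grid, "tastant_grid"), grid$step_width > 0)
  cr_log10 / grid$step_width
}

#' Bland-Altman plot
#'
#' Differences between sessions plotted against session means, with the mean
#' difference and 95% limits of agreement as dashed lines and their
#' confidence intervals shaded. With `log10_pathway = TRUE` the statistics
#' are computed on the log scale and the lines are back-transformed, giving
#' limits that fan out with the session mean. Requires ggplot2.
#'
#' @param pairs A [paired_measurements()] object.
#' @param log10_pathway Compute statistics on the log10 scale and
#'   back-transform the lines.
#' @param loa_ci_method Passed to [agreement()].
#' @return A ggplot object.
#' @export
bland_altman_plot <- function(pairs, log10_pathway = FALSE,
                              loa_ci_method = "exact") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("bland_altman_plot requires the ggplot2 package")
  }
  m <- (pairs$test + pairs$retest) / 2
  d <- pairs$test - pairs$retest
  df <- data.frame(mean = m, diff = d)
  if (log10_pathway) {
    st <- log_agreement(pairs, loa_ci_method = loa_ci_method)
    xs <- seq(min(m), max(m), length.out = 100)
    lines <- data.frame(
      mean = xs,
      mid = back_transform(st$mean_diff, xs),
      lo = back_transform(st$loa_low, xs),
      hi = back_transform(st$loa_high, xs))
  } else {
    st <- agreement(pairs, loa_ci_method = loa_ci_method)
    xs <- range(m)
    lines <- data.frame(mean = xs, mid = st$mean_diff,
                        lo = st$loa_low, hi = st$loa_high)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = lines, ggplot2::aes(y = .data$mid),
                       linetype = "dashed") +
    ggplot2::geom_line(data = lines, ggplot2::aes(y = .data$lo),
                       linetype = "dashed") +
    ggplot2::geom_line(data = lines, ggplot2::aes(y = .data$hi),
                       linetype = "dashed") +
    ggplot2::labs(x = paste("Session mean", pairs$units),
                  y = paste("Test - Retest", pairs$units))
}
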