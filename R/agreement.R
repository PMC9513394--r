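#' Paired measurements of the same lesions
#'
#' The unit of every agreement statistic: two values per lesion, either
#' two raters with one method or two methods with one rater. Values must
#' be complete and equal length.
#'
#' @param a,b numeric vectors of paired values (same length, no missing).
#' @param labels optional per-lesion identifiers.
#' @return An object of class \code{abus_pairs}.
#' @export
paired_measurements <- function(a, b, labels = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("paired measurements must have equal length")
  if (length(a) < 1L) stop("paired measurements must be non-empty")
  if (anyNA(a) || anyNA(b) || any(!is.finite(a)) || any(!is.finite(b)))
    stop("paired measurements must be finite and complete")
  if (is.null(labels)) labels <- seq_along(a)
  if (length(labels) != length(a)) stop("labels length mismatch")
  structure(list(labels = labels, a = a, b = b), class = "abus_pairs")
}

as_pairs <- function(a, b = NULL, labels = NULL) {
  if (inherits(a, "abus_pairs")) return(a)
  paired_measurements(a, b, labels)
}

#' Wilcoxon signed-rank test for paired measurements
#'
#' Ranks the absolute paired differences d = a - b (mid-ranks on ties) and
#' sums the ranks by sign of d, giving the positive and negative rank sums
#' W+ and W-. Zero differences are either dropped before ranking
#' (\code{"drop"}, the classical test) or ranked with everything else and
#' then excluded from both sums (\code{"pratt"}).
#'
#' The two-sided p-value is exact — the null distribution of W+ over all
#' 2^n sign assignments, computed by dynamic programming — when n <= 25 and
#' the nonzero |d| are tie-free under the drop policy; otherwise a normal
#' approximation with tie correction and a 0.5 continuity correction is
#' used. \code{p_mode} can force either route.
#'
#' @param a,b paired values; \code{a} may be an \code{abus_pairs}, or a
#'   vector of precomputed differences when \code{b} is \code{NULL}.
#' @param zero_policy \code{"drop"} (default) or \code{"pratt"}.
#' @param p_mode \code{"auto"} (default), \code{"exact"} or \code{"normal"}.
#' @return An object of class \code{abus_wilcoxon} with \code{w_plus},
#'   \code{w_minus}, \code{n_used} (nonzero differences), \code{p_value},
#'   \code{p_method}, and \code{degenerate} (TRUE when all differences are
#'   zero, in which case p = 1).
#' @examples
#' wilcoxon_signed_rank(c(1, -2, 3))  # W+ = 4, W- = 2
#' @export
wilcoxon_signed_rank <- function(a, b = NULL,
                                 zero_policy = c("drop", "pratt"),
                                 p_mode = c("auto", "exact", "normal")) {
  zero_policy <- match.arg(zero_policy)
  p_mode <- match.arg(p_mode)
  d <- if (inherits(a, "abus_pairs")) a$a - a$b
       else if (is.null(b)) as.numeric(a)
       else as_pairs(a, b)$a - as_pairs(a, b)$b
  if (length(d) < 1L) stop("need at least one difference")

  nonzero <- d != 0
  if (!any(nonzero)) {
    warning("degenerate test: all differences are zero")
    return(structure(list(w_plus = 0, w_minus = 0, n_used = 0L, p_value = 1,
                          p_method = "degenerate", zero_policy = zero_policy,
                          degenerate = TRUE),
                     class = "abus_wilcoxon"))
  }

  if (zero_policy == "drop") {
    dz <- d[nonzero]
    r <- rank(abs(dz))
    w_plus <- sum(r[dz > 0]); w_minus <- sum(r[dz < 0])
  } else {
    r_all <- rank(abs(d))
    w_plus <- sum(r_all[d > 0]); w_minus <- sum(r_all[d < 0])
    dz <- d[nonzero]
    r <- r_all[nonzero]
  }
  n <- sum(nonzero)
  ties <- anyDuplicated(abs(dz)) > 0L

  exact_ok <- n <= 25L && !ties && zero_policy == "drop"
  if (p_mode == "exact" && !exact_ok)
    stop("exact p-value requires drop policy, n <= 25 and tie-free |d|")
  use_exact <- (p_mode == "exact") || (p_mode == "auto" && exact_ok)

  if (use_exact) {
    p <- signed_rank_exact_p(w_plus, n)
    method <- "exact"
  } else {
    # normal approximation on W+ with tie and continuity corrections;
    # under pratt, zero ranks shift the null mean of W+ downward
    if (zero_policy == "pratt") {
      n_all <- length(d)
      n0 <- n_all - n
      mu <- (n_all * (n_all + 1) / 2 - n0 * (n0 + 1) / 2) / 2
      sig2 <- n_all * (n_all + 1) * (2 * n_all + 1) / 24 -
        n0 * (n0 + 1) * (2 * n0 + 1) / 24
      tie_tab <- table(abs(dz))
    } else {
      mu <- n * (n + 1) / 4
      sig2 <- n * (n + 1) * (2 * n + 1) / 24
      tie_tab <- table(abs(dz))
    }
    tie_corr <- sum(tie_tab^3 - tie_tab) / 48
    sig2 <- sig2 - tie_corr
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }

  structure(list(w_plus = w_plus, w_minus = w_minus, n_used = n,
                 p_value = p, p_method = method, zero_policy = zero_policy,
                 degenerate = FALSE),
            class = "abus_wilcoxon")
}

# exact two-sided p for W+ = w with n tie-free nonzero differences:
# null counts of each achievable rank sum by DP convolution over ranks
# 1..n (equivalent to enumerating all 2^n sign vectors)
signed_rank_exact_p <- function(w, n) {
  maxw <- n * (n + 1) / 2
  counts <- numeric(maxw + 1L)
  counts[1L] <- 1
  for (k in seq_len(n)) {
    shifted <- c(numeric(k), counts[seq_len(maxw + 1L - k)])
    counts <- counts + shifted
  }
  total <- 2^n
  lower <- sum(counts[seq_len(floor(w) + 1L)]) / total      # P(W+ <= w)
  upper <- sum(counts[(floor(w) + 1L):(maxw + 1L)]) / total # P(W+ >= w)
  min(1, 2 * min(lower, upper))
}

#' @export
print.abus_wilcoxon <- function(x, ...) {
  cat("Wilcoxon signed-rank test\n")
  cat(sprintf("  W+ = %g, W- = %g  (n = %d nonzero, zeros: %s)\n",
              x$w_plus, x$w_minus, x$n_used, x$zero_policy))
  cat(sprintf("  two-sided p = %.4g (%s)\n", x$p_value, x$p_method))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean of paired differences a - b), sample SD of the differences,
#' and limits of agreement bias +/- k * SD (k = 1.96 by default, the
#' interval expected to contain ~95% of differences under normality).
#' Lesions whose difference falls outside the limits are flagged.
#'
#' @inheritParams wilcoxon_signed_rank
#' @param k limits-of-agreement multiplier (default 1.96).
#' @return An object of class \code{abus_bland_altman} with \code{bias},
#'   \code{sd}, \code{loa_low}, \code{loa_high}, \code{k},
#'   \code{outside_indices}, plus the per-lesion \code{means} and
#'   \code{differences} used for plotting.
#' @export
bland_altman <- function(a, b = NULL, k = 1.96) {
  pairs <- if (inherits(a, "abus_pairs")) a else as_pairs(a, b)
  n <- length(pairs$a)
  if (n < 2L) stop("insufficient data: Bland-Altman needs at least 2 pairs")
  d <- pairs$a - pairs$b
  bias <- mean(d)
  s <- stats::sd(d)
  lo <- bias - k * s; hi <- bias + k * s
  outside <- which(d < lo | d > hi)
  structure(list(bias = bias, sd = s, loa_low = lo, loa_high = hi, k = k,
                 outside_indices = outside, labels = pairs$labels,
                 means = (pairs$a + pairs$b) / 2, differences = d),
            class = "abus_bland_altman")
}

#' @export
print.abus_bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement\n")
  cat(sprintf("  bias = %.4g, SD = %.4g\n", x$bias, x$sd))
  cat(sprintf("  limits of agreement (k = %g): [%.4g, %.4g]\n",
              x$k, x$loa_low, x$loa_high))
  cat(sprintf("  %d of %d points outside the limits\n",
              length(x$outside_indices), length(x$differences)))
  invisible(x)
}

#' @export
plot.abus_bland_altman <- function(x, xlab = "Mean of paired measurements",
                                   ylab = "Difference", main = "Bland-Altman plot",
                                   ...) {
  graphics::plot(x$means, x$differences, xlab = xlab, ylab = ylab,
                 main = main, pch = 19, ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  if (length(x$outside_indices))
    graphics::points(x$means[x$outside_indices],
                     x$differences[x$outside_indices], pch = 1, cex = 2)
  invisible(x)
}

#' Summary statistics of a sample
#'
#' Mean, sample SD (n - 1 denominator), median and quartiles. Quartiles
#' use linear interpolation of order statistics (\code{stats::quantile}
#' type 5 by default), the convention that reproduces the packaged study
#' table's printed values.
#'
#' @param x numeric vector, non-empty.
#' @param quantile_type passed to \code{stats::quantile}.
#' @return named list with \code{mean}, \code{sd} (NA when n < 2),
#'   \code{median}, \code{q1}, \code{q3}, \code{n}.
#' @export
summary_stats <- function(x, quantile_type = 5) {
  x <- as.numeric(x)
  if (length(x) < 1L || anyNA(x)) stop("insufficient data: need non-empty, complete input")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = quantile_type, names = FALSE)
  list(mean = mean(x),
       sd = if (length(x) >= 2L) stats::sd(x) else NA_real_,
       median = q[2L], q1 = q[1L], q3 = q[3L], n = length(x))
}

#' Per-lesion ratio summary of two methods
#'
#' The ratio r_i = a_i / b_i per lesion, with mean, sample SD and the mean
#' -/+ 2 SD interval (the dispersion interval the study literature reports
#' for method ratios). All denominators must be strictly positive.
#'
#' @inheritParams wilcoxon_signed_rank
#' @return An object of class \code{abus_ratio} with \code{mean_ratio},
#'   \code{sd_ratio}, \code{interval_low}, \code{interval_high},
#'   \code{ratios}.
#' @export
ratio_summary <- function(a, b = NULL) {
  pairs <- if (inherits(a, "abus_pairs")) a else as_pairs(a, b)
  if (any(pairs$b <= 0)) stop("invalid ratio: denominators must be positive")
  r <- pairs$a / pairs$b
  m <- mean(r)
  s <- if (length(r) >= 2L) stats::sd(r) else 0
  structure(list(mean_ratio = m, sd_ratio = s,
                 interval_low = m - 2 * s, interval_high = m + 2 * s,
                 ratios = r),
            class = "abus_ratio")
}

#' @export
print.abus_ratio <- function(x, ...) {
  cat(sprintf("Ratio summary: mean %.3f, SD %.3f, mean +/- 2SD [%.3f, %.3f]\n",
              x$mean_ratio, x$sd_ratio, x$interval_low, x$interval_high))
  invisible(x)
}
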