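#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average (midrank) ranks, with the two-sided
#' p-value from the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' on `n - 2` degrees of freedom (the approximation used by mainstream
#' statistical software for moderate n). Pairs with a missing value in
#' either vector are dropped (pairwise-complete).
#'
#' @param x,y Numeric vectors of equal length; at least 3 complete pairs.
#' @return A one-row tibble with columns `rho`, `n`, `p`. If either vector
#'   is constant after pairwise deletion, `rho` and `p` are `NA` (undefined
#'   correlation) with a warning.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)) # rho = 0.6
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    rlang::abort("`x` and `y` must have the same length.")
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) {
    rlang::abort("Need at least 3 complete pairs for a rank correlation.")
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    rlang::warn("Constant vector: Spearman's rho is undefined.")
    return(tibble::tibble(rho = NA_real_, n = n, p = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  tibble::tibble(rho = rho, n = n, p = p)
}

#' Compare two correlations from independent samples by Fisher's Z
#'
#' Applies the Fisher z (atanh) transform to each correlation and forms
#' \deqn{Z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'   {\sqrt{1/(n_1-3) + 1/(n_2-3)}}}
#' which is approximately standard normal when the two samples are
#' independent. The primary p-value is one-sided, `pnorm(-|z|)`; the
#' two-sided value is also returned.
#'
#' @param r1,r2 Correlation coefficients, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes, each > 3.
#' @param labels Optional character pair naming the two correlations, echoed
#'   in the output.
#' @return A one-row tibble with `z`, `p_one_sided`, `p_two_sided`,
#'   `label1`, `label2`. Swapping the two correlations negates `z` exactly.
#' @examples
#' fisher_z_compare(0.234, 108, 0.463, 107) # z = -1.899, p = 0.029
#' @export
fisher_z_compare <- function(r1, n1, r2, n2, labels = c("r1", "r2")) {
  if (any(abs(c(r1, r2)) >= 1)) {
    rlang::abort("Correlations must be strictly inside (-1, 1) for the Fisher z transform.")
  }
  if (any(c(n1, n2) <= 3)) {
    rlang::abort("Fisher-Z comparison requires both sample sizes > 3.")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(
    z = z,
    p_one_sided = stats::pnorm(-abs(z)),
    p_two_sided = 2 * stats::pnorm(-abs(z)),
    label1 = labels[[1]],
    label2 = labels[[2]]
  )
}

#' Bland-Altman agreement analysis
#'
#' Computes per-subject differences `measured - estimated`, their mean
#' (mean bias), the sample standard deviation of the differences, and the
#' 95% limits of agreement `bias +/- 1.96 * SD`. The significance of the
#' bias is assessed with a one-sample t-test of the differences against
#' zero. Positive bias means the method under study underestimates the
#' measurement.
#'
#' @param measured,estimated Numeric vectors of equal length (>= 2 complete
#'   pairs), same units (mg/d in the sodium analyses).
#' @return An object of class `bland_altman`: a list with `mean_bias`,
#'   `sd_diff`, `loa_lower`, `loa_upper`, `bias_p`, `n` and a `data` tibble
#'   of `(mean, difference)` pairs for plotting. Supports [tidy()],
#'   [glance()], [ggplot2::autoplot()] and `print()`. When the differences
#'   are constant (e.g. perfect agreement) `bias_p` is `NA`.
#' @examples
#' ba <- bland_altman(c(100, 200, 300), c(110, 190, 310))
#' tidy(ba)
#' @export
bland_altman <- function(measured, estimated) {
  if (length(measured) != length(estimated)) {
    rlang::abort("`measured` and `estimated` must have the same length.")
  }
  ok <- stats::complete.cases(measured, estimated)
  measured <- measured[ok]
  estimated <- estimated[ok]
  n <- length(measured)
  if (n < 2) {
    rlang::abort("Need at least 2 complete pairs for a Bland-Altman analysis.")
  }
  d <- measured - estimated
  bias <- mean(d)
  s <- stats::sd(d)
  p <- if (s == 0) NA_real_ else stats::t.test(d)$p.value
  structure(
    list(
      mean_bias = bias,
      sd_diff = s,
      loa_lower = bias - 1.96 * s,
      loa_upper = bias + 1.96 * s,
      bias_p = p,
      n = n,
      data = tibble::tibble(
        mean = (measured + estimated) / 2,
        difference = d
      )
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, digits = 4, ...) {
  cat("Bland-Altman agreement (measured - estimated), n =", x$n, "\n")
  cat("  mean bias:", signif(x$mean_bias, digits),
      " (p =", format.pval(x$bias_p, digits = 3), ")\n")
  cat("  SD of differences:", signif(x$sd_diff, digits), "\n")
  cat("  95% limits of agreement: [", signif(x$loa_lower, digits), ",",
      signif(x$loa_upper, digits), "]\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    mean_bias = x$mean_bias,
    sd_diff = x$sd_diff,
    loa_lower = x$loa_lower,
    loa_upper = x$loa_upper,
    bias_p = x$bias_p,
    n = x$n
  )
}

#' @rdname bland_altman
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) tidy.bland_altman(x)

#' @rdname bland_altman
#' @param object A `bland_altman` object.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_bias, colour = "orange") +
    ggplot2::geom_hline(
      yintercept = c(object$loa_lower, object$loa_upper),
      colour = "steelblue", linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "Mean of measured and estimated (mg/d)",
      y = "Measured - estimated (mg/d)",
      title = sprintf(
        "Mean bias %.1f (%.1f to %.1f)",
        object$mean_bias, object$loa_lower, object$loa_upper
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' P30: percentage of estimates within +/-30% of the measurement
#'
#' The standard nephrology precision metric: the share of subjects whose
#' estimate falls within 30% of the measured value, boundary inclusive.
#'
#' @param measured Strictly positive numeric vector.
#' @param estimated Numeric vector of the same length.
#' @return Percentage in `[0, 100]`.
#' @examples
#' p30_precision(c(100, 100), c(129, 131)) # 50
#' @export
p30_precision <- function(measured, estimated) {
  if (length(measured) != length(estimated)) {
    rlang::abort("`measured` and `estimated` must have the same length.")
  }
  ok <- stats::complete.cases(measured, estimated)
  measured <- measured[ok]
  estimated <- estimated[ok]
  if (any(measured <= 0)) {
    rlang::abort("P30 requires strictly positive measured values.")
  }
  100 * mean(abs(estimated - measured) <= 0.30 * measured)
}

#' Threshold classification of estimated vs measured daily sodium
#'
#' Dichotomises measured and estimated daily sodium excretion at a
#' guideline threshold (strictly greater-than) and reports the confusion
#' counts and sensitivity, specificity, positive and negative predictive
#' values as percentages:
#' `sens = 100 tp/(tp+fn)`, `spec = 100 tn/(tn+fp)`, `ppv = 100 tp/(tp+fp)`,
#' `npv = 100 tn/(tn+fn)`. Metrics with a zero denominator are reported as
#' `NA` (undefined), never 0.
#'
#' @param measured_g_d,estimated_g_d Daily sodium excretion, g/d.
#' @param threshold Threshold in g/d (> 0); 2 and 4 g/d sodium correspond to
#'   about 5 and 10 g/d salt.
#' @return One-row tibble: `threshold`, `n`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`.
#' @examples
#' classification_metrics(c(3, 5, 1, 2.5, 4.5, 1.5),
#'                        c(4.2, 4.8, 2.5, 1.8, 5, 1.2), threshold = 2)
#' @export
classification_metrics <- function(measured_g_d, estimated_g_d, threshold) {
  if (threshold <= 0) rlang::abort("`threshold` must be positive.")
  if (length(measured_g_d) != length(estimated_g_d)) {
    rlang::abort("`measured_g_d` and `estimated_g_d` must have the same length.")
  }
  ok <- stats::complete.cases(measured_g_d, estimated_g_d)
  m <- measured_g_d[ok] > threshold
  e <- estimated_g_d[ok] > threshold
  tp <- sum(m & e)
  fp <- sum(!m & e)
  tn <- sum(!m & !e)
  fn <- sum(m & !e)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tibble::tibble(
    threshold = threshold,
    n = length(m),
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    ppv = pct(tp, tp + fp),
    npv = pct(tn, tn + fn)
  )
}
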