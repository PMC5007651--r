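#' Distributional diagnostics for reflected track angles
#'
#' Two-sample Kolmogorov-Smirnov comparisons, sample moment diagnostics
#' (skewness, excess kurtosis) and the component comparison that mirrors the
#' field analysis: negate the left-of-sun component, compare the two
#' component subsamples, and test each component mean against zero (the
#' direction of the sun).
#' @name diststats
NULL

#' Two-sample Kolmogorov-Smirnov test
#'
#' Classical two-sample KS statistic with the asymptotic p-value.
#'
#' @param a,b numeric samples, each n >= 2.
#' @return list with `D`, `p`, `n_a`, `n_b`.
#' @export
ks_2sample <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("both samples need at least 2 observations", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Sample skewness and excess kurtosis
#'
#' Moment (biased, method-of-moments) estimators: skewness m3/m2^(3/2) and
#' excess kurtosis m4/m2^2 - 3, both 0 for a normal distribution. Negative
#' excess kurtosis = platykurtic.
#'
#' @param x numeric sample, n >= 4.
#' @return list with `skewness` and `excess_kurtosis`.
#' @export
moments <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("degenerate sample: zero variance", call. = FALSE)
  list(skewness = mean((x - m)^3) / m2^1.5,
       excess_kurtosis = mean((x - m)^4) / m2^2 - 3)
}

#' Compare the two fitted mixture components
#'
#' Assigns each observation to a component by maximum responsibility,
#' negates the values of the left-of-sun component (the one with negative
#' mean) so both subsamples live on a common positive scale, then compares
#' the two subsamples with a KS test and a Welch t magnitude comparison,
#' and tests each component's mean against zero.
#'
#' @param fit a converged [em_fit()] result.
#' @param x the data the fit was computed on.
#' @return list with `ks` (the [ks_2sample()] result on the aligned
#'   subsamples), `magnitude` (Welch test: estimate = mean|left| -
#'   mean|right|, t, p), and `mean_vs_zero`, a data.frame with one row per
#'   component (mean, t, p).
#' @export
compare_components <- function(fit, x) {
  stopifnot(inherits(fit, "mixture_fit"))
  comp <- mixture_responsibilities(fit, x)$component
  x1 <- x[comp == 1L]  # component with the smaller mean (left of sun)
  x2 <- x[comp == 2L]
  if (length(x1) < 5L || length(x2) < 5L) {
    stop("a component has fewer than 5 assigned observations", call. = FALSE)
  }
  # negate whichever component sits left of the sun
  a1 <- if (fit$mu1 < 0) -x1 else x1
  a2 <- if (fit$mu2 < 0) -x2 else x2
  ks <- ks_2sample(a1, a2)
  tt <- stats::t.test(a1, a2)
  t1 <- stats::t.test(x1, mu = 0)
  t2 <- stats::t.test(x2, mu = 0)
  list(ks = ks,
       magnitude = list(estimate = mean(a1) - mean(a2),
                        t = unname(tt$statistic), p = tt$p.value),
       mean_vs_zero = data.frame(
         component = 1:2,
         mean = c(mean(x1), mean(x2)),
         t = c(unname(t1$statistic), unname(t2$statistic)),
         p = c(t1$p.value, t2$p.value)),
       n = c(length(x1), length(x2)))
}
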