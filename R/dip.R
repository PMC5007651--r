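#' Hartigan's dip statistic and Monte-Carlo dip test
#'
#' The dip is the smallest sup-norm distance between the empirical CDF and
#' the class of unimodal CDFs. It is computed exactly from the greatest
#' convex minorant / least concave majorant characterisation: for a candidate
#' mode placement, the part of the empirical CDF left of the mode must be
#' approximable by a convex function and the part to the right by a concave
#' one; a jump of the fitted CDF is allowed at the mode, which decouples the
#' two sides. The statistic is the minimum over mode placements of the larger
#' of the two one-sided hull deviations, halved (see `src/dip.cpp`).
#' @name dip
NULL

#' Dip statistic of a numeric sample
#'
#' @param x numeric sample (n >= 2, not all values equal; need not be
#'   sorted).
#' @return the dip statistic D. D always respects the lower bound 1/(2n);
#'   n = 2 and n = 3 samples attain it exactly.
#' @examples
#' dip_statistic(c(0, 1))  # 0.25, the two-point lower bound
#' @export
dip_statistic <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (x[1] == x[n]) stop("degenerate sample: zero range", call. = FALSE)
  if (anyNA(x)) stop("sample contains NA", call. = FALSE)
  .dip_stat_cpp(x)
}

#' Monte-Carlo dip test
#'
#' Tests unimodality of a sample by comparing its dip statistic with the
#' null distribution of the dip for samples of the same size drawn from a
#' uniform distribution (the customary reference null, under which the dip
#' is asymptotically largest among unimodal distributions).
#'
#' @param x numeric sample (n >= 4).
#' @param n_mc number of Monte-Carlo null replicates (default 10000).
#' @param seed optional integer seed for the null draws (restores the
#'   caller's random state on exit).
#' @return list with `D` (observed dip), `p` (Monte-Carlo p-value, the
#'   proportion of null dips >= D), `n` and `n_mc`.
#' @export
dip_test <- function(x, n_mc = 10000, seed = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations for the dip test", call. = FALSE)
  if (min(x) == max(x)) stop("degenerate sample: zero range", call. = FALSE)
  D <- dip_statistic(x)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  null_d <- vapply(seq_len(n_mc), function(i) dip_statistic(stats::runif(n)),
                   numeric(1))
  list(D = D, p = mean(null_d >= D), n = n, n_mc = n_mc)
}
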