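#' Two-component Gaussian mixture by EM, with bootstrap standard errors
#'
#' The distribution of reflected track angles is modelled as a two-component
#' univariate Gaussian mixture fitted by expectation-maximisation. Labels
#' are ordered so that `mu1 < mu2`; the mixing proportion `lambda` is the
#' weight of component 1. Standard errors come from a parametric bootstrap
#' (refit on samples simulated from the fitted mixture, SD of each parameter
#' across replicates after label alignment by mean ordering).
#' @name mixture
NULL

mix_loglik <- function(x, lambda, mu1, mu2, s1, s2) {
  sum(log(lambda * stats::dnorm(x, mu1, s1) +
            (1 - lambda) * stats::dnorm(x, mu2, s2)))
}

# One EM run from a given start; returns NULL on degeneracy.
em_run <- function(x, start, tol, max_iter) {
  n <- length(x)
  lambda <- start$lambda; mu1 <- start$mu1; mu2 <- start$mu2
  s1 <- start$sigma1; s2 <- start$sigma2
  sd_floor <- 1e-6 * stats::sd(x)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d1 <- lambda * stats::dnorm(x, mu1, s1)
    d2 <- (1 - lambda) * stats::dnorm(x, mu2, s2)
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
    r <- d1 / tot
    n1 <- sum(r)
    if (n1 < 1e-8 || n - n1 < 1e-8) return(NULL)
    lambda <- n1 / n
    mu1 <- sum(r * x) / n1
    mu2 <- sum((1 - r) * x) / (n - n1)
    s1 <- sqrt(sum(r * (x - mu1)^2) / n1)
    s2 <- sqrt(sum((1 - r) * (x - mu2)^2) / (n - n1))
    if (s1 < sd_floor || s2 < sd_floor) return(NULL)
    ll <- mix_loglik(x, lambda, mu1, mu2, s1, s2)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      return(list(lambda = lambda, mu1 = mu1, mu2 = mu2, sigma1 = s1,
                  sigma2 = s2, loglik = ll, n_iter = it, converged = TRUE,
                  ll_trace = ll_trace))
    }
    ll_old <- ll
  }
  list(lambda = lambda, mu1 = mu1, mu2 = mu2, sigma1 = s1, sigma2 = s2,
       loglik = ll_old, n_iter = max_iter, converged = FALSE,
       ll_trace = ll_trace)
}

order_fit <- function(f) {
  if (f$mu1 > f$mu2) {
    f[c("lambda", "mu1", "mu2", "sigma1", "sigma2")] <-
      list(1 - f$lambda, f$mu2, f$mu1, f$sigma2, f$sigma1)
  }
  f
}

#' Fit a two-component Gaussian mixture by EM
#'
#' Initialisation is a deterministic quantile split (observations below vs
#' above the median) followed by `n_starts - 1` randomly perturbed restarts;
#' the best converged log-likelihood wins. This gives a reproducible
#' baseline with stochastic escape from local optima.
#'
#' @param x numeric sample, n >= 10.
#' @param init optional list with `lambda`, `mu1`, `mu2`, `sigma1`,
#'   `sigma2` used as the first start instead of the quantile split.
#' @param tol EM stopping tolerance on the log-likelihood gain.
#' @param max_iter maximum EM iterations per start.
#' @param n_starts number of starts (1 deterministic + rest random).
#' @param seed optional seed for the random restarts.
#' @return an object of class `mixture_fit`: `lambda`, `mu1 < mu2`,
#'   `sigma1`, `sigma2`, `loglik`, `n_iter`, `converged`, `n`, plus the
#'   per-iteration `ll_trace` of the winning run.
#' @export
em_fit <- function(x, init = NULL, tol = 1e-8, max_iter = 2000,
                   n_starts = 20, seed = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L) stop("need at least 10 observations for a mixture fit", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate sample: zero variance", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  base <- list(lambda = 0.5, mu1 = mean(lo), mu2 = mean(hi),
               sigma1 = max(stats::sd(x) / 4, stats::sd(lo), na.rm = TRUE),
               sigma2 = max(stats::sd(x) / 4, stats::sd(hi), na.rm = TRUE))
  if (!is.null(init)) base <- init
  starts <- list(base)
  if (n_starts > 1) {
    rng <- diff(range(x))
    for (k in seq_len(n_starts - 1)) {
      starts[[k + 1]] <- list(
        lambda = stats::runif(1, 0.15, 0.85),
        mu1 = base$mu1 + stats::rnorm(1, 0, rng / 4),
        mu2 = base$mu2 + stats::rnorm(1, 0, rng / 4),
        sigma1 = base$sigma1 * exp(stats::rnorm(1, 0, 0.4)),
        sigma2 = base$sigma2 * exp(stats::rnorm(1, 0, 0.4)))
    }
  }
  best <- NULL
  for (s in starts) {
    f <- em_run(x, s, tol, max_iter)
    if (is.null(f)) next
    if (is.null(best) || f$loglik > best$loglik) best <- f
  }
  if (is.null(best)) stop("EM failed from every start", call. = FALSE)
  if (!best$converged) {
    warning("EM did not converge in ", max_iter,
            " iterations; returning best fit", call. = FALSE)
  }
  best <- order_fit(best)
  best$n <- n
  class(best) <- "mixture_fit"
  best
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("Two-component Gaussian mixture (n = %d)\n",
                     "  lambda = %.3f\n",
                     "  comp 1: mu = %+.4f, sigma = %.4f\n",
                     "  comp 2: mu = %+.4f, sigma = %.4f\n",
                     "  loglik = %.4f (%d EM iterations%s)\n"),
              x$n, x$lambda, x$mu1, x$sigma1, x$mu2, x$sigma2,
              x$loglik, x$n_iter,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Posterior responsibilities and hard component assignment
#'
#' @param fit a [em_fit()] result.
#' @param x the data the fit was computed on.
#' @return data.frame with `r1` (posterior probability of component 1) and
#'   `component` (1 or 2 by maximum responsibility).
#' @export
mixture_responsibilities <- function(fit, x) {
  d1 <- fit$lambda * stats::dnorm(x, fit$mu1, fit$sigma1)
  d2 <- (1 - fit$lambda) * stats::dnorm(x, fit$mu2, fit$sigma2)
  r1 <- d1 / (d1 + d2)
  data.frame(r1 = r1, component = ifelse(r1 >= 0.5, 1L, 2L))
}

#' Simulate from a fitted two-component mixture
#' @param n sample size.
#' @param fit a `mixture_fit` (or list with the five parameters).
#' @return numeric vector of draws.
#' @export
rmixture <- function(n, fit) {
  z <- stats::rbinom(n, 1, fit$lambda)
  ifelse(z == 1, stats::rnorm(n, fit$mu1, fit$sigma1),
         stats::rnorm(n, fit$mu2, fit$sigma2))
}

#' Parametric bootstrap standard errors for a mixture fit
#'
#' Simulates `B` samples of size `n` from the fitted mixture, refits each by
#' EM (few restarts, warm-started at the fitted parameters), aligns labels
#' by mean ordering and reports the SD of every parameter across converged
#' replicates.
#'
#' @param fit a converged [em_fit()] result.
#' @param B bootstrap replicates (the analysis default is 2000).
#' @param seed optional seed.
#' @param n_starts restarts per replicate (warm start usually suffices).
#' @return list of class `mixture_boot`: `B`, `se_lambda`, `se_mu1`,
#'   `se_mu2`, `se_sigma1`, `se_sigma2`, `n_failed`, `warning` (non-NULL
#'   when more than 10 percent of replicates failed to converge), and the
#'   replicate parameter matrix `reps`.
#' @export
bootstrap_se <- function(fit, B = 2000, seed = NULL, n_starts = 3) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!fit$converged) stop("bootstrap requires a converged fit", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  init <- fit[c("lambda", "mu1", "mu2", "sigma1", "sigma2")]
  reps <- matrix(NA_real_, B, 5,
                 dimnames = list(NULL, c("lambda", "mu1", "mu2", "sigma1", "sigma2")))
  failed <- 0L
  for (b in seq_len(B)) {
    xb <- rmixture(fit$n, fit)
    fb <- tryCatch(
      suppressWarnings(em_fit(xb, init = init, n_starts = n_starts)),
      error = function(e) NULL)
    if (is.null(fb) || !fb$converged) { failed <- failed + 1L; next }
    reps[b, ] <- c(fb$lambda, fb$mu1, fb$mu2, fb$sigma1, fb$sigma2)
  }
  ses <- apply(reps, 2, stats::sd, na.rm = TRUE)
  warn <- NULL
  if (failed > 0.1 * B) {
    warn <- sprintf("%d of %d bootstrap replicates failed to converge", failed, B)
    warning(warn, call. = FALSE)
  }
  structure(list(B = B, se_lambda = if (B > 1) ses[["lambda"]] else 0,
                 se_mu1 = if (B > 1) ses[["mu1"]] else 0,
                 se_mu2 = if (B > 1) ses[["mu2"]] else 0,
                 se_sigma1 = if (B > 1) ses[["sigma1"]] else 0,
                 se_sigma2 = if (B > 1) ses[["sigma2"]] else 0,
                 n_failed = failed, meaningless = B < 2, warning = warn,
                 reps = reps),
            class = "mixture_boot")
}

#' Asymptotic standard errors from the observed information
#'
#' Numerical Hessian of the mixture log-likelihood at the MLE, inverted to
#' give Wald standard errors. Much cheaper than the bootstrap; used for
#' confidence-interval coverage checks in simulations.
#'
#' @param fit a converged [em_fit()] result.
#' @param x the data the fit was computed on.
#' @return named numeric vector of standard errors for lambda, mu1, mu2,
#'   sigma1, sigma2 (NA where the information matrix is singular).
#' @export
mixture_se_hessian <- function(fit, x) {
  th0 <- c(fit$lambda, fit$mu1, fit$mu2, fit$sigma1, fit$sigma2)
  f <- function(th) mix_loglik(x, th[1], th[2], th[3], th[4], th[5])
  p <- length(th0)
  h <- pmax(1e-5, abs(th0) * 1e-4)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) for (j in i:p) {
    ei <- ej <- numeric(p); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- H[j, i] <- (f(th0 + ei + ej) - f(th0 + ei - ej) -
                             f(th0 - ei + ej) + f(th0 - ei - ej)) /
      (4 * h[i] * h[j])
  }
  V <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- c("lambda", "mu1", "mu2", "sigma1", "sigma2")
  se
}
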