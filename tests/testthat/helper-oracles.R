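# Independent oracles used across the suite (never the code paths they check).

# exact great-circle distance (haversine) for projection-error checks
haversine_m <- function(lat1, lon1, lat2, lon2, R = 6371008.8) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r
  dlon <- (lon2 - lon1) * r
  a <- sin(dlat / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# brute-force two-sample KS statistic: max ECDF difference over all jump points
ks_brute <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(fa - fb))
}

# direct maximisation of the two-component mixture log-likelihood (an EM-free
# reference): multi-start L-BFGS-B on (logit lambda, mu1, mu2, log s1, log s2)
mixture_loglik_direct <- function(x, n_starts = 12, seed = 1) {
  ll <- function(p) {
    lam <- stats::plogis(p[1])
    d <- lam * stats::dnorm(x, p[2], exp(p[4])) +
      (1 - lam) * stats::dnorm(x, p[3], exp(p[5]))
    if (any(d <= 0)) return(1e10)
    -sum(log(d))
  }
  rs <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
  set.seed(seed)
  best <- Inf
  s <- stats::sd(x)
  for (k in seq_len(n_starts)) {
    p0 <- c(stats::rnorm(1, 0, 1),
            mean(x) + stats::rnorm(2, 0, s),
            log(s * exp(stats::rnorm(2, 0, 0.5))))
    o <- tryCatch(stats::optim(p0, ll, method = "L-BFGS-B",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(o) && o$value < best) best <- o$value
  }
  -best
}

# small synthetic dataset shared by several tests
make_small_sim <- function(seed = 3, ...) {
  generate_synthetic(synth_config(seed = seed,
                                  obs_days_per_subject = 2L,
                                  ...))
}
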