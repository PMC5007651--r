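test_that("EM matches a direct likelihood-maximisation oracle", {
  set.seed(41)
  for (i in 1:8) {
    n <- sample(40:80, 1)
    x <- c(rnorm(n %/% 2, -1, 0.4), rnorm(n - n %/% 2, 0.8, 0.5))
    fit <- em_fit(x, seed = i)
    ll_ref <- mixture_loglik_direct(x, seed = i)
    # EM must reach (not beat by more than numerical slack) the best
    # directly-optimised likelihood
    expect_gt(fit$loglik, ll_ref - 1e-6)
  }
})

test_that("EM recovers known parameters and keeps labels ordered", {
  set.seed(42)
  truth <- list(lambda = 0.5, mu1 = -1.01, mu2 = 0.59,
                sigma1 = 0.35, sigma2 = 0.40)
  x <- rmixture(5000, truth)
  fit <- em_fit(x, seed = 1)
  expect_lt(abs(fit$mu1 - truth$mu1), 0.05)
  expect_lt(abs(fit$mu2 - truth$mu2), 0.05)
  expect_lt(fit$mu1, fit$mu2)
  expect_true(fit$converged)
  # log-likelihood trace is monotone non-decreasing (EM guarantee)
  expect_true(all(diff(fit$ll_trace) > -1e-8))
})

test_that("EM degrades gracefully on effectively single-component data", {
  set.seed(43)
  x <- rnorm(200, 2, 0.5)
  fit <- suppressWarnings(em_fit(x, seed = 2))
  # components nearly coincide; the overall mean is still right
  expect_lt(abs(fit$lambda * fit$mu1 + (1 - fit$lambda) * fit$mu2 - 2), 0.15)
  expect_error(em_fit(rep(1, 50)), "zero variance")
  expect_error(em_fit(rnorm(5)), "at least 10")
})

test_that("bootstrap SEs behave: degenerate B, label order, scaling, closed form", {
  set.seed(44)
  truth <- list(lambda = 0.5, mu1 = -2, mu2 = 2, sigma1 = 0.5, sigma2 = 0.5)
  x <- rmixture(400, truth)
  fit <- em_fit(x, seed = 3)
  b1 <- suppressWarnings(bootstrap_se(fit, B = 1, seed = 1))
  expect_true(b1$meaningless)
  b <- bootstrap_se(fit, B = 60, seed = 2)
  reps <- b$reps[stats::complete.cases(b$reps), , drop = FALSE]
  expect_true(all(reps[, "mu1"] < reps[, "mu2"]))  # label alignment
  # well-separated limit: se_mu ~= sigma / sqrt(n * weight) within x1.5
  pred <- truth$sigma1 / sqrt(400 * 0.5)
  expect_lt(b$se_mu1 / pred, 1.5)
  expect_gt(b$se_mu1 / pred, 1 / 1.5)
  # 1/sqrt(n) scaling across a 16x size ratio (expect ~4x, allow 2.2-7x)
  set.seed(45)
  f_small <- em_fit(rmixture(200, truth), seed = 4)
  f_big <- em_fit(rmixture(3200, truth), seed = 5)
  bs <- bootstrap_se(f_small, B = 40, seed = 6)
  bb <- bootstrap_se(f_big, B = 40, seed = 7)
  ratio <- bs$se_mu2 / bb$se_mu2
  expect_gt(ratio, 2.2)
  expect_lt(ratio, 7)
})

test_that("two-sample KS agrees with a brute-force oracle and edge cases", {
  a <- c(1, 2, 3, 4)
  expect_equal(ks_2sample(a, a)$D, 0)
  expect_equal(ks_2sample(a, a + 100)$D, 1)
  set.seed(46)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), 0.5)
    expect_equal(ks_2sample(x, y)$D, ks_brute(x, y), tolerance = 1e-12)
  }
  expect_error(ks_2sample(1, 1:5), "at least 2")
})

test_that("moment diagnostics match closed forms", {
  expect_equal(moments(c(-1, 1, -1, 1))$skewness, 0)
  set.seed(47)
  u <- runif(2e5)
  expect_lt(abs(moments(u)$excess_kurtosis - (-1.2)), 0.05)
  g <- rnorm(2e5)
  expect_lt(abs(moments(g)$skewness), 0.05)
  expect_lt(abs(moments(g)$excess_kurtosis), 0.1)
  expect_error(moments(rep(2, 10)), "zero variance")
})

test_that("component comparison detects asymmetry and tests means against zero", {
  set.seed(48)
  # perfectly mirror-symmetric components: no magnitude difference
  sym <- list(lambda = 0.5, mu1 = -1, mu2 = 1, sigma1 = 0.3, sigma2 = 0.3)
  xs <- rmixture(600, sym)
  fs <- em_fit(xs, seed = 6)
  cs <- compare_components(fs, xs)
  expect_gt(cs$ks$p, 0.05)
  expect_lt(abs(cs$magnitude$estimate), 0.1)
  # field-structure mixture: left-of-sun magnitudes exceed right-of-sun
  asym <- list(lambda = 0.45, mu1 = -1.01, mu2 = 0.59,
               sigma1 = 0.35, sigma2 = 0.40)
  xa <- rmixture(600, asym)
  fa <- em_fit(xa, seed = 7)
  ca <- compare_components(fa, xa)
  expect_gt(ca$magnitude$estimate, 0.2)
  expect_true(all(ca$mean_vs_zero$p < 0.01))
  # power for the smaller displaced component at the field sample size
  set.seed(49)
  rej <- mean(replicate(20, {
    x1 <- rnorm(265, 0.59, 0.40)
    stats::t.test(x1, mu = 0)$p.value < 0.05
  }))
  expect_equal(rej, 1)
})
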