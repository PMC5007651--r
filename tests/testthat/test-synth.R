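test_that("generation is deterministic under a fixed seed, down to the files", {
  a <- make_small_sim(seed = 5)
  b <- make_small_sim(seed = 5)
  expect_identical(a, b)
  d1 <- tempfile(); d2 <- tempfile()
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  write_synth(a, d1); write_synth(b, d2)
  for (f in c("fixes.csv", "events.csv", "burrows.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_false(identical(a$fixes, make_small_sim(seed = 6)$fixes))
})

test_that("all generated fix and event timestamps fall in daylight", {
  sim <- make_small_sim(seed = 13)
  site <- study_site()
  check_daylight <- function(tstr) {
    t <- as.POSIXct(tstr, tz = "UTC")
    for (d in unique(as.Date(t))) {
      ss <- sunrise_sunset(as.Date(d, origin = "1970-01-01"), site)
      idx <- as.Date(t) == d
      expect_true(all(t[idx] >= ss$sunrise - 60 & t[idx] <= ss$sunset + 60))
    }
  }
  check_daylight(sim$fixes$timestamp_utc)
  check_daylight(sim$events$event_time_utc[!is.na(sim$events$event_time_utc)])
})

test_that("latent draws respect bounds and the toward/away flag is coherent", {
  sim <- make_small_sim(seed = 14)
  tt <- sim$truth$tracks
  expect_true(all(abs(tt$theta) <= pi / 2))
  expect_true(all(abs(wrap_pi(tt$rel_angle)) <= pi + 1e-9))
  # reflect_half of the pre-reflection relative angle returns the latent draw
  r <- reflect_half(wrap_pi(tt$rel_angle))
  expect_equal(r$reflected_rad, tt$theta, tolerance = 1e-9)
  expect_equal(r$toward_sun, tt$toward)
})

test_that("theft times decrease with the number of individuals present", {
  sim <- generate_synthetic(synth_config(seed = 15, obs_days_per_subject = 4L))
  tc <- sim$truth$caches
  grp <- cut(tc$n_present, quantile(tc$n_present, c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE)
  med <- tapply(tc$theft_daylight_h, grp, median)
  expect_true(all(diff(med) < 0))
})

test_that("the noise-free world is exactly recoverable", {
  sim <- generate_synthetic(synth_config(
    seed = 16, obs_days_per_subject = 2L, gps_sd_m = 0,
    straightness_target = 1, recovery_jitter_min = 0))
  rep <- run_pipeline(sim$fixes, sim$events, sim$burrows, seed = 16,
                      B = 0, n_mc = 100)
  m <- merge(rep$tracks, sim$truth$tracks[, c("track_id", "theta")],
             by = "track_id")
  ok <- !is.na(m$reflected_rad)
  # only CSV coordinate digits separate estimate from truth
  expect_lt(max(abs(m$reflected_rad[ok] - m$theta[ok])), 1e-6)
  expect_equal(rep$tracks$straightness, rep(1, nrow(rep$tracks)),
               tolerance = 1e-9)
  tc <- truth_compare(sim$truth, recoveries = rep$recoveries)
  expect_equal(tc$classification$accuracy, 1)
})

test_that("default world has the intended angular and straightness structure", {
  sim <- generate_synthetic(synth_config(seed = 17))
  tt <- sim$truth$tracks
  expect_gt(nrow(tt), 150)
  by_comp <- tapply(tt$theta, tt$component, mean)
  expect_lt(abs(by_comp[["1"]] - (-1.01)), 0.12)  # small-sample run
  expect_lt(abs(by_comp[["2"]] - 0.59), 0.12)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write.csv(sim$fixes, f, row.names = FALSE)
  rep_tr <- track_metrics_table(read_fixes_csv(f), sim$burrows)
  expect_lt(abs(mean(rep_tr$straightness) - 0.89), 0.04)
  expect_lt(moments(rep_tr$straightness)$skewness, 0)  # left-skewed to 1
})

test_that("larger worlds concentrate component means at the configured truth", {
  sim <- generate_synthetic(synth_config(seed = 18, obs_days_per_subject = 12L,
                                         p_attend = 1))
  tt <- sim$truth$tracks
  expect_gte(nrow(tt), 2000)
  by_comp <- tapply(tt$theta, tt$component, mean)
  expect_lt(abs(by_comp[["1"]] - (-1.01)), 0.05)
  expect_lt(abs(by_comp[["2"]] - 0.59), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(straightness_target = 1.2), "straightness")
  expect_error(synth_config(mixture = list(lambda = 1.4, mu1 = 0, mu2 = 1,
                                           sigma1 = 1, sigma2 = 1)),
               "mixture")
  expect_error(synth_config(p_toward_sun = -0.1), "probabilities")
  expect_error(synth_config(gps_sd_m = -1), "negative")
})

test_that("truth_compare tabulates estimator-versus-truth errors", {
  sim <- make_small_sim(seed = 19)
  rep <- run_pipeline(sim$fixes, sim$events, sim$burrows, seed = 19,
                      B = 0, n_mc = 100)
  tc <- truth_compare(sim$truth, fit = rep$mixture,
                      recoveries = rep$recoveries, tracks = rep$tracks)
  expect_named(tc$mixture_errors,
               c("lambda", "mu1", "mu2", "sigma1", "sigma2"))
  expect_lt(max(abs(tc$mixture_errors[c("mu1", "mu2")])), 0.25)
  expect_gt(tc$classification$accuracy, 0.9)  # 30-min jitter default
  expect_lt(tc$angle_rmse, 0.3)
})
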