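site <- study_site()

test_that("recovery at exactly +24 h classifies as A24 with tiny error", {
  for (ct in c("2014-05-10 07:30:00", "2014-06-02 13:10:00")) {
    cache_t <- as.POSIXct(ct, tz = "UTC")
    r <- classify_recovery(cache_t, cache_t + 86400, site)
    expect_equal(r$category, "A24")
    expect_lt(r$dist_a_deg, 0.01)  # theta_a matches by construction
    expect_lt(r$az_error_deg, 1.5)  # azimuth drifts < ~1 degree per day
  }
})

test_that("recovery at the mirrored-azimuth instant classifies as PRE24", {
  cache_t <- as.POSIXct("2014-05-10 07:30:00", tz = "UTC")
  theta_a <- solar_position(cache_t + 86400, site)$azimuth_deg
  t_mirror <- time_at_azimuth("2014-05-10", mirrored_azimuth(theta_a), site)
  expect_gt(as.numeric(t_mirror) - as.numeric(cache_t), 0)
  r <- classify_recovery(cache_t, t_mirror, site)
  expect_equal(r$category, "PRE24")
  expect_lt(r$dist_b_deg, 0.05)
  expect_lt(r$az_error_deg, 1.5)
})

test_that("night recoveries are flagged unclassifiable", {
  cache_t <- as.POSIXct("2014-05-10 07:30:00", tz = "UTC")
  r <- classify_recovery(cache_t, cache_t + 15 * 3600, site)  # 22:30 UTC
  expect_true(r$unclassifiable)
  expect_true(is.na(r$category))
  expect_error(classify_recovery(cache_t, cache_t - 100, site), "after")
})

test_that("proportion test reproduces worked arithmetic and matches prop.test", {
  r <- proportion_test(12, 20, 0.5)
  expect_equal(r$chi2, 0.45, tolerance = 1e-12)
  expect_equal(r$p, 0.502, tolerance = 1e-3)
  # k = n p0 exactly: continuity correction clamps to zero
  expect_equal(proportion_test(10, 20, 0.5)$chi2, 0)
  # without continuity: (12 - 10)^2 / 5 = 0.8
  expect_equal(proportion_test(12, 20, 0.5, continuity = FALSE)$chi2, 0.8)
  set.seed(51)
  for (i in 1:10) {
    n <- sample(10:80, 1); k <- sample(0:n, 1)
    mine <- proportion_test(k, n, 0.5)
    ref <- suppressWarnings(stats::prop.test(k, n, p = 0.5))
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(proportion_test(25, 20), "k <= n")
})

test_that("theft summary reports the field proportions from raw counts", {
  t0 <- as.POSIXct("2014-05-10 08:00:00", tz = "UTC")
  ev <- data.frame(
    outcome = c(rep("stolen", 27), rep("recovered_by_cacher", 20)),
    cache_time_utc = format(t0, "%Y-%m-%d %H:%M:%S"),
    event_time_utc = format(t0 + 3600 * c(rep(12, 27), rep(c(10, 22), 10)),
                            "%Y-%m-%d %H:%M:%S"),
    stringsAsFactors = FALSE)
  s <- theft_summary(ev)
  expect_equal(s$n_monitored, 47)
  expect_equal(round(100 * s$prop_stolen, 1), 57.4)
  expect_equal(s$mean_recovery_h, 16)
  # all-intact edge case
  ev2 <- data.frame(outcome = rep("intact", 5),
                    cache_time_utc = format(t0), event_time_utc = NA)
  s2 <- theft_summary(ev2)
  expect_equal(s2$prop_stolen, 0)
  expect_true(is.na(s2$mean_recovery_h))
  expect_error(theft_summary(ev2[0, ]), "no cache fates")
})

test_that("median azimuthal error grows with recovery timing jitter", {
  meds <- vapply(c(2, 30, 120), function(jit) {
    sim <- generate_synthetic(synth_config(
      seed = 99, obs_days_per_subject = 2L, gps_sd_m = 0,
      recovery_jitter_min = jit, theft_base_hazard = 1e-4,
      hazard_per_individual = 1e-5))
    rc <- classify_recoveries(sim$events)
    stats::median(rc$az_error_deg, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})
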