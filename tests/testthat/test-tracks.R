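origin <- study_site()

test_that("local projection is exact at the origin and inverts cleanly", {
  expect_equal(unname(local_xy(origin, origin)), c(0, 0))
  # one arcsecond of latitude is R * pi/648000 metres north
  p <- geo_point(origin$lat_deg + 1 / 3600, origin$lon_deg)
  xy <- local_xy(p, origin)
  expect_equal(unname(xy[2]), 6371008.8 * pi / 648000, tolerance = 1e-9)
  expect_lt(abs(xy[1]), 1e-9)
  # round trip within 1 mm at 100 m range
  for (ang in seq(0, 330, by = 60)) {
    x <- 100 * sin(ang * pi / 180); y <- 100 * cos(ang * pi / 180)
    ll <- inv_local_xy(x, y, origin)
    back <- local_xy(geo_point(ll$lat_deg, ll$lon_deg), origin)
    expect_lt(sqrt((back[1] - x)^2 + (back[2] - y)^2), 1e-3)
  }
  expect_error(local_xy(geo_point(origin$lat_deg + 1, origin$lon_deg), origin),
               "5 km")
})

test_that("projection error versus the geodesic is below 1 cm within 200 m", {
  set.seed(11)
  for (i in 1:25) {
    x <- runif(1, -200, 200); y <- runif(1, -200, 200)
    ll <- inv_local_xy(x, y, origin)
    d_proj <- sqrt(x^2 + y^2)
    d_geo <- haversine_m(origin$lat_deg, origin$lon_deg, ll$lat_deg, ll$lon_deg)
    expect_lt(abs(d_proj - d_geo), 0.01)
  }
})

test_that("bearings follow compass conventions", {
  north <- geo_point(origin$lat_deg + 0.0005, origin$lon_deg)
  east <- inv_local_xy(50, 0, origin)
  east <- geo_point(east$lat_deg, east$lon_deg)
  expect_equal(bearing(origin, north), 0, tolerance = 1e-6)
  expect_equal(bearing(origin, east), 90, tolerance = 1e-6)
  expect_equal(wrap_deg(bearing(origin, east) - bearing(east, origin)), 180,
               tolerance = 1e-6)
  expect_error(bearing(origin, origin), "zero displacement")
})

make_track <- function(xy, t0 = "2014-05-10 08:00:00") {
  ll <- inv_local_xy(xy[, 1], xy[, 2], origin)
  cache_track("T1", "S1", "G1", ll$lat_deg, ll$lon_deg,
              as.POSIXct(t0, tz = "UTC") + seq_len(nrow(xy)) * 10)
}

test_that("straightness is 1 on collinear tracks and root-2/2 on a right dogleg", {
  straight <- make_track(cbind(c(0, 5, 12, 20), c(0, 5, 12, 20) * 0.5))
  expect_equal(straightness(straight)$straightness, 1, tolerance = 1e-12)
  dog <- make_track(cbind(c(0, 10, 10), c(0, 0, 10)))
  m <- straightness(dog)
  expect_equal(m$straightness, sqrt(2) / 2, tolerance = 1e-9)
  expect_equal(m$path_length_m, 20, tolerance = 1e-6)
  # triangle inequality: straightness <= 1 for arbitrary tracks
  set.seed(21)
  for (i in 1:20) {
    xy <- cbind(cumsum(rnorm(6, 2)), cumsum(rnorm(6, 1)))
    expect_lte(straightness(make_track(xy))$straightness, 1 + 1e-12)
  }
  same <- cbind(c(0, 0), c(0, 0))
  expect_error(straightness(make_track(same)), "coincident")
})

test_that("signed relative angle wraps to (-pi, pi] with right-positive sign", {
  expect_equal(signed_rel_angle(120, 120), 0)
  expect_equal(signed_rel_angle(210, 120), pi / 2)
  expect_equal(signed_rel_angle(120 - 135, 120), -3 * pi / 4)
  expect_equal(signed_rel_angle(300 + 181, 300), -pi + pi / 180,
               tolerance = 1e-9)
})

test_that("reflect_half folds away-from-sun angles while preserving sign", {
  r <- reflect_half(pi / 4)
  expect_equal(r$reflected_rad, pi / 4)
  expect_true(r$toward_sun)
  r <- reflect_half(3 * pi / 4)
  expect_equal(r$reflected_rad, pi / 4)
  expect_false(r$toward_sun)
  expect_equal(reflect_half(-3 * pi / 4)$reflected_rad, -pi / 4)
  # property: composition maps any pair into [-pi/2, pi/2]; magnitudes are
  # invariant to reversing the bearing (toward/away pooling)
  set.seed(31)
  b <- runif(300, 0, 360); az <- runif(300, 0, 360)
  r1 <- reflect_half(signed_rel_angle(b, az))
  r2 <- reflect_half(signed_rel_angle(wrap_deg(b + 180), az))
  expect_true(all(abs(r1$reflected_rad) <= pi / 2 + 1e-12))
  expect_equal(abs(r1$reflected_rad), abs(r2$reflected_rad), tolerance = 1e-9)
  expect_equal(r1$toward_sun, !r2$toward_sun)
})

test_that("caching boundary uses the farthest cache as radius", {
  caches <- inv_local_xy(c(0, 12, -9), c(5, 0, 0), origin)
  cb <- caching_boundary(origin, caches)
  expect_equal(cb$radius_m, 12, tolerance = 1e-6)
  bp <- cb$boundary_point(0)
  expect_equal(bearing(origin, bp), 0, tolerance = 1e-4)
  for (az in c(0, 77, 190, 301)) {
    d <- local_xy(cb$boundary_point(az), origin)
    expect_equal(sqrt(sum(d^2)), 12, tolerance = 1e-6)
  }
  expect_error(caching_boundary(origin, data.frame()), "at least one")
})

test_that("fixes CSV reader validates schema and rebuilds tracks", {
  sim <- make_small_sim(seed = 12)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write.csv(sim$fixes, f, row.names = FALSE)
  tracks <- read_fixes_csv(f)
  expect_equal(length(tracks), length(unique(sim$fixes$track_id)))
  expect_s3_class(tracks[[1]], "cache_track")
  # missing column
  bad <- sim$fixes[, -3]
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_fixes_csv(f), "missing column")
  # malformed row gets a row-numbered diagnostic
  bad2 <- sim$fixes
  bad2$fix_role[7] <- "wandering"
  write.csv(bad2, f, row.names = FALSE)
  expect_error(read_fixes_csv(f), "row")
})

test_that("degenerate short tracks are excluded from angle analysis only", {
  xy <- cbind(c(0, 0.5, 1), c(0, 0.2, 0.5))  # ~1 m displacement
  tr <- make_track(xy)
  row <- track_angles(tr, origin)
  expect_true(row$degenerate)
  expect_true(is.na(row$reflected_rad))
  expect_false(is.na(row$straightness))
})

test_that("GPX reader rebuilds tracks equivalent to the CSV path", {
  sim <- make_small_sim(seed = 27)
  ids <- unique(sim$fixes$track_id)[1:3]
  gpx_trk <- vapply(ids, function(id) {
    d <- sim$fixes[sim$fixes$track_id == id, ]
    pts <- paste(sprintf(
      '      <trkpt lat="%.9f" lon="%.9f"><time>%sZ</time></trkpt>',
      d$lat, d$lon, sub(" ", "T", d$timestamp_utc)), collapse = "\n")
    sprintf("  <trk>\n    <name>%s</name>\n    <desc>%s/%s</desc>\n    <trkseg>\n%s\n    </trkseg>\n  </trk>",
            id, d$subject_id[1], d$group_id[1], pts)
  }, character(1))
  gpx <- paste0('<?xml version="1.0"?>\n',
                '<gpx version="1.1" xmlns="http://www.topografix.com/GPX/1/1">\n',
                paste(gpx_trk, collapse = "\n"), "\n</gpx>\n")
  f <- tempfile(fileext = ".gpx")
  on.exit(unlink(f))
  writeLines(gpx, f)
  tracks <- read_fixes_gpx(f)
  expect_length(tracks, 3)
  m_gpx <- track_metrics_table(tracks, sim$burrows)
  csvf <- tempfile(fileext = ".csv")
  write.csv(sim$fixes[sim$fixes$track_id %in% ids, ], csvf, row.names = FALSE)
  m_csv <- track_metrics_table(read_fixes_csv(csvf), sim$burrows)
  unlink(csvf)
  # the GPX fixture carries 9-decimal coordinates (~0.1 mm), which moves
  # bearings on 15 m tracks by up to ~1e-3 degrees
  expect_equal(m_gpx$bearing_deg, m_csv$bearing_deg, tolerance = 1e-4)
  expect_equal(m_gpx$straightness, m_csv$straightness, tolerance = 1e-5)
  expect_error(read_fixes_gpx(tempfile()), ".")
})
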