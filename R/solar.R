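#' Low-precision solar ephemeris
#'
#' Position of the sun (azimuth/elevation), sunrise and sunset, the daily
#' observation-period schedule used for field sessions, and the solar-arc
#' mirror operation. The position algorithm is the NOAA/Meeus low-precision
#' formulation (geometric mean longitude and anomaly, equation of centre,
#' apparent longitude with nutation term, equation of time, hour angle),
#' accurate to roughly 0.01-0.1 degrees over 1950-2050 -- far below the
#' angular error contributed by +/-1.5 m GPS accuracy at track scale.
#'
#' Azimuth is measured in degrees clockwise from TRUE north, wrapped to
#' [0, 360); elevation is degrees above the geometric horizon with no
#' refraction correction (refraction enters only through the fixed -0.833
#' degree sunrise/sunset horizon).
#' @name solar
NULL

julian_day <- function(t) as.numeric(as_utc(t)) / 86400 + 2440587.5

# Core NOAA solar geometry for a vector of instants. Returns declination
# (deg), equation of time (minutes).
noaa_sun_geometry <- function(t) {
  jd <- julian_day(t)
  T <- (jd - 2451545) / 36525
  L0 <- (280.46646 + T * (36000.76983 + T * 0.0003032)) %% 360
  M <- 357.52911 + T * (35999.05029 - 0.0001537 * T)
  e <- 0.016708634 - T * (0.000042037 + 0.0000001267 * T)
  Mr <- deg2rad(M)
  C <- sin(Mr) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
    sin(2 * Mr) * (0.019993 - 0.000101 * T) +
    sin(3 * Mr) * 0.000289
  true_long <- L0 + C
  omega <- deg2rad(125.04 - 1934.136 * T)
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega)
  mean_obliq <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 - T * 0.001813))) / 60) / 60
  obliq <- mean_obliq + 0.00256 * cos(omega)
  obliq_r <- deg2rad(obliq)
  decl <- asin(sin(obliq_r) * sin(deg2rad(app_long)))
  y <- tan(obliq_r / 2)^2
  L0r <- deg2rad(L0)
  eq_time <- 4 * rad2deg(
    y * sin(2 * L0r) - 2 * e * sin(Mr) + 4 * e * y * sin(Mr) * cos(2 * L0r) -
      0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * Mr)
  )
  list(decl_rad = decl, eq_time_min = eq_time)
}

check_ephemeris_window <- function(t) {
  jd <- julian_day(t)
  # 1950-01-01 .. 2051-01-01 in Julian days
  if (any(jd < 2433282.5 | jd > 2470172.5)) {
    stop("timestamp outside the 1950-2050 validity window of the ephemeris",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Solar position (azimuth and elevation)
#'
#' @param t instant(s), anything coercible to POSIXct UTC; must lie within
#'   1950--2050, the validity window of the low-precision algorithm.
#' @param loc a [geo_point()]; defaults to the Kalahari [study_site()].
#' @return a data.frame with one row per instant: `time_utc`, `azimuth_deg`
#'   (clockwise from true north, in [0, 360)) and `elevation_deg`.
#' @examples
#' solar_position(as.POSIXct("2014-06-21 10:00:00", tz = "UTC"))
#' @export
solar_position <- function(t, loc = study_site()) {
  if (!inherits(loc, "geo_point")) stop("loc must be a geo_point", call. = FALSE)
  t <- as_utc(t)
  check_ephemeris_window(t)
  geom <- noaa_sun_geometry(t)
  lat <- deg2rad(loc$lat_deg)
  # true solar time in minutes of day
  mins_utc <- (as.numeric(t) %% 86400) / 60
  tst <- (mins_utc + geom$eq_time_min + 4 * loc$lon_deg) %% 1440
  ha <- deg2rad(tst / 4 - 180)
  decl <- geom$decl_rad
  cos_zen <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  zen <- acos(cos_zen)
  elev <- 90 - rad2deg(zen)
  # azimuth via the zenith triangle; guard the degenerate zenith/nadir case
  sin_zen <- sin(zen)
  az_cos <- ifelse(sin_zen < 1e-9, 1,
                   pmin(1, pmax(-1, (sin(lat) * cos_zen - sin(decl)) / (cos(lat) * sin_zen))))
  az0 <- rad2deg(acos(az_cos))
  az <- ifelse(ha > 0, wrap_deg(az0 + 180), wrap_deg(540 - az0))
  data.frame(time_utc = t, azimuth_deg = az, elevation_deg = elev)
}

#' Sunrise and sunset instants
#'
#' Times at which the solar elevation crosses the standard -0.833 degree
#' horizon (solar radius plus mean refraction). Computed from the NOAA
#' closed-form hour angle and then refined by bisection on the elevation so
#' the returned instants match [solar_position()] to well under 0.2 degrees.
#'
#' @param date a `Date` (or string coercible to one), interpreted as the UTC
#'   calendar date.
#' @param loc a [geo_point()].
#' @return list with POSIXct elements `sunrise` and `sunset` (UTC).
#' @export
sunrise_sunset <- function(date, loc = study_site()) {
  if (!inherits(loc, "geo_point")) stop("loc must be a geo_point", call. = FALSE)
  date <- as.Date(date)
  key <- sprintf("%s|%.6f|%.6f", format(date), loc$lat_deg, loc$lon_deg)
  hit <- .sun_cache[[key]]
  if (!is.null(hit)) return(hit)
  noon_guess <- as_utc(paste(format(date), "12:00:00"))
  check_ephemeris_window(noon_guess)
  geom <- noaa_sun_geometry(noon_guess)
  # solar noon in minutes UTC, then closed-form half-day hour angle
  solar_noon_min <- 720 - 4 * loc$lon_deg - geom$eq_time_min
  lat <- deg2rad(loc$lat_deg)
  decl <- geom$decl_rad
  cos_ha <- (cos(deg2rad(90.833)) - sin(lat) * sin(decl)) / (cos(lat) * cos(decl))
  if (!is.finite(cos_ha) || abs(cos_ha) >= 1) {
    stop("no sunrise/sunset event: polar day or polar night at this ",
         "latitude/date", call. = FALSE)
  }
  ha_min <- 4 * rad2deg(acos(cos_ha))
  day0 <- as.numeric(noon_guess) - 12 * 3600
  refine <- function(t_guess, rising) {
    # bracket the -0.833 crossing and bisect on elevation
    f <- function(t) {
      solar_position(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
                     loc)$elevation_deg + 0.833
    }
    lo <- t_guess - 900
    hi <- t_guess + 900
    flo <- f(lo); fhi <- f(hi)
    if (sign(flo) == sign(fhi)) return(t_guess)  # guess already adequate
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if ((fm > 0) == (fhi > 0)) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
    }
    (lo + hi) / 2
  }
  sr <- refine(day0 + 60 * (solar_noon_min - ha_min), rising = TRUE)
  ss <- refine(day0 + 60 * (solar_noon_min + ha_min), rising = FALSE)
  out <- list(sunrise = as.POSIXct(sr, origin = "1970-01-01", tz = "UTC"),
              sunset = as.POSIXct(ss, origin = "1970-01-01", tz = "UTC"))
  .sun_cache[[key]] <- out
  out
}

# memoisation cache for sunrise_sunset (pure function of date/location)
.sun_cache <- new.env(parent = emptyenv())

#' Daily observation-period schedule
#'
#' Field sessions ran at four times per day obtained by dividing the interval
#' from sunrise to sunset into five equal parts; the four interior division
#' points are the session start times (the animals are below ground around
#' sunrise and sunset themselves).
#'
#' @inheritParams sunrise_sunset
#' @return list with `sunrise`, `sunset` (POSIXct UTC) and `period_starts`,
#'   a POSIXct vector of the 4 session start instants.
#' @export
observation_periods <- function(date, loc = study_site()) {
  ss <- sunrise_sunset(date, loc)
  step <- (as.numeric(ss$sunset) - as.numeric(ss$sunrise)) / 5
  starts <- as.POSIXct(as.numeric(ss$sunrise) + (1:4) * step,
                       origin = "1970-01-01", tz = "UTC")
  list(sunrise = ss$sunrise, sunset = ss$sunset, period_starts = starts)
}

#' Mirror an azimuth across the North-South plane
#'
#' The sun's daily arc is symmetric about the local meridian: for any
#' position of the sun there is an earlier/later instant at which the sun
#' sits at the same elevation but at the azimuth reflected across the
#' North-South axis. This reflection is `az -> (360 - az) mod 360`.
#'
#' @param az azimuth(s) in degrees; wrapped to [0, 360) first.
#' @return mirrored azimuth(s) in [0, 360).
#' @examples
#' mirrored_azimuth(90)   # east -> west
#' @export
mirrored_azimuth <- function(az) {
  stopifnot(is.numeric(az))
  wrap_deg(360 - wrap_deg(az))
}

#' Find the daylight instant at which the sun reaches a target azimuth
#'
#' Searches the daylight window of `date` for the instant when the solar
#' azimuth equals `target_az_deg`, by bisection on the signed circular
#' difference. Used to place solar-arc-symmetric recovery events.
#'
#' @param date UTC calendar date to search.
#' @param target_az_deg target azimuth in degrees.
#' @param loc a [geo_point()].
#' @param tol_sec bisection tolerance in seconds.
#' @return POSIXct UTC instant, or NA if the azimuth is not attained during
#'   daylight on that date.
#' @export
time_at_azimuth <- function(date, target_az_deg, loc = study_site(),
                            tol_sec = 1) {
  ss <- sunrise_sunset(date, loc)
  t0 <- as.numeric(ss$sunrise)
  t1 <- as.numeric(ss$sunset)
  # signed difference azimuth(t) - target on (-180, 180]
  f <- function(t) {
    az <- solar_position(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
                         loc)$azimuth_deg
    d <- (az - target_az_deg) %% 360
    ifelse(d > 180, d - 360, d)
  }
  # azimuth is monotone (clockwise in the south, anticlockwise pieces near the
  # poles are out of scope); scan a coarse grid for a sign-change bracket
  grid <- seq(t0, t1, length.out = 97)
  fg <- f(grid)
  hit <- which(abs(fg) < 1e-9)
  if (length(hit)) {
    return(as.POSIXct(grid[hit[1]], origin = "1970-01-01", tz = "UTC"))
  }
  br <- which(fg[-1] * fg[-length(fg)] < 0 &
                abs(fg[-1] - fg[-length(fg)]) < 180)
  if (!length(br)) return(as.POSIXct(NA))
  lo <- grid[br[1]]; hi <- grid[br[1] + 1]
  flo <- f(lo)
  while (hi - lo > tol_sec) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  as.POSIXct((lo + hi) / 2, origin = "1970-01-01", tz = "UTC")
}
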