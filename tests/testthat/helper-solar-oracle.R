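# Independent solar-position oracle: the PSA algorithm (Blanco-Muriel et al.
# 2001, Solar Energy 70:431-441), a published formulation entirely different
# from the NOAA/Meeus equations used by the package (ecliptic coordinates ->
# right ascension/declination -> local hour angle via sidereal time, with a
# parallax correction). Stated accuracy ~0.01 deg over 1999-2015, ample for
# the 0.5 deg acceptance tolerance.
psa_solar_position <- function(t, lat_deg, lon_deg) {
  t <- as.POSIXct(t, tz = "UTC")
  jd <- as.numeric(t) / 86400 + 2440587.5
  ed <- jd - 2451545
  hours <- (as.numeric(t) %% 86400) / 3600
  omega <- 2.1429 - 0.0010394594 * ed
  mean_long <- 4.8950630 + 0.017202791698 * ed
  mean_anom <- 6.2400600 + 0.0172019699 * ed
  ecl_long <- mean_long + 0.03341607 * sin(mean_anom) +
    0.00034894 * sin(2 * mean_anom) - 0.0001134 - 0.0000203 * sin(omega)
  obliq <- 0.4090928 - 6.2140e-9 * ed + 0.0000396 * cos(omega)
  ra <- atan2(cos(obliq) * sin(ecl_long), cos(ecl_long)) %% (2 * pi)
  dec <- asin(sin(obliq) * sin(ecl_long))
  gmst <- 6.6974243242 + 0.0657098283 * ed + hours
  lmst <- (gmst * 15 + lon_deg) * pi / 180
  ha <- lmst - ra
  lat <- lat_deg * pi / 180
  zen <- acos(cos(lat) * cos(ha) * cos(dec) + sin(dec) * sin(lat))
  az <- atan2(-sin(ha), tan(dec) * cos(lat) - sin(lat) * cos(ha))
  az <- (az %% (2 * pi)) * 180 / pi
  zen <- zen + (6371.01 / 149597890) * sin(zen)  # parallax
  data.frame(azimuth_deg = az, elevation_deg = 90 - zen * 180 / pi)
}
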