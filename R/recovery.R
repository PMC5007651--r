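#' Solar-arc symmetric classification of cache recoveries
#'
#' The sun's daily arc is symmetric about the local meridian, so the solar
#' azimuth 24 h after a cache (theta_a) has a same-elevation mirror image
#' (theta_b) on the opposite side of the North-South plane. A recovery is
#' classified A24 if the solar azimuth at the recovery instant is closer
#' (circularly) to theta_a than to theta_b, otherwise PRE24. Exact ties go
#' to A24 (deterministic, and measure-zero under continuous time).
#' @name recovery
NULL

#' Classify one cache recovery by solar-arc symmetry
#'
#' All azimuths are evaluated at the burrow centre, matching how the field
#' azimuths were extracted. The accuracy measure `az_error_deg` is the
#' smaller circular distance between the recovery azimuth and either the
#' cache-time azimuth or its North-South mirror (the mirror handling for
#' PRE24 recoveries); both raw distances are retained.
#'
#' @param cache_time,event_time UTC instants of caching and recovery.
#' @param burrow a [geo_point()]: the burrow centre.
#' @return one-row data.frame: `theta_a_deg` (azimuth 24 h post-cache),
#'   `theta_b_deg` (its mirror), `az_recovery_deg`, `category` ("A24" or
#'   "PRE24"), `dist_a_deg`, `dist_b_deg`, `az_cache_deg`,
#'   `elevation_at_cache_deg`, `az_error_deg`, `unclassifiable` (TRUE when
#'   the sun is below the horizon at recovery).
#' @export
classify_recovery <- function(cache_time, event_time, burrow = study_site()) {
  cache_time <- as_utc(cache_time); event_time <- as_utc(event_time)
  if (event_time <= cache_time) {
    stop("event_time must be after cache_time", call. = FALSE)
  }
  sun_cache <- solar_position(cache_time, burrow)
  sun_24 <- solar_position(cache_time + 24 * 3600, burrow)
  sun_rec <- solar_position(event_time, burrow)
  theta_a <- sun_24$azimuth_deg
  theta_b <- mirrored_azimuth(theta_a)
  da <- circular_dist_deg(sun_rec$azimuth_deg, theta_a)
  db <- circular_dist_deg(sun_rec$azimuth_deg, theta_b)
  unclassifiable <- sun_rec$elevation_deg < 0
  category <- if (da <= db) "A24" else "PRE24"
  err <- min(circular_dist_deg(sun_rec$azimuth_deg, sun_cache$azimuth_deg),
             circular_dist_deg(sun_rec$azimuth_deg,
                               mirrored_azimuth(sun_cache$azimuth_deg)))
  data.frame(theta_a_deg = theta_a, theta_b_deg = theta_b,
             az_recovery_deg = sun_rec$azimuth_deg,
             category = if (unclassifiable) NA_character_ else category,
             dist_a_deg = da, dist_b_deg = db,
             az_cache_deg = sun_cache$azimuth_deg,
             elevation_at_cache_deg = sun_cache$elevation_deg,
             az_error_deg = err, unclassifiable = unclassifiable,
             stringsAsFactors = FALSE)
}

#' Classify all recovered caches in an events table
#'
#' @param events data.frame with at least `cache_id`, `cache_time_utc`,
#'   `event_time_utc`, `outcome`, `burrow_lat`, `burrow_lon` (the schema
#'   written by the synthetic generator / events reader).
#' @return data.frame with one row per recovered cache: the event columns
#'   joined with the [classify_recovery()] output.
#' @export
classify_recoveries <- function(events) {
  rec <- events[events$outcome == "recovered_by_cacher" &
                  !is.na(events$event_time_utc), , drop = FALSE]
  if (nrow(rec) == 0L) return(NULL)
  out <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
    classify_recovery(rec$cache_time_utc[i], rec$event_time_utc[i],
                      geo_point(rec$burrow_lat[i], rec$burrow_lon[i]))
  }))
  cbind(rec[, intersect(c("cache_id", "group_id", "subject_id", "group_size"),
                        names(rec)), drop = FALSE],
        out, row.names = NULL)
}

#' One-sample equality-of-proportions test (Yates-corrected chi-squared)
#'
#' chi^2 = (|k - n p0| - 1/2)^2 / (n p0 (1 - p0)) referred to chi^2(1); the
#' continuity correction is clamped so overshooting |k - n p0| < 1/2 gives
#' chi^2 = 0 rather than a negative-squared artefact.
#'
#' @param k successes; @param n trials; @param p0 null proportion.
#' @param continuity apply the Yates correction (default TRUE).
#' @return list with `k`, `n`, `p0`, `chi2`, `p`.
#' @export
proportion_test <- function(k, n, p0 = 0.5, continuity = TRUE) {
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1", call. = FALSE)
  dev <- abs(k - n * p0)
  if (continuity) dev <- max(0, dev - 0.5)
  chi2 <- dev^2 / (n * p0 * (1 - p0))
  list(k = k, n = n, p0 = p0, chi2 = chi2,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Theft and recovery summary for a set of monitored caches
#'
#' @param events data.frame with columns `outcome` (one of
#'   `recovered_by_cacher`, `stolen`, `intact`), `cache_time_utc`,
#'   `event_time_utc` (NA when intact or unknown).
#' @return list with counts (`n_monitored`, `n_stolen`, `n_recovered`),
#'   `prop_stolen`, `prop_stolen_within_24h` (over stolen caches with known
#'   theft time), `prop_recovered_within_24h`, and `mean_recovery_h` /
#'   `sd_recovery_h` over recovered caches (NA when none).
#' @export
theft_summary <- function(events) {
  if (is.null(events) || nrow(events) == 0L) {
    stop("no cache fates supplied", call. = FALSE)
  }
  lag_h <- (as.numeric(as_utc(events$event_time_utc)) -
              as.numeric(as_utc(events$cache_time_utc))) / 3600
  stolen <- events$outcome == "stolen"
  recov <- events$outcome == "recovered_by_cacher"
  stolen_lag <- lag_h[stolen & !is.na(lag_h)]
  rec_lag <- lag_h[recov & !is.na(lag_h)]
  list(n_monitored = nrow(events),
       n_stolen = sum(stolen),
       n_recovered = sum(recov),
       prop_stolen = mean(stolen),
       prop_stolen_within_24h = if (length(stolen_lag)) mean(stolen_lag <= 24) else NA_real_,
       prop_recovered_within_24h = if (length(rec_lag)) mean(rec_lag <= 24) else NA_real_,
       mean_recovery_h = if (length(rec_lag)) mean(rec_lag) else NA_real_,
       sd_recovery_h = if (length(rec_lag) > 1) stats::sd(rec_lag) else NA_real_)
}
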