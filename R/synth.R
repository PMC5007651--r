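#' Seeded synthetic-data generator
#'
#' Generates GPS-fix and cache-event tables with the statistical structure
#' the analysis pipeline assumes, so that every stage can be exercised and
#' calibrated without field data. The generator emulates the field design:
#' a handful of social groups along a dry riverbed, subjects observed at 4
#' observation periods per day (the interior points of a 5-way split of the
#' sunrise-sunset interval), 5 provisioning trials per session, near-straight
#' cache tracks whose bearings sit at a two-component mixture of angular
#' offsets from the solar azimuth, theft hazard increasing with group size,
#' and recoveries timed near either the +24 h solar position (A24) or its
#' North-South mirror (PRE24).
#' @name synth
NULL

#' Synthetic-data configuration
#'
#' Defaults encode the study design and its reported quantities: 9 subjects
#' across 5 groups, Apr-Jul observation window, mixture component means
#' -1.01 and 0.59 rad, straightness 0.89, GPS radial accuracy 1.5 m, group
#' sizes up to 36. Component SDs (0.35, 0.40), the mixing weight 0.45, the
#' theft hazard scale and the session-attendance probability are calibration
#' choices of the generator (the field study does not print them) and are
#' recorded in the truth output.
#'
#' @param seed integer RNG seed.
#' @param site a [geo_point()].
#' @param date_start,date_end observation window (Dates).
#' @param n_groups,subjects_per_group group structure; `subjects_total`
#'   trims the ragged allocation (9 subjects from 5 x 2).
#' @param group_size_range inclusive range of resident group sizes.
#' @param obs_days_per_subject observation days sampled per subject.
#' @param sessions_per_day observation periods used per day (max 4).
#' @param tracks_per_session provisioning trials per session.
#' @param p_attend probability a scheduled session is observed.
#' @param mixture list: lambda, mu1, mu2, sigma1, sigma2 of the reflected
#'   track-angle mixture (radians).
#' @param p_toward_sun probability a track is made towards (rather than
#'   away from) the sun.
#' @param straightness_target expected straightness index; 1 means
#'   perfectly straight tracks (no lateral jitter).
#' @param gps_sd_m radial GPS accuracy (m); 0 disables GPS noise.
#' @param track_length_meanlog,track_length_sdlog lognormal cache-track
#'   length (m).
#' @param start_dist_meanlog,start_dist_sdlog lognormal distance of
#'   provisioning start points from the burrow (m).
#' @param theft_base_hazard,hazard_per_individual theft hazard per daylight
#'   hour: base + per_individual * group_size.
#' @param p_pre24_slope log-odds increase of PRE24 recovery per resident
#'   individual above the mid-range group size.
#' @param recovery_jitter_min SD (minutes) of recovery timing jitter around
#'   the targeted solar instant; 0 disables jitter.
#' @param monitor_days camera-monitoring window after caching (days).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         site = study_site(),
                         date_start = as.Date("2014-04-01"),
                         date_end = as.Date("2014-07-31"),
                         n_groups = 5L,
                         subjects_per_group = 2L,
                         subjects_total = 9L,
                         group_size_range = c(3L, 36L),
                         obs_days_per_subject = 3L,
                         sessions_per_day = 4L,
                         tracks_per_session = 5L,
                         p_attend = 0.5,
                         mixture = list(lambda = 0.45, mu1 = -1.01,
                                        mu2 = 0.59, sigma1 = 0.35,
                                        sigma2 = 0.40),
                         p_toward_sun = 0.5,
                         straightness_target = 0.89,
                         gps_sd_m = 1.5,
                         track_length_meanlog = log(15), track_length_sdlog = 0.5,
                         start_dist_meanlog = log(12), start_dist_sdlog = 0.6,
                         theft_base_hazard = 0.015,
                         hazard_per_individual = 0.005,
                         p_pre24_slope = 0.15,
                         recovery_jitter_min = 30,
                         monitor_days = 5L) {
  cfg <- as.list(environment())
  if (cfg$straightness_target > 1 || cfg$straightness_target <= 0) {
    stop("straightness_target must be in (0, 1]", call. = FALSE)
  }
  if (cfg$mixture$sigma1 <= 0 || cfg$mixture$sigma2 <= 0 ||
      cfg$mixture$lambda <= 0 || cfg$mixture$lambda >= 1) {
    stop("invalid mixture configuration", call. = FALSE)
  }
  if (cfg$p_toward_sun < 0 || cfg$p_toward_sun > 1 || cfg$p_attend < 0 ||
      cfg$p_attend > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$gps_sd_m < 0 || cfg$theft_base_hazard < 0 ||
      cfg$hazard_per_individual < 0) {
    stop("negative rate or noise parameter", call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

# Advance a daylight instant by `hours` counting daylight time only
# (nights are skipped: the animals are below ground).
advance_daylight <- function(t, hours, loc) {
  t <- as_utc(t)
  remaining <- hours * 3600
  for (i in 1:400) {
    ss <- sunrise_sunset(as.Date(t), loc)
    if (t < ss$sunrise) t <- ss$sunrise
    today <- as.numeric(ss$sunset) - as.numeric(t)
    if (remaining <= today) return(t + remaining)
    remaining <- remaining - today
    nxt <- sunrise_sunset(as.Date(t) + 1, loc)
    t <- nxt$sunrise
  }
  stop("advance_daylight: window too long", call. = FALSE)
}

# Lateral-jitter SD (as a fraction of track length) calibrated so the
# EXPECTED straightness index of generated tracks matches the target. The
# calibration simulates the full fix-generation process (lognormal track
# lengths, intermediate fixes, GPS noise), because GPS noise alone already
# lowers straightness on short tracks. Runs on a private RNG stream so it
# does not disturb the caller's. If GPS noise alone puts straightness below
# the target, lateral jitter is 0 (the closest attainable world).
calibrate_perp_frac <- function(target, gps_axis_sd, meanlog, sdlog,
                                n_mid = 2L, n_sim = 4000L) {
  if (target >= 1 && gps_axis_sd == 0) return(0)
  sim <- function(frac) {
    rs <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
    set.seed(991L)
    s <- numeric(n_sim)
    for (i in seq_len(n_sim)) {
      L <- stats::rlnorm(1, meanlog, sdlog)
      fr <- sort(stats::runif(n_mid))
      xs <- c(0, fr, 1) * L
      ys <- c(0, stats::rnorm(n_mid, 0, frac * L), 0)
      if (gps_axis_sd > 0) {
        xs <- xs + stats::rnorm(n_mid + 2, 0, gps_axis_sd)
        ys <- ys + stats::rnorm(n_mid + 2, 0, gps_axis_sd)
      }
      path <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
      s[i] <- sqrt((xs[n_mid + 2] - xs[1])^2 + (ys[n_mid + 2] - ys[1])^2) / path
    }
    mean(s)
  }
  if (sim(0) <= target) return(0)
  stats::uniroot(function(f) sim(f) - target, c(1e-5, 1.5), tol = 1e-4)$root
}

# Draw one reflected angle from the configured mixture, truncated by
# resampling to [-pi/2, pi/2].
draw_reflected <- function(mix) {
  for (i in 1:1000) {
    th <- if (stats::runif(1) < mix$lambda) {
      stats::rnorm(1, mix$mu1, mix$sigma1)
    } else stats::rnorm(1, mix$mu2, mix$sigma2)
    if (abs(th) <= pi / 2) return(th)
  }
  stop("mixture truncation failed; check mixture parameters", call. = FALSE)
}

#' Generate a synthetic field dataset
#'
#' @param config a [synth_config()].
#' @return list of class `synth_data`:
#'   \describe{
#'     \item{fixes}{data.frame in the fixes-CSV schema (`track_id,
#'       subject_id, group_id, lat, lon, timestamp_utc, fix_role`).}
#'     \item{events}{data.frame in the events-CSV schema (cache fates).}
#'     \item{burrows}{per-group burrow coordinates and resident group size.}
#'     \item{truth}{every latent draw: per-track component, reflected
#'       angle, toward/away flag, bearing, period index; per-cache intended
#'       category and competing times; the calibration constants.}
#'   }
#' @export
generate_synthetic <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  site <- config$site
  gps_axis_sd <- config$gps_sd_m / sqrt(2)
  perp_frac <- calibrate_perp_frac(config$straightness_target, gps_axis_sd,
                                   config$track_length_meanlog,
                                   config$track_length_sdlog)

  # groups strung along an (east-west) riverbed, a few hundred metres apart
  burrows <- data.frame(
    group_id = paste0("G", seq_len(config$n_groups)),
    burrow_lat = site$lat_deg + stats::rnorm(config$n_groups, 0, 0.0005),
    burrow_lon = site$lon_deg + seq(0, by = 0.004,
                                    length.out = config$n_groups) +
      stats::rnorm(config$n_groups, 0, 0.0005),
    group_size = sample(seq(config$group_size_range[1],
                            config$group_size_range[2]),
                        config$n_groups, replace = TRUE),
    stringsAsFactors = FALSE)

  subjects <- do.call(rbind, lapply(seq_len(config$n_groups), function(g) {
    data.frame(subject_id = paste0("S", g, letters[seq_len(config$subjects_per_group)]),
               group_id = burrows$group_id[g], stringsAsFactors = FALSE)
  }))
  subjects <- subjects[seq_len(min(nrow(subjects), config$subjects_total)), ,
                       drop = FALSE]

  all_days <- seq(config$date_start, config$date_end, by = "day")
  mid_gs <- mean(config$group_size_range)

  fixes <- list(); events <- list(); truth_tracks <- list(); truth_caches <- list()
  track_no <- 0L; cache_no <- 0L
  sched_cache <- new.env()
  get_sched <- function(day) {
    key <- as.character(day)
    if (is.null(sched_cache[[key]])) {
      sched_cache[[key]] <- observation_periods(day, site)
    }
    sched_cache[[key]]
  }

  for (si in seq_len(nrow(subjects))) {
    sub <- subjects[si, ]
    b <- burrows[burrows$group_id == sub$group_id, ]
    burrow <- geo_point(b$burrow_lat, b$burrow_lon)
    gs <- b$group_size
    days <- sample(all_days, config$obs_days_per_subject)
    for (day in as.list(days)) {
      sched <- get_sched(day)
      for (per in seq_len(config$sessions_per_day)) {
        if (stats::runif(1) > config$p_attend) next
        # whole seconds: CSV timestamps are second-resolution
        t_sess <- as.POSIXct(round(as.numeric(sched$period_starts[per])),
                             origin = "1970-01-01", tz = "UTC")
        for (trial in seq_len(config$tracks_per_session)) {
          track_no <- track_no + 1L
          cache_no <- cache_no + 1L
          tid <- sprintf("T%04d", track_no)
          cid <- sprintf("C%04d", cache_no)
          # provisioning start point: clustered near the burrow
          d0 <- stats::rlnorm(1, config$start_dist_meanlog,
                              config$start_dist_sdlog)
          a0 <- stats::runif(1, 0, 2 * pi)
          sx <- d0 * sin(a0); sy <- d0 * cos(a0)
          L <- stats::rlnorm(1, config$track_length_meanlog,
                             config$track_length_sdlog)
          speed <- 0.5  # m/s while moving to the cache site
          t_start <- t_sess + (trial - 1) * 300
          # whole-second fix times so the CSV round-trip is lossless
          dur <- max(ceiling(L / speed), 6)
          t_cache <- t_start + dur
          # latent angular structure, relative to the azimuth at cache time
          theta <- draw_reflected(config$mixture)
          comp <- if (abs(theta - config$mixture$mu1) /
                        config$mixture$sigma1 <
                      abs(theta - config$mixture$mu2) /
                        config$mixture$sigma2) 1L else 2L
          toward <- stats::runif(1) < config$p_toward_sun
          rel <- if (toward) theta else sign(theta) * (pi - abs(theta))
          az <- solar_position(t_cache, burrow)$azimuth_deg
          brg <- wrap_deg(az + rad2deg(rel))
          ex <- sx + L * sin(deg2rad(brg)); ey <- sy + L * cos(deg2rad(brg))
          # intermediate fixes with lateral jitter tuned to the
          # straightness target
          n_mid <- 2L  # near-straight tracks: fixes only at deviations
          frac <- sort(stats::runif(n_mid))
          perp <- if (perp_frac > 0) stats::rnorm(n_mid, 0, perp_frac * L) else rep(0, n_mid)
          ux <- sin(deg2rad(brg)); uy <- cos(deg2rad(brg))
          px <- -uy; py <- ux
          mx <- sx + frac * (ex - sx) + perp * px
          my <- sy + frac * (ey - sy) + perp * py
          xs <- c(sx, mx, ex); ys <- c(sy, my, ey)
          if (config$gps_sd_m > 0) {
            xs <- xs + stats::rnorm(length(xs), 0, gps_axis_sd)
            ys <- ys + stats::rnorm(length(ys), 0, gps_axis_sd)
          }
          tt <- as.numeric(t_start) +
            c(0, sort(sample(seq_len(dur - 1), n_mid)), dur)
          ll <- inv_local_xy(xs, ys, burrow)
          fixes[[length(fixes) + 1L]] <- data.frame(
            track_id = tid, subject_id = sub$subject_id,
            group_id = sub$group_id, lat = ll$lat_deg, lon = ll$lon_deg,
            timestamp_utc = format_utc(tt),
            fix_role = c("start", rep("mid", n_mid), "stop"),
            stringsAsFactors = FALSE)
          truth_tracks[[length(truth_tracks) + 1L]] <- data.frame(
            track_id = tid, cache_id = cid, subject_id = sub$subject_id,
            group_id = sub$group_id, period = per,
            component = comp, theta = theta, toward = toward,
            rel_angle = rel, bearing_deg = brg, sun_azimuth_deg = az,
            track_length_m = L, stringsAsFactors = FALSE)

          # cache fate: theft (hazard in the number of individuals present)
          # races the planned recovery at the A24 instant or the PRE24
          # mirror instant. Presence fluctuates around ~70% of residents.
          n_present <- 1L + stats::rbinom(1, gs - 1L, 0.7)
          haz <- config$theft_base_hazard +
            config$hazard_per_individual * n_present
          theft_dl_h <- stats::rexp(1, haz)
          p_pre <- stats::plogis(config$p_pre24_slope * (n_present - 0.7 * mid_gs))
          pre24 <- stats::runif(1) < p_pre
          az24 <- solar_position(t_cache + 86400, burrow)$azimuth_deg
          if (pre24) {
            target_az <- mirrored_azimuth(az24)
            t_rec <- time_at_azimuth(as.Date(t_cache), target_az, burrow)
            if (is.na(t_rec) || t_rec <= t_cache) {
              t_rec <- time_at_azimuth(as.Date(t_cache) + 1, target_az, burrow)
            }
          } else {
            t_rec <- t_cache + 86400
          }
          if (config$recovery_jitter_min > 0) {
            t_rec <- t_rec + stats::rnorm(1, 0, config$recovery_jitter_min * 60)
          }
          ssr <- get_sched(as.Date(t_rec))
          t_rec <- min(max(t_rec, ssr$sunrise + 60), ssr$sunset - 60)
          t_rec <- max(t_rec, t_cache + 60)  # cannot recover before caching
          monitor_end <- t_cache + config$monitor_days * 86400
          # thefts far beyond the monitoring window need no exact instant
          theft_t <- if (theft_dl_h > 15 * (config$monitor_days + 1)) {
            monitor_end + 86400
          } else advance_daylight(t_cache, theft_dl_h, site)
          if (theft_t < t_rec) {
            outcome <- "stolen"
            ev_t <- theft_t
          } else {
            outcome <- "recovered_by_cacher"
            ev_t <- t_rec
          }
          if (ev_t > monitor_end) {
            outcome <- "intact"; ev_t <- NA
          }
          cl <- inv_local_xy(ex, ey, burrow)
          events[[length(events) + 1L]] <- data.frame(
            cache_id = cid, group_id = sub$group_id,
            subject_id = sub$subject_id,
            cache_time_utc = format_utc(t_cache),
            cache_lat = cl$lat_deg, cache_lon = cl$lon_deg,
            burrow_lat = b$burrow_lat, burrow_lon = b$burrow_lon,
            outcome = outcome,
            event_time_utc = if (is.na(ev_t[1])) NA_character_ else format_utc(ev_t),
            group_size = n_present, stringsAsFactors = FALSE)
          truth_caches[[length(truth_caches) + 1L]] <- data.frame(
            cache_id = cid, intended_category = if (pre24) "PRE24" else "A24",
            n_present = n_present, resident_group_size = gs,
            p_pre24 = p_pre, theft_daylight_h = theft_dl_h,
            planned_recovery_utc = format_utc(t_rec),
            theft_utc = format_utc(theft_t), outcome = outcome,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- list(
    fixes = do.call(rbind, c(fixes, list(make.row.names = FALSE))),
    events = do.call(rbind, c(events, list(make.row.names = FALSE))),
    burrows = burrows,
    truth = list(config = unclass(config)[setdiff(names(config), "site")],
                 site = list(lat_deg = site$lat_deg, lon_deg = site$lon_deg),
                 perp_frac = perp_frac,
                 tracks = do.call(rbind, c(truth_tracks, list(make.row.names = FALSE))),
                 caches = do.call(rbind, c(truth_caches, list(make.row.names = FALSE))),
                 run_id = sprintf("synth-seed%d", config$seed)))
  class(out) <- "synth_data"
  out
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf("<synth_data: %d fixes, %d tracks, %d cache events, %d groups>\n",
              nrow(x$fixes), length(unique(x$fixes$track_id)),
              nrow(x$events), nrow(x$burrows)))
  invisible(x)
}

#' Write a synthetic dataset to CSV/JSON files
#'
#' Writes `fixes.csv`, `events.csv`, `burrows.csv` and `truth.json` (the
#' exact dialects the readers consume).
#'
#' @param sim a [generate_synthetic()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths.
#' @export
write_synth <- function(sim, dir) {
  stopifnot(inherits(sim, "synth_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("fixes.csv", "events.csv", "burrows.csv",
                            "truth.json"))
  utils::write.csv(sim$fixes, paths[1], row.names = FALSE)
  utils::write.csv(sim$events, paths[2], row.names = FALSE)
  utils::write.csv(sim$burrows, paths[3], row.names = FALSE)
  writeLines(jsonlite::toJSON(sim$truth, dataframe = "columns",
                              auto_unbox = TRUE, digits = NA, null = "null"),
             paths[4])
  invisible(paths)
}

#' Compare pipeline estimates with the generator's latent truth
#'
#' @param truth the `truth` element of a [generate_synthetic()] result.
#' @param fit a [em_fit()] on the pipeline's reflected angles (optional).
#' @param recoveries a [classify_recoveries()] table (optional).
#' @param tracks per-track metrics table (optional; used for the
#'   angle-recovery error).
#' @return list with `mixture_errors` (fitted minus configured parameters),
#'   `classification` (confusion matrix and accuracy of PRE24/A24 against
#'   the intended category), and `angle_rmse` (RMSE of recovered reflected
#'   angles against the latent draws, matched by track).
#' @export
truth_compare <- function(truth, fit = NULL, recoveries = NULL, tracks = NULL) {
  out <- list(run_id = truth$run_id)
  if (!is.null(fit)) {
    mix <- truth$config$mixture
    out$mixture_errors <- c(lambda = fit$lambda - mix$lambda,
                            mu1 = fit$mu1 - mix$mu1, mu2 = fit$mu2 - mix$mu2,
                            sigma1 = fit$sigma1 - mix$sigma1,
                            sigma2 = fit$sigma2 - mix$sigma2)
  }
  if (!is.null(recoveries)) {
    m <- merge(recoveries, truth$caches[, c("cache_id", "intended_category")],
               by = "cache_id")
    m <- m[!is.na(m$category), , drop = FALSE]
    if (nrow(m)) {
      tab <- table(intended = m$intended_category, classified = m$category)
      out$classification <- list(confusion = tab,
                                 accuracy = mean(m$category == m$intended_category),
                                 n = nrow(m))
    }
  }
  if (!is.null(tracks)) {
    m <- merge(tracks, truth$tracks[, c("track_id", "theta")], by = "track_id")
    m <- m[!is.na(m$reflected_rad), , drop = FALSE]
    if (nrow(m)) {
      out$angle_rmse <- sqrt(mean((m$reflected_rad - m$theta)^2))
    }
  }
  out
}
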