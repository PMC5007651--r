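#' End-to-end analysis pipeline
#'
#' Orchestrates tracks -> distributional analysis -> recovery
#' classification -> mixed models -> foraging areas on fix/event tables,
#' writing per-stage CSV/JSON outputs plus one combined report.
#' @name pipeline
NULL

#' Assign each track to its daily observation period
#'
#' @param times POSIXct cache instants.
#' @param loc a [geo_point()].
#' @return integer vector: index (1-4) of the nearest observation-period
#'   start on each instant's day.
#' @export
assign_period <- function(times, loc = study_site()) {
  times <- as_utc(times)
  days <- as.Date(times)
  out <- integer(length(times))
  for (d in unique(days)) {
    idx <- which(days == d)
    sched <- observation_periods(as.Date(d, origin = "1970-01-01"), loc)
    for (i in idx) {
      out[i] <- which.min(abs(as.numeric(times[i]) -
                                as.numeric(sched$period_starts)))
    }
  }
  out
}

#' Run the complete pipeline on in-memory tables
#'
#' @param fixes fixes table (schema of [read_fixes_csv()]).
#' @param events cache-events table.
#' @param burrows per-group burrow table (`group_id`, `burrow_lat`,
#'   `burrow_lon`).
#' @param site a [geo_point()] used for period assignment.
#' @param seed seed for the stochastic stages (dip test Monte Carlo, EM
#'   restarts, bootstrap).
#' @param B bootstrap replicates for the mixture standard errors (set to 0
#'   to skip the bootstrap).
#' @param n_mc dip-test Monte-Carlo replicates.
#' @return list of class `pipeline_report` with elements `tracks` (per-track
#'   metrics + period + component), `dip`, `mixture`, `bootstrap`,
#'   `moments`, `component_comparison`, `toward_away_ks`, `recoveries`,
#'   `recovery_summary`, `proportion_test`, `areas`, `models`, and `meta`.
#' @export
run_pipeline <- function(fixes, events, burrows, site = study_site(),
                         seed = 1L, B = 200L, n_mc = 2000L) {
  tracks <- if (is.data.frame(fixes)) {
    df <- tempfile(fileext = ".csv")
    utils::write.csv(fixes, df, row.names = FALSE)
    on.exit(unlink(df), add = TRUE)
    read_fixes_csv(df)
  } else fixes
  tr <- track_metrics_table(tracks, burrows)
  tr$period <- assign_period(as_utc(tr$cache_time_utc), site)

  ang <- tr$reflected_rad[!is.na(tr$reflected_rad)]
  dip <- dip_test(ang, n_mc = n_mc, seed = seed)
  fit <- em_fit(ang, seed = seed + 1L)
  boot <- if (B > 0) bootstrap_se(fit, B = B, seed = seed + 2L) else NULL
  resp <- mixture_responsibilities(fit, tr$reflected_rad)
  tr$component <- ifelse(is.na(tr$reflected_rad), NA_integer_, resp$component)
  mom_all <- moments(ang)
  comp_cmp <- tryCatch(compare_components(fit, ang), error = function(e) NULL)
  ta <- tryCatch(
    ks_2sample(abs(tr$reflected_rad[tr$toward_sun %in% TRUE]),
               abs(tr$reflected_rad[tr$toward_sun %in% FALSE])),
    error = function(e) NULL)

  recov <- classify_recoveries(events)
  rec_summary <- theft_summary(events)
  prop <- if (!is.null(recov)) {
    cl <- recov$category[!is.na(recov$category)]
    proportion_test(sum(cl == "PRE24"), length(cl))
  } else NULL

  starts <- do.call(rbind, lapply(tracks, function(t) data.frame(
    subject_id = t$subject_id, group_id = t$group_id,
    lat_deg = t$lat_deg[1], lon_deg = t$lon_deg[1],
    stringsAsFactors = FALSE)))
  areas <- area_report(starts, burrows)

  models <- paper_model_suite(tracks = tr, recoveries = recov,
                              events = events,
                              areas = area_report_long(areas))
  structure(list(
    tracks = tr, dip = dip, mixture = fit, bootstrap = boot,
    moments = mom_all, component_comparison = comp_cmp,
    toward_away_ks = ta, recoveries = recov,
    recovery_summary = rec_summary, proportion_test = prop,
    areas = areas, models = models,
    meta = list(seed = seed, n_tracks = nrow(tr),
                n_angle_tracks = length(ang),
                n_events = nrow(events),
                version = as.character(utils::packageVersion("solarcache")))),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d tracks (%d with angles), %d cache events\n",
              x$meta$n_tracks, x$meta$n_angle_tracks, x$meta$n_events))
  cat(sprintf("  dip D = %.4f (MC p = %.3f)\n", x$dip$D, x$dip$p))
  cat(sprintf("  mixture: lambda = %.2f, mu = (%.3f, %.3f), sigma = (%.3f, %.3f)\n",
              x$mixture$lambda, x$mixture$mu1, x$mixture$mu2,
              x$mixture$sigma1, x$mixture$sigma2))
  cat(sprintf("  mean straightness = %.3f (skewness %.2f)\n",
              mean(x$tracks$straightness),
              moments(x$tracks$straightness)$skewness))
  if (!is.null(x$recoveries)) {
    cl <- x$recoveries$category[!is.na(x$recoveries$category)]
    cat(sprintf("  recoveries: %d (PRE24 %d / A24 %d), prop test chi2 = %.2f, p = %.3f\n",
                length(cl), sum(cl == "PRE24"), sum(cl == "A24"),
                x$proportion_test$chi2, x$proportion_test$p))
  }
  cat(sprintf("  mean %% of null area covered: %.1f%%\n",
              mean(x$areas$pct_covered)))
  invisible(x)
}

# serialisable subset of a report (drops model objects)
report_for_json <- function(rep) {
  list(meta = rep$meta,
       dip = rep$dip,
       mixture = unclass(rep$mixture)[c("lambda", "mu1", "mu2", "sigma1",
                                        "sigma2", "loglik", "n_iter",
                                        "converged", "n")],
       bootstrap = if (!is.null(rep$bootstrap)) {
         unclass(rep$bootstrap)[c("B", "se_lambda", "se_mu1", "se_mu2",
                                  "se_sigma1", "se_sigma2", "n_failed")]
       },
       moments = rep$moments,
       toward_away_ks = rep$toward_away_ks,
       recovery_summary = rep$recovery_summary,
       proportion_test = rep$proportion_test,
       models = lapply(rep$models, function(m) m[setdiff(names(m), "model")]),
       straightness = list(mean = mean(rep$tracks$straightness),
                           sd = stats::sd(rep$tracks$straightness),
                           skewness = moments(rep$tracks$straightness)$skewness),
       areas = list(mean_pct_covered = mean(rep$areas$pct_covered),
                    sd_pct_covered = stats::sd(rep$areas$pct_covered)))
}

#' Run the pipeline on files and write a report bundle
#'
#' Reads `fixes.csv`, `events.csv` and `burrows.csv` from `input_dir`,
#' runs [run_pipeline()], and writes per-track metrics, recovery
#' classifications, the area report (CSVs), a combined `report.json` and a
#' `manifest.json` (seed, inputs, package version) into `out_dir`.
#'
#' @param input_dir directory with the three input CSVs.
#' @param out_dir output directory (created if needed).
#' @param site a [geo_point()].
#' @param seed,B,n_mc passed to [run_pipeline()].
#' @return the `pipeline_report`, invisibly.
#' @export
run_pipeline_files <- function(input_dir, out_dir, site = study_site(),
                               seed = 1L, B = 200L, n_mc = 2000L) {
  fixes <- utils::read.csv(file.path(input_dir, "fixes.csv"),
                           stringsAsFactors = FALSE)
  events <- utils::read.csv(file.path(input_dir, "events.csv"),
                            stringsAsFactors = FALSE)
  burrows <- utils::read.csv(file.path(input_dir, "burrows.csv"),
                             stringsAsFactors = FALSE)
  rep <- run_pipeline(fixes, events, burrows, site = site, seed = seed,
                      B = B, n_mc = n_mc)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rep$tracks, file.path(out_dir, "track_metrics.csv"),
                   row.names = FALSE)
  if (!is.null(rep$recoveries)) {
    utils::write.csv(rep$recoveries,
                     file.path(out_dir, "recovery_classification.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(rep$areas, file.path(out_dir, "area_report.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(report_for_json(rep), auto_unbox = TRUE,
                              digits = NA, null = "null", force = TRUE),
             file.path(out_dir, "report.json"))
  manifest <- list(seed = seed, input_dir = normalizePath(input_dir),
                   site = list(lat_deg = site$lat_deg, lon_deg = site$lon_deg),
                   package = "solarcache",
                   version = as.character(utils::packageVersion("solarcache")))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "manifest.json"))
  invisible(rep)
}
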