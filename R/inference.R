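#' Mixed-model inference layer
#'
#' Linear mixed models with random intercepts for subject nested within
#' group, and likelihood-ratio tests (LRT) for fixed effects. Fitting is
#' delegated to lme4 (the modelling machinery is standard; the scientific
#' content of this package lies in the solar/angular/mixture modules). All
#' LRT comparisons use ML fits: REML likelihoods are not comparable across
#' fixed-effect structures. All tested effects are fixed effects, so the
#' chi-squared reference distribution applies without boundary corrections.
#' @name inference
NULL

#' Fit a linear mixed model with subject-in-group random intercepts
#'
#' @param data a data.frame.
#' @param response response column name.
#' @param fixed character vector of fixed-effect terms (may be empty for an
#'   intercept-only model; use `"0"` to drop the intercept).
#' @param random random-effect specification; the default nests subject
#'   within group. Set to NULL to fall back to a plain linear model (used
#'   when the grouping structure is absent).
#' @param method "ML" (default; required for LRTs) or "REML".
#' @return list of class `lmm_fit`: `model` (the lmer/lm object),
#'   `coefficients`, `varcomp` (random-intercept and residual SDs),
#'   `loglik`, `n`, `n_fixed` (fixed-effect parameter count), `singular`
#'   (TRUE when a variance component collapsed to zero).
#' @export
fit_lmm <- function(data, response, fixed = character(),
                    random = "(1 | group_id / subject_id)",
                    method = c("ML", "REML")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), response %in% names(data))
  rhs_fixed <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  if (is.null(random)) {
    fm <- stats::as.formula(paste(response, "~", rhs_fixed))
    m <- stats::lm(fm, data = data)
    out <- list(model = m, coefficients = stats::coef(m),
                varcomp = c(residual = summary(m)$sigma),
                loglik = as.numeric(stats::logLik(m)),
                n = stats::nobs(m), n_fixed = length(stats::coef(m)),
                singular = FALSE, method = method, response = response,
                fixed = fixed)
    class(out) <- "lmm_fit"
    return(out)
  }
  fm <- stats::as.formula(paste(response, "~", rhs_fixed, "+", random))
  m <- suppressMessages(suppressWarnings(
    lme4::lmer(fm, data = data, REML = (method == "REML"))))
  vc <- as.data.frame(lme4::VarCorr(m))
  varcomp <- stats::setNames(vc$sdcor, sub("^Residual$", "residual", vc$grp))
  out <- list(model = m, coefficients = lme4::fixef(m), varcomp = varcomp,
              loglik = as.numeric(stats::logLik(m)), n = stats::nobs(m),
              n_fixed = length(lme4::fixef(m)),
              singular = lme4::isSingular(m), method = method,
              response = response, fixed = fixed)
  class(out) <- "lmm_fit"
  out
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("LMM (%s): %s ~ %s  [n = %d, logLik = %.3f%s]\n",
              x$method, x$response,
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
              x$n, x$loglik, if (x$singular) ", singular fit" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Likelihood-ratio test between nested ML fits
#'
#' @param full,reduced [fit_lmm()] results fitted by ML on identical rows,
#'   with the reduced fixed-effect terms a subset of the full ones.
#' @return list with `chi2`, `df`, `p`, `loglik_full`, `loglik_reduced`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "lmm_fit"), inherits(reduced, "lmm_fit"))
  if (full$method != "ML" || reduced$method != "ML") {
    stop("LRT requires ML fits", call. = FALSE)
  }
  if (full$n != reduced$n) {
    stop("models fitted on different numbers of rows", call. = FALSE)
  }
  if (!all(reduced$fixed %in% full$fixed)) {
    stop("reduced model is not nested in the full model", call. = FALSE)
  }
  df <- full$n_fixed - reduced$n_fixed
  if (df < 0) stop("reduced model has more parameters than the full model",
                   call. = FALSE)
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  list(chi2 = chi2, df = df,
       p = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else 1,
       loglik_full = full$loglik, loglik_reduced = reduced$loglik)
}

# Run one named model + its LRT; returns a record (or a skip record).
run_model <- function(id, desc, data, response, fixed, drop,
                      random = "(1 | group_id / subject_id)") {
  if (is.null(data) || nrow(data) < 8L ||
      !all(c(response, setdiff(fixed, "0")) %in% names(data))) {
    return(list(id = id, description = desc, skipped = TRUE,
                reason = "insufficient or missing input data"))
  }
  data <- data[stats::complete.cases(data[, c(response, setdiff(fixed, "0")),
                                          drop = FALSE]), , drop = FALSE]
  if (nrow(data) < 8L) {
    return(list(id = id, description = desc, skipped = TRUE,
                reason = "fewer than 8 complete rows"))
  }
  use_random <- !is.null(random) &&
    all(c("group_id", "subject_id") %in% names(data)) &&
    length(unique(data$group_id)) >= 2L
  r <- if (use_random) random else NULL
  fit_f <- tryCatch(fit_lmm(data, response, fixed, random = r),
                    error = function(e) NULL)
  fit_r <- tryCatch(fit_lmm(data, response, setdiff(fixed, drop), random = r),
                    error = function(e) NULL)
  if (is.null(fit_f) || is.null(fit_r)) {
    return(list(id = id, description = desc, skipped = TRUE,
                reason = "model fit failed"))
  }
  lr <- lrt(fit_f, fit_r)
  list(id = id, description = desc, skipped = FALSE, n = fit_f$n,
       estimates = as.list(fit_f$coefficients), singular = fit_f$singular,
       chi2 = lr$chi2, df = lr$df, p = lr$p)
}

#' Run the full suite of named mixed models
#'
#' Reproduces the structure of the field analysis on pipeline outputs:
#' \describe{
#'   \item{a_track_vs_sun}{track bearing (signed degrees from north) against
#'     the solar azimuth (signed): do tracks follow the shifting sun?}
#'   \item{b_relangle_vs_period}{reflected track angle against observation
#'     period (factor): is the solar offset constant across the day?}
#'   \item{c1/c2_component_mean}{per mixture component, reflected angle
#'     against zero (intercept-only vs no-intercept LRT).}
#'   \item{d_survival_vs_groupsize}{hours until theft against group size.}
#'   \item{e_groupsize_vs_category}{group size against recovery category.}
#'   \item{f_recovery_vs_cache_az}{relative (meridian-folded) recovery
#'     azimuth against the relative cache azimuth.}
#'   \item{g_error_vs_elevation}{azimuthal recovery error against solar
#'     elevation at caching.}
#'   \item{h_error_vs_category}{azimuthal recovery error against category.}
#'   \item{i_area_vs_null}{log area against area type (alpha hull vs
#'     circular null), paired within subject.}
#' }
#'
#' @param tracks per-track metrics table (needs `bearing_deg`,
#'   `sun_azimuth_deg`, `reflected_rad`, `period`, `component`,
#'   `subject_id`, `group_id`; extra columns ignored).
#' @param recoveries classification table from [classify_recoveries()].
#' @param events full events table (for theft survival).
#' @param areas per-subject area report (long format from
#'   [area_report_long()]).
#' @return list of model records; each has `id`, `description`, and either
#'   `skipped`/`reason` or `n`, `estimates`, `chi2`, `df`, `p`.
#' @export
paper_model_suite <- function(tracks = NULL, recoveries = NULL,
                              events = NULL, areas = NULL) {
  out <- list()
  signed_deg <- function(az) { a <- wrap_deg(az); ifelse(a > 180, a - 360, a) }
  if (!is.null(tracks)) {
    tr <- tracks[!is.na(tracks$reflected_rad), , drop = FALSE]
    # axial track bearing: tracks made away from the sun are rotated by
    # 180 degrees so the heading axis (not the travel direction) is
    # regressed on the solar azimuth; without this folding, pooled
    # toward/away tracks cancel the slope.
    tr$bearing_signed <- signed_deg(
      ifelse(tr$toward_sun, tr$bearing_deg, tr$bearing_deg + 180))
    tr$sun_signed <- signed_deg(tr$sun_azimuth_deg)
    if (!"period" %in% names(tr)) tr$period <- NA
    tr$period <- factor(tr$period)
    out$a_track_vs_sun <- run_model(
      "a_track_vs_sun", "axial track bearing ~ solar azimuth",
      tr, "bearing_signed", "sun_signed", "sun_signed")
    out$b_relangle_vs_period <- run_model(
      "b_relangle_vs_period", "reflected angle ~ observation period",
      tr, "reflected_rad", "period", "period")
    if ("component" %in% names(tr)) {
      for (k in 1:2) {
        trk <- tr[tr$component == k, , drop = FALSE]
        out[[paste0("c", k, "_component_mean")]] <- run_model(
          paste0("c", k, "_component_mean"),
          sprintf("component %d mean vs zero", k),
          trk, "reflected_rad", character(), character())
        # intercept-only vs zero-mean: refit reduced without intercept
        rec <- out[[paste0("c", k, "_component_mean")]]
        if (!isTRUE(rec$skipped)) {
          use_r <- length(unique(trk$group_id)) >= 2L
          r <- if (use_r) "(1 | group_id / subject_id)" else NULL
          f_full <- tryCatch(fit_lmm(trk, "reflected_rad", character(), random = r),
                             error = function(e) NULL)
          f_red <- tryCatch(fit_lmm(trk, "reflected_rad", "0", random = r),
                            error = function(e) NULL)
          if (!is.null(f_full) && !is.null(f_red)) {
            lr0 <- list(chi2 = max(0, 2 * (f_full$loglik - f_red$loglik)), df = 1)
            rec$chi2 <- lr0$chi2; rec$df <- 1L
            rec$p <- stats::pchisq(lr0$chi2, 1, lower.tail = FALSE)
            out[[paste0("c", k, "_component_mean")]] <- rec
          }
        }
      }
    }
  }
  if (!is.null(events)) {
    st <- events[events$outcome == "stolen" & !is.na(events$event_time_utc), ,
                 drop = FALSE]
    if (nrow(st)) {
      st$survival_h <- (as.numeric(as_utc(st$event_time_utc)) -
                          as.numeric(as_utc(st$cache_time_utc))) / 3600
      out$d_survival_vs_groupsize <- run_model(
        "d_survival_vs_groupsize", "cache survival time ~ group size",
        st, "survival_h", "group_size", "group_size")
    }
  }
  if (!is.null(recoveries)) {
    rc <- recoveries[!is.na(recoveries$category), , drop = FALSE]
    rc$rel_az_cache <- abs(signed_deg(rc$az_cache_deg))
    rc$rel_az_recovery <- abs(signed_deg(rc$az_recovery_deg))
    out$e_groupsize_vs_category <- run_model(
      "e_groupsize_vs_category", "group size ~ recovery category",
      rc, "group_size", "category", "category")
    out$f_recovery_vs_cache_az <- run_model(
      "f_recovery_vs_cache_az", "relative recovery azimuth ~ relative cache azimuth",
      rc, "rel_az_recovery", "rel_az_cache", "rel_az_cache")
    out$g_error_vs_elevation <- run_model(
      "g_error_vs_elevation", "azimuthal error ~ elevation at caching",
      rc, "az_error_deg", "elevation_at_cache_deg", "elevation_at_cache_deg")
    out$h_error_vs_category <- run_model(
      "h_error_vs_category", "azimuthal error ~ recovery category",
      rc, "az_error_deg", "category", "category")
  }
  if (!is.null(areas)) {
    ar <- areas
    ar$log_area <- log(pmax(ar$area_m2, 1e-6))
    out$i_area_vs_null <- run_model(
      "i_area_vs_null", "log area ~ area type (hull vs circular null)",
      ar, "log_area", "area_type", "area_type",
      random = "(1 | subject_id)")
  }
  out
}
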