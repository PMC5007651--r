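#' Angle and time helpers shared across modules
#'
#' All internal angle statistics use radians; degrees appear only at I/O
#' boundaries and for compass azimuths (clockwise from true north).
#' @name solarcache-utils
#' @keywords internal
NULL

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Wrap an angle in degrees to [0, 360)
#' @param deg numeric vector of angles in degrees.
#' @return numeric vector in [0, 360).
#' @export
wrap_deg <- function(deg) {
  stopifnot(is.numeric(deg))
  ((deg %% 360) + 360) %% 360
}

#' Wrap an angle in radians to (-pi, pi]
#' @param rad numeric vector of angles in radians.
#' @return numeric vector in (-pi, pi].
#' @export
wrap_pi <- function(rad) {
  stopifnot(is.numeric(rad))
  out <- rad %% (2 * pi)
  out[out > pi] <- out[out > pi] - 2 * pi
  out
}

#' Circular distance between two compass azimuths
#'
#' Shortest angular separation, always in [0, 180] degrees.
#' @param a,b azimuths in degrees.
#' @return numeric vector of separations in degrees.
#' @export
circular_dist_deg <- function(a, b) {
  d <- abs(wrap_deg(a) - wrap_deg(b)) %% 360
  pmin(d, 360 - d)
}

#' Construct a geographic point
#'
#' @param lat_deg latitude in decimal degrees, in [-90, 90].
#' @param lon_deg longitude in decimal degrees, in [-180, 180].
#' @return an object of class `geo_point` (named list with `lat_deg`,
#'   `lon_deg`).
#' @examples
#' geo_point(-26.9667, 21.8167)  # Kalahari study site
#' @export
geo_point <- function(lat_deg, lon_deg) {
  if (!is.numeric(lat_deg) || !is.numeric(lon_deg) ||
      length(lat_deg) != 1L || length(lon_deg) != 1L ||
      !is.finite(lat_deg) || !is.finite(lon_deg)) {
    stop("lat_deg and lon_deg must be single finite numbers", call. = FALSE)
  }
  if (abs(lat_deg) > 90) stop("lat_deg out of range [-90, 90]", call. = FALSE)
  if (abs(lon_deg) > 180) stop("lon_deg out of range [-180, 180]", call. = FALSE)
  structure(list(lat_deg = lat_deg, lon_deg = lon_deg), class = "geo_point")
}

#' @export
print.geo_point <- function(x, ...) {
  cat(sprintf("<geo_point %.5f%s, %.5f%s>\n",
              abs(x$lat_deg), if (x$lat_deg < 0) "S" else "N",
              abs(x$lon_deg), if (x$lon_deg < 0) "W" else "E"))
  invisible(x)
}

#' Default study site: southern Kalahari (26deg58'S, 21deg49'E)
#'
#' @return a `geo_point` for the semi-arid Kalahari site where the focal
#'   ground-squirrel groups live.
#' @export
study_site <- function() geo_point(-(26 + 58 / 60), 21 + 49 / 60)

# Coerce any timestamp-ish input to POSIXct UTC; error if unresolvable.
as_utc <- function(t) {
  if (is.logical(t) && all(is.na(t))) {  # all-NA column (e.g. intact caches)
    return(as.POSIXct(rep(NA_real_, length(t)), origin = "1970-01-01",
                      tz = "UTC"))
  }
  if (inherits(t, "POSIXct")) {
    attr(t, "tzone") <- "UTC"
    return(t)
  }
  if (inherits(t, "Date")) {
    return(as.POSIXct(as.character(t), tz = "UTC"))
  }
  if (is.character(t)) {
    out <- tryCatch(
      as.POSIXct(t, tz = "UTC",
                 tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                                "%Y-%m-%d %H:%M", "%Y-%m-%d")),
      error = function(e) rep(as.POSIXct(NA), length(t)))
    if (anyNA(out)) stop("timestamp not resolvable as UTC: ",
                         paste(t[is.na(out)], collapse = ", "), call. = FALSE)
    return(out)
  }
  if (is.numeric(t)) {
    return(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"))
  }
  stop("cannot interpret timestamp of class ", paste(class(t), collapse = "/"),
       call. = FALSE)
}

format_utc <- function(t) format(as_utc(t), "%Y-%m-%d %H:%M:%S", tz = "UTC")
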