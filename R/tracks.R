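#' Cache-track geometry
#'
#' Local planar projection, bearings, path length and straightness, the
#' signed/reflected track-angle transform relative to the solar azimuth, and
#' the circular caching-area boundary. At the <=100 m scale of cache tracks a
#' local equirectangular projection centred on the burrow replaces spherical
#' trigonometry; the projection error is orders of magnitude below the
#' +/-1.5 m GPS accuracy.
#' @name tracks
NULL

EARTH_RADIUS_M <- 6371008.8

#' Project a point to local planar coordinates
#'
#' Equirectangular projection about `origin`: x east-positive, y
#' north-positive, metres.
#'
#' @param p,origin [geo_point()]s (or data.frames with `lat_deg`, `lon_deg`
#'   columns for `p`).
#' @return for a single point, numeric `c(x_m, y_m)`; for a data.frame, a
#'   two-column matrix.
#' @export
local_xy <- function(p, origin) {
  if (!inherits(origin, "geo_point")) stop("origin must be a geo_point", call. = FALSE)
  if (inherits(p, "geo_point")) {
    lat <- p$lat_deg; lon <- p$lon_deg
  } else if (is.data.frame(p)) {
    lat <- p$lat_deg; lon <- p$lon_deg
  } else stop("p must be a geo_point or data.frame", call. = FALSE)
  x <- EARTH_RADIUS_M * deg2rad(lon - origin$lon_deg) * cos(deg2rad(origin$lat_deg))
  y <- EARTH_RADIUS_M * deg2rad(lat - origin$lat_deg)
  if (any(sqrt(x^2 + y^2) > 5000)) {
    stop("point further than 5 km from projection origin", call. = FALSE)
  }
  if (length(x) == 1L) c(x_m = unname(x), y_m = unname(y)) else cbind(x_m = x, y_m = y)
}

#' Inverse of the local projection
#' @param x_m,y_m local coordinates in metres.
#' @param origin a [geo_point()].
#' @return a data.frame with `lat_deg`, `lon_deg`.
#' @export
inv_local_xy <- function(x_m, y_m, origin) {
  lat <- origin$lat_deg + rad2deg(y_m / EARTH_RADIUS_M)
  lon <- origin$lon_deg + rad2deg(x_m / (EARTH_RADIUS_M * cos(deg2rad(origin$lat_deg))))
  data.frame(lat_deg = lat, lon_deg = lon)
}

#' Compass bearing between two points
#'
#' @param start,stop [geo_point()]s.
#' @param origin projection origin; defaults to `start`.
#' @return bearing in degrees clockwise from true north, in [0, 360).
#' @export
bearing <- function(start, stop, origin = start) {
  a <- local_xy(start, origin)
  b <- local_xy(stop, origin)
  dx <- unname(b[1] - a[1]); dy <- unname(b[2] - a[2])
  if (dx == 0 && dy == 0) stop("undefined bearing: zero displacement", call. = FALSE)
  wrap_deg(rad2deg(atan2(dx, dy)))
}

#' Construct a cache track
#'
#' An ordered sequence of GPS fixes from the provisioning point (first fix)
#' to the cache point (last fix).
#'
#' @param track_id,subject_id,group_id identifiers.
#' @param lat_deg,lon_deg numeric vectors of fix coordinates (>= 2 fixes).
#' @param time_utc fix timestamps, strictly increasing.
#' @return an object of class `cache_track`.
#' @export
cache_track <- function(track_id, subject_id, group_id, lat_deg, lon_deg,
                        time_utc) {
  n <- length(lat_deg)
  if (n < 2L || length(lon_deg) != n) {
    stop("a cache track needs >= 2 fixes with matching lat/lon", call. = FALSE)
  }
  time_utc <- as_utc(time_utc)
  if (length(time_utc) != n || any(diff(as.numeric(time_utc)) <= 0)) {
    stop("fix timestamps must be strictly increasing", call. = FALSE)
  }
  structure(list(track_id = track_id, subject_id = subject_id,
                 group_id = group_id, lat_deg = lat_deg, lon_deg = lon_deg,
                 time_utc = time_utc, cache_time = time_utc[n]),
            class = "cache_track")
}

#' Path length, Euclidean displacement and straightness of a track
#'
#' Straightness is the Euclidean start-to-stop distance divided by the total
#' path length: 1 for a perfectly straight track, approaching 0 for a highly
#' tortuous one. Fixes were recorded at deviations from a straight path, so
#' the observed path length is a lower bound on the true path length; no
#' correction is attempted.
#'
#' @param track a [cache_track()].
#' @return list with `path_length_m`, `euclid_m`, `straightness`.
#' @export
straightness <- function(track) {
  stopifnot(inherits(track, "cache_track"))
  origin <- geo_point(track$lat_deg[1], track$lon_deg[1])
  xy <- local_xy(data.frame(lat_deg = track$lat_deg, lon_deg = track$lon_deg),
                 origin)
  xy <- unname(xy)
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  path <- sum(seg)
  if (path == 0) stop("degenerate track: all fixes coincident", call. = FALSE)
  n <- nrow(xy)
  euclid <- sqrt((xy[n, 1] - xy[1, 1])^2 + (xy[n, 2] - xy[1, 2])^2)
  list(path_length_m = path, euclid_m = euclid, straightness = euclid / path)
}

#' Signed angular offset of a track bearing from the solar azimuth
#'
#' Positive values mean the track points to the right (clockwise) of the sun,
#' negative to the left; 0 means the animal moved directly towards (or, for
#' |angle| > pi/2, away from) the sun's azimuth.
#'
#' @param bearing_deg track bearing, degrees clockwise from north.
#' @param sun_azimuth_deg solar azimuth, degrees clockwise from north.
#' @return signed offset in radians, in (-pi, pi].
#' @export
signed_rel_angle <- function(bearing_deg, sun_azimuth_deg) {
  stopifnot(is.finite(bearing_deg), is.finite(sun_azimuth_deg))
  wrap_pi(deg2rad(bearing_deg - sun_azimuth_deg))
}

#' Reflect a signed track angle into [-pi/2, pi/2]
#'
#' Tracks made while moving away from the sun (|angle| > pi/2) are reflected
#' about the line joining -pi/2 and +pi/2, putting towards- and away-moving
#' tracks on a common scale bounded by [-pi/2, pi/2] while preserving the
#' left/right sign. This bounding is what lets the downstream analysis avoid
#' circular statistics.
#'
#' @param a signed relative angle(s) in radians, in (-pi, pi].
#' @return list with `reflected_rad` in [-pi/2, pi/2] and logical
#'   `toward_sun` (TRUE when |a| <= pi/2, i.e. no reflection applied).
#' @export
reflect_half <- function(a) {
  stopifnot(is.numeric(a), all(is.finite(a)))
  if (any(a <= -pi - 1e-12 | a > pi + 1e-12)) {
    stop("input must lie in (-pi, pi]", call. = FALSE)
  }
  toward <- abs(a) <= pi / 2
  out <- ifelse(toward, a, sign(a) * (pi - abs(a)))
  list(reflected_rad = out, toward_sun = toward)
}

#' Full per-track angle computation
#'
#' Bearing from first to last fix (intermediate fixes contribute only to path
#' length), solar azimuth at the cache instant evaluated at the burrow
#' centre, and the signed/reflected offsets.
#'
#' @param track a [cache_track()].
#' @param burrow [geo_point()] of the group's burrow centre (reference point
#'   for the solar azimuth).
#' @param min_displacement_m tracks with Euclidean displacement below this
#'   (default 3 m = 2x GPS accuracy) are flagged `degenerate`: their bearing
#'   is noise-dominated and they are excluded from angle analyses.
#' @return one-row data.frame of track metrics (see the fixes writer schema).
#' @export
track_angles <- function(track, burrow, min_displacement_m = 3) {
  stopifnot(inherits(track, "cache_track"))
  m <- straightness(track)
  n <- length(track$lat_deg)
  start <- geo_point(track$lat_deg[1], track$lon_deg[1])
  stop_ <- geo_point(track$lat_deg[n], track$lon_deg[n])
  degenerate <- m$euclid_m < min_displacement_m
  sun <- solar_position(track$cache_time, burrow)
  if (degenerate) {
    brg <- NA_real_; rel <- NA_real_; refl <- NA_real_; toward <- NA
  } else {
    brg <- bearing(start, stop_, origin = burrow)
    rel <- signed_rel_angle(brg, sun$azimuth_deg)
    rh <- reflect_half(rel)
    refl <- rh$reflected_rad; toward <- rh$toward_sun
  }
  data.frame(track_id = track$track_id, subject_id = track$subject_id,
             group_id = track$group_id,
             cache_time_utc = format_utc(track$cache_time),
             bearing_deg = brg, sun_azimuth_deg = sun$azimuth_deg,
             sun_elevation_deg = sun$elevation_deg,
             rel_angle_rad = rel, reflected_rad = refl, toward_sun = toward,
             path_m = m$path_length_m, euclid_m = m$euclid_m,
             straightness = m$straightness, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Circular caching-area boundary for a group
#'
#' The hypothetical caching-area boundary is the circle centred on the home
#' burrow whose radius is the distance to the group's farthest cache point.
#'
#' @param burrow [geo_point()] burrow centre.
#' @param caches data.frame with `lat_deg`, `lon_deg` of cache points (>= 1).
#' @return list with `center`, `radius_m`, and `boundary_point(az_deg)`, a
#'   function returning the [geo_point()] where azimuth `az_deg` from the
#'   burrow meets the boundary circle.
#' @export
caching_boundary <- function(burrow, caches) {
  if (!is.data.frame(caches) || nrow(caches) < 1L) {
    stop("need at least one cache point", call. = FALSE)
  }
  xy <- local_xy(caches, burrow)
  r <- max(sqrt(xy[, 1]^2 + xy[, 2]^2))
  bp <- function(az_deg) {
    p <- inv_local_xy(r * sin(deg2rad(az_deg)), r * cos(deg2rad(az_deg)), burrow)
    geo_point(p$lat_deg, p$lon_deg)
  }
  list(center = burrow, radius_m = r, boundary_point = bp)
}

#' Read a fixes CSV into a list of cache tracks
#'
#' Expected columns: `track_id, subject_id, group_id, lat, lon,
#' timestamp_utc, fix_role` with `fix_role` in start/mid/stop.
#'
#' @param path CSV file path.
#' @return named list of [cache_track()] objects, ordered by track_id.
#' @export
read_fixes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "subject_id", "group_id", "lat", "lon",
            "timestamp_utc", "fix_role")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("fixes CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$fix_role %in% c("start", "mid", "stop") |
                 !is.finite(df$lat) | !is.finite(df$lon))
  if (length(bad)) {
    stop("malformed fixes CSV row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$track_id), function(d) {
    d <- d[order(as.POSIXct(d$timestamp_utc, tz = "UTC")), ]
    cache_track(d$track_id[1], d$subject_id[1], d$group_id[1],
                d$lat, d$lon, d$timestamp_utc)
  })
  out[order(names(out))]
}

#' Read GPX tracks into cache tracks
#'
#' Each GPX `<trk>` becomes one [cache_track()]: track points in document
#' order, the first point the provisioning start and the last the cache.
#' The GPX track `<name>` is used as the track id; subject and group ids
#' are taken from `<desc>` as "subject_id/group_id" when present.
#'
#' @param path GPX file path.
#' @param subject_id,group_id fallback identifiers when the GPX carries
#'   none.
#' @return named list of [cache_track()] objects.
#' @export
read_fixes_gpx <- function(path, subject_id = "S1", group_id = "G1") {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  trks <- xml2::xml_find_all(doc, ".//g:trk", ns)
  if (!length(trks)) stop("no <trk> elements in GPX file", call. = FALSE)
  out <- lapply(seq_along(trks), function(i) {
    trk <- trks[[i]]
    nm <- xml2::xml_text(xml2::xml_find_first(trk, "./g:name", ns))
    if (is.na(nm) || nm == "") nm <- sprintf("gpx%03d", i)
    desc <- xml2::xml_text(xml2::xml_find_first(trk, "./g:desc", ns))
    sid <- subject_id; gid <- group_id
    if (!is.na(desc) && grepl("/", desc, fixed = TRUE)) {
      parts <- strsplit(desc, "/", fixed = TRUE)[[1]]
      sid <- parts[1]; gid <- parts[2]
    }
    pts <- xml2::xml_find_all(trk, ".//g:trkpt", ns)
    if (length(pts) < 2) stop("GPX track '", nm, "' has fewer than 2 points",
                              call. = FALSE)
    cache_track(nm, sid, gid,
                as.numeric(xml2::xml_attr(pts, "lat")),
                as.numeric(xml2::xml_attr(pts, "lon")),
                xml2::xml_text(xml2::xml_find_all(pts, "./g:time", ns)))
  })
  names(out) <- vapply(out, function(t) t$track_id, character(1))
  out[order(names(out))]
}

#' Compute the per-track metrics table for a set of tracks
#'
#' @param tracks list of [cache_track()]s.
#' @param burrows data.frame with `group_id`, `burrow_lat`, `burrow_lon`.
#' @param min_displacement_m passed to [track_angles()].
#' @return data.frame with one row per track.
#' @export
track_metrics_table <- function(tracks, burrows, min_displacement_m = 3) {
  rows <- lapply(tracks, function(tr) {
    b <- burrows[burrows$group_id == tr$group_id, , drop = FALSE]
    if (nrow(b) == 0) stop("no burrow metadata for group ", tr$group_id, call. = FALSE)
    track_angles(tr, geo_point(b$burrow_lat[1], b$burrow_lon[1]),
                 min_displacement_m)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
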