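#' Foraging-area estimation: alpha hull versus circular null
#'
#' The used foraging area of a subject is estimated as the area of the
#' alpha shape of its provisioning start points, at the smallest alpha for
#' which every input point lies on or in the shape (so no point is left
#' stranded outside). The null model is the circle centred on the burrow
#' whose radius is the maximum start-point distance: if a subject ranged
#' homogeneously, the two areas would be comparable; strongly clustered
#' start points give an alpha-hull area that is a small fraction of the
#' null.
#'
#' The alpha shape is built from the Delaunay triangulation (triangles with
#' circumradius <= alpha are kept). The "minimum convex hull with an alpha
#' value" phrasing used in field work is internally contradictory (alpha
#' shapes are generally non-convex); both the alpha-shape and convex-hull
#' areas are therefore reported, with the convex hull as fallback for
#' degenerate configurations.
#' @name area
NULL

shoelace_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

tri_area <- function(x, y, tri) {
  abs((x[tri[, 2]] - x[tri[, 1]]) * (y[tri[, 3]] - y[tri[, 1]]) -
        (x[tri[, 3]] - x[tri[, 1]]) * (y[tri[, 2]] - y[tri[, 1]])) / 2
}

#' Alpha-shape area of a planar point set
#'
#' Finds the smallest alpha (over the finite set of triangle circumradii,
#' an exact search equivalent to bisection) such that every input point is
#' a vertex of at least one retained Delaunay triangle, and returns the
#' total area of the retained triangles.
#'
#' @param x,y point coordinates in metres (local projection).
#' @return list with `area_m2`, `alpha_m` (chosen alpha; Inf means the full
#'   triangulation/convex hull), `convex_area_m2`, `degenerate` (TRUE when
#'   fewer than 3 non-collinear points: areas are 0).
#' @export
alpha_hull_area <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !duplicated(cbind(x, y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    return(list(area_m2 = 0, alpha_m = NA_real_, convex_area_m2 = 0,
                degenerate = TRUE))
  }
  ch <- grDevices::chull(x, y)
  if (length(ch) < 3L) {  # all collinear
    return(list(area_m2 = 0, alpha_m = NA_real_, convex_area_m2 = 0,
                degenerate = TRUE))
  }
  convex_area <- shoelace_area(x[ch], y[ch])
  # deterministic symbolic perturbation so cocircular point sets (e.g.
  # rectangles) triangulate uniquely; areas use the original coordinates
  scale <- max(diff(range(x)), diff(range(y)))
  eps <- scale * 1e-9
  set_jit <- function(v, salt) v + eps * sin(salt * seq_along(v) + salt)
  dt <- .delaunay_cpp(set_jit(x, 1.3), set_jit(y, 2.7))
  tri <- cbind(dt$i, dt$j, dt$k)
  if (nrow(tri) == 0L) {
    return(list(area_m2 = convex_area, alpha_m = Inf,
                convex_area_m2 = convex_area, degenerate = FALSE))
  }
  r <- dt$circumradius
  areas <- tri_area(x, y, tri)
  # Smallest alpha (among circumradii) such that every input point is a
  # vertex of the retained complex AND the complex is edge-connected. The
  # connectivity requirement is what makes convex-position inputs reproduce
  # their convex hull exactly: every ear triangle is forced by its private
  # vertex, and connecting the ears forces the whole adjacency tree.
  alphas <- sort(unique(r))
  covered_at <- function(a) {
    sel <- which(r <= a)
    if (!length(sel)) return(FALSE)
    kept <- tri[sel, , drop = FALSE]
    if (length(unique(as.vector(kept))) != n) return(FALSE)
    # union-find over triangles sharing an edge
    parent <- seq_along(sel)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    edge_key <- function(a_, b_) paste(pmin(a_, b_), pmax(a_, b_))
    edges <- new.env(parent = emptyenv())
    for (t_ in seq_along(sel)) {
      v <- kept[t_, ]
      for (k in edge_key(v[c(1, 1, 2)], v[c(2, 3, 3)])) {
        o <- edges[[k]]
        if (is.null(o)) edges[[k]] <- t_ else {
          ra <- find(o); rb <- find(t_)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
    length(unique(vapply(seq_along(sel), find, integer(1)))) == 1L
  }
  lo <- 1L; hi <- length(alphas)
  if (!covered_at(alphas[hi])) {
    # triangulation misses a vertex (should not happen): convex fallback
    return(list(area_m2 = convex_area, alpha_m = Inf,
                convex_area_m2 = convex_area, degenerate = FALSE))
  }
  while (lo < hi) {  # binary search over the candidate alphas
    mid <- (lo + hi) %/% 2L
    if (covered_at(alphas[mid])) hi <- mid else lo <- mid + 1L
  }
  alpha <- alphas[lo]
  list(area_m2 = sum(areas[r <= alpha]), alpha_m = alpha,
       convex_area_m2 = convex_area, degenerate = FALSE)
}

#' Circular null foraging area
#'
#' @param x,y start-point coordinates (metres, local projection centred on
#'   the burrow).
#' @return list with `radius_m` (maximum distance from the origin/burrow)
#'   and `area_m2` (pi r^2); `degenerate` flags zero radius.
#' @export
null_area <- function(x, y) {
  if (length(x) < 1L) stop("need at least one start point", call. = FALSE)
  r <- max(sqrt(x^2 + y^2))
  list(radius_m = r, area_m2 = pi * r^2, degenerate = r == 0)
}

#' Per-subject foraging-area report
#'
#' @param starts data.frame of start points with `subject_id`, `group_id`,
#'   `lat_deg`, `lon_deg`.
#' @param burrows data.frame with `group_id`, `burrow_lat`, `burrow_lon`.
#' @return data.frame with one row per subject: `hull_area_m2`,
#'   `convex_area_m2`, `alpha_m`, `null_radius_m`, `null_area_m2`,
#'   `pct_covered` (100 * hull / null).
#' @export
area_report <- function(starts, burrows) {
  rows <- lapply(split(starts, starts$subject_id), function(d) {
    b <- burrows[burrows$group_id == d$group_id[1], , drop = FALSE]
    origin <- geo_point(b$burrow_lat[1], b$burrow_lon[1])
    xy <- local_xy(data.frame(lat_deg = d$lat_deg, lon_deg = d$lon_deg), origin)
    if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
    h <- alpha_hull_area(xy[, 1], xy[, 2])
    nl <- null_area(xy[, 1], xy[, 2])
    data.frame(subject_id = d$subject_id[1], group_id = d$group_id[1],
               n_points = nrow(d), hull_area_m2 = h$area_m2,
               convex_area_m2 = h$convex_area_m2, alpha_m = h$alpha_m,
               null_radius_m = nl$radius_m, null_area_m2 = nl$area_m2,
               pct_covered = 100 * h$area_m2 / nl$area_m2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write foraging areas as GeoJSON
#'
#' Emits one FeatureCollection with, per subject, the convex-hull polygon of
#' its start points and the circular null area (64-gon) around the burrow.
#'
#' @param starts,burrows as in [area_report()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_area_geojson <- function(starts, burrows, path) {
  ring_of <- function(lon, lat) {
    lapply(c(seq_along(lon), 1L), function(i) c(lon[i], lat[i]))
  }
  feats <- list()
  for (d in split(starts, starts$subject_id)) {
    b <- burrows[burrows$group_id == d$group_id[1], , drop = FALSE]
    origin <- geo_point(b$burrow_lat[1], b$burrow_lon[1])
    xy <- local_xy(data.frame(lat_deg = d$lat_deg, lon_deg = d$lon_deg), origin)
    if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
    ch <- grDevices::chull(xy[, 1], xy[, 2])
    if (length(ch) >= 3) {
      hull_ll <- inv_local_xy(xy[ch, 1], xy[ch, 2], origin)
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(subject_id = d$subject_id[1], kind = "hull"),
        geometry = list(type = "Polygon",
                        coordinates = list(ring_of(hull_ll$lon_deg,
                                                   hull_ll$lat_deg))))
    }
    r <- max(sqrt(xy[, 1]^2 + xy[, 2]^2))
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    circ <- inv_local_xy(r * sin(th), r * cos(th), origin)
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(subject_id = d$subject_id[1], kind = "null_circle",
                        radius_m = r),
      geometry = list(type = "Polygon",
                      coordinates = list(ring_of(circ$lon_deg, circ$lat_deg))))
  }
  writeLines(jsonlite::toJSON(list(type = "FeatureCollection",
                                   features = feats),
                              auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Long-format area table for the mixed-model comparison
#'
#' @param report output of [area_report()].
#' @return data.frame with two rows per subject (`area_type` = "hull" or
#'   "null") for the paired hull-versus-null model.
#' @export
area_report_long <- function(report) {
  rbind(
    data.frame(subject_id = report$subject_id, group_id = report$group_id,
               area_type = "hull", area_m2 = report$hull_area_m2,
               stringsAsFactors = FALSE),
    data.frame(subject_id = report$subject_id, group_id = report$group_id,
               area_type = "null", area_m2 = report$null_area_m2,
               stringsAsFactors = FALSE))
}
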