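#' Coastline interpolation of station HSI scores
#'
#' Station scores are spread over a coastline polyline by a nearest-
#' neighbour rule: the polyline is cut into short pieces and each piece
#' takes the HSI class of the station nearest to its midpoint
#' (great-circle distance). Summing piece lengths per class yields the
#' length of coast in each HSI class.
#'
#' @name spatial
NULL

EARTH_RADIUS_KM <- 6371.0088

# great-circle distance in km between (lon, lat) points (WGS84 lon/lat)
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

#' Read a coastline from GeoJSON
#'
#' Accepts a `LineString` or `MultiLineString` geometry, a `Feature`
#' wrapping one, or a `FeatureCollection` whose first feature does.
#'
#' @param path GeoJSON file path.
#' @return object of class `coastline`: a list of matrices with columns
#'   `lon`, `lat` (one matrix per polyline part).
#' @export
read_coastline <- function(path) {
  if (!file.exists(path)) stop("coastline file not found: ", path)
  gj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- gj
  if (identical(gj$type, "FeatureCollection")) geom <- gj$features$geometry
  if (identical(geom$type[1], "Feature")) geom <- geom$geometry
  type <- geom$type[1]
  coords <- geom$coordinates
  parts <- switch(type,
    LineString = list(if (is.list(coords)) coords[[1]] else coords),
    MultiLineString = if (is.list(coords)) coords else list(coords),
    stop("unsupported coastline geometry type: ", type))
  parts <- lapply(parts, function(p) {
    p <- as.matrix(p)
    if (nrow(p) < 2L) stop("coastline polyline needs at least 2 vertices")
    colnames(p) <- c("lon", "lat")[seq_len(ncol(p))]
    p[, c("lon", "lat"), drop = FALSE]
  })
  structure(parts, class = "coastline")
}

#' Make a coastline object from coordinates
#'
#' @param lon,lat numeric vectors of vertex coordinates (decimal degrees).
#' @return a `coastline` object with a single polyline.
#' @export
coastline <- function(lon, lat) {
  stopifnot(length(lon) == length(lat), length(lon) >= 2L)
  structure(list(cbind(lon = lon, lat = lat)), class = "coastline")
}

#' Total length of a coastline
#'
#' @param coast a `coastline` object.
#' @return length in km (haversine, Earth radius 6371.0088 km).
#' @export
coastline_length <- function(coast) {
  sum(vapply(unclass(coast), function(p) {
    n <- nrow(p)
    sum(haversine_km(p[-n, "lon"], p[-n, "lat"], p[-1, "lon"], p[-1, "lat"]))
  }, numeric(1)))
}

#' Nearest station to a point
#'
#' Returns the station minimising the great-circle distance to the query
#' point; exact ties (to within floating-point tolerance) break towards
#' the lowest station id.
#'
#' @param lon,lat query point coordinates.
#' @param stations data.frame with columns `station_id`, `lon`, `lat`.
#' @return the `station_id` of the nearest station.
#' @export
nearest_station <- function(lon, lat, stations) {
  if (is.null(stations) || nrow(stations) == 0L)
    stop("no stations supplied")
  d <- haversine_km(lon, lat, stations$lon, stations$lat)
  tol <- max(min(d) * 1e-9, 1e-9)
  tied <- which(d <= min(d) + tol)
  ids <- stations$station_id[tied]
  ids[order(ids)][1L]
}

#' HSI class label of a score
#'
#' Scores are rounded to 2 decimals and binned into the ten standard HSI
#' classes `0.00-0.10`, `0.11-0.20`, ..., `0.81-0.90`, `0.90-1.00`
#' (contiguous on the rounded scale; the top label follows the
#' conventional class table).
#'
#' @param hsi numeric vector in \[0, 1\].
#' @return factor of class labels with all ten levels.
#' @export
classify_hsi <- function(hsi) {
  if (any(!is.finite(hsi)) || any(hsi < 0 | hsi > 1))
    stop("hsi scores must be finite and in [0, 1]")
  # half-up rounding to 2 decimals (a small epsilon counters binary
  # representation of values like 0.105, which must round up to 0.11)
  r <- floor(hsi * 100 + 0.5 + 1e-9) / 100
  # thresholds between rounded-scale bins: 0.10|0.11, 0.20|0.21, ...
  idx <- findInterval(r, seq(0.105, 0.905, by = 0.1)) + 1L
  factor(hsi_class_labels()[idx], levels = hsi_class_labels())
}

#' @rdname classify_hsi
#' @export
hsi_class_labels <- function() {
  c("0.00-0.10", "0.11-0.20", "0.21-0.30", "0.31-0.40", "0.41-0.50",
    "0.51-0.60", "0.61-0.70", "0.71-0.80", "0.81-0.90", "0.90-1.00")
}

#' Assign coastline pieces to stations
#'
#' Each polyline edge is subdivided into pieces no longer than
#' `max_seg_km` (linear interpolation in lon/lat, adequate for the short
#' pieces involved); each piece is assigned the station nearest its
#' midpoint.
#'
#' @param coast a `coastline` object.
#' @param stations data.frame with `station_id`, `lon`, `lat` and an `hsi`
#'   column (e.g. output of [hsi_pipeline()]).
#' @param max_seg_km maximum piece length in km (default 1).
#' @return data.frame with one row per piece: `part`, `segment`, `piece`,
#'   `mid_lon`, `mid_lat`, `length_km`, `station_id`, `hsi`,
#'   `class_label`.
#' @export
coastline_segments <- function(coast, stations, max_seg_km = 1) {
  stopifnot(inherits(coast, "coastline"), max_seg_km > 0)
  if (!all(c("station_id", "lon", "lat", "hsi") %in% names(stations)))
    stop("stations need columns station_id, lon, lat, hsi")
  rows <- list()
  for (ip in seq_along(coast)) {
    p <- coast[[ip]]
    n <- nrow(p)
    seg_len <- haversine_km(p[-n, "lon"], p[-n, "lat"],
                            p[-1, "lon"], p[-1, "lat"])
    for (is in seq_len(n - 1L)) {
      k <- max(1L, ceiling(seg_len[is] / max_seg_km))
      frac_mid <- (seq_len(k) - 0.5) / k
      rows[[length(rows) + 1L]] <- data.frame(
        part = ip, segment = is, piece = seq_len(k),
        mid_lon = p[is, "lon"] + frac_mid * (p[is + 1L, "lon"] - p[is, "lon"]),
        mid_lat = p[is, "lat"] + frac_mid * (p[is + 1L, "lat"] - p[is, "lat"]),
        length_km = seg_len[is] / k)
    }
  }
  out <- do.call(rbind, rows)
  out$station_id <- vapply(seq_len(nrow(out)), function(i)
    nearest_station(out$mid_lon[i], out$mid_lat[i], stations),
    stations$station_id[1L])
  out$hsi <- stations$hsi[match(out$station_id, stations$station_id)]
  out$class_label <- classify_hsi(out$hsi)
  out
}

#' Coastline length per HSI class
#'
#' Sums assigned piece lengths per HSI class and counts stations per
#' class. The class lengths conserve the total coastline length and the
#' site counts sum to the number of stations.
#'
#' @inheritParams coastline_segments
#' @return data.frame with `class_label`, `n_sites`, `length_km` for all
#'   ten classes (zeros where empty).
#' @export
coastline_class_lengths <- function(coast, stations, max_seg_km = 1) {
  seg <- coastline_segments(coast, stations, max_seg_km)
  len <- tapply(seg$length_km, seg$class_label, sum, default = 0)
  cls <- classify_hsi(stations$hsi)
  data.frame(class_label = hsi_class_labels(),
             n_sites = as.integer(table(cls)),
             length_km = as.numeric(len),
             stringsAsFactors = FALSE)
}

#' Write assigned coastline pieces as GeoJSON
#'
#' Emits a FeatureCollection of short LineString pieces with `station_id`,
#' `hsi` and `class_label` properties, for mapping in any GIS.
#'
#' @param segments output of [coastline_segments()].
#' @param coast the `coastline` the segments came from.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_class_geojson <- function(segments, coast, path) {
  feats <- lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    p <- coast[[s$part]]
    a <- p[s$segment, ]; b <- p[s$segment + 1L, ]
    k <- sum(segments$part == s$part & segments$segment == s$segment)
    f0 <- (s$piece - 1L) / k; f1 <- s$piece / k
    list(type = "Feature",
         properties = list(station_id = s$station_id, hsi = s$hsi,
                           class_label = as.character(s$class_label),
                           length_km = s$length_km),
         geometry = list(type = "LineString",
                         coordinates = list(
                           c(a["lon"] + f0 * (b["lon"] - a["lon"]),
                             a["lat"] + f0 * (b["lat"] - a["lat"])),
                           c(a["lon"] + f1 * (b["lon"] - a["lon"]),
                             a["lat"] + f1 * (b["lat"] - a["lat"])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a coastline as GeoJSON
#'
#' @param coast a `coastline` object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_coastline <- function(coast, path) {
  stopifnot(inherits(coast, "coastline"))
  if (length(coast) == 1L) {
    geom <- list(type = "LineString",
                 coordinates = apply(coast[[1L]], 1L, as.numeric,
                                     simplify = FALSE))
  } else {
    geom <- list(type = "MultiLineString",
                 coordinates = lapply(unclass(coast), function(p)
                   apply(p, 1L, as.numeric, simplify = FALSE)))
  }
  jsonlite::write_json(geom, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
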