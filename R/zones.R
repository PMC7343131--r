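#' Great-circle distance in nautical miles
#'
#' Haversine distance on a spherical earth (radius 6371 km, 1 nm = 1852 m).
#' Inputs are recycled, so one endpoint may be scalar and the other a vector.
#'
#' @param lat1,lon1 Coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 Coordinates of the second point(s), decimal degrees.
#' @return Numeric vector of distances in nautical miles.
#' @examples
#' haversine_nm(0, 0, 0, 1) # one degree of longitude at the equator
#' @export
haversine_nm <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  if (any(abs(c(lon1, lon2)) > 360, na.rm = TRUE)) {
    stop("longitude out of range", call. = FALSE)
  }
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  a <- pmin(a, 1)
  d_km <- 2 * 6371 * asin(sqrt(a))
  d_km * 1000 / 1852
}

#' Zone and closure-schedule configuration
#'
#' Defines the geometry of the analysis: the shallow features (atolls/reefs)
#' around which closures are placed, the staged closure schedule, the
#' spillover buffer added to closures to form treatment zones, and the
#' boundaries splitting the open fishing grounds into three control zones
#' (south, northwest and northeast of the island chain).
#'
#' Feature coordinates default to approximate positions of Kingman Reef,
#' Palmyra Atoll and Johnston Atoll; radii are measured from the feature
#' point (no shoreline polygons). The default schedule stages closures of
#' 3 nm (from the study start), 12 nm (2001) and 50 nm (2009) around
#' Kingman/Palmyra, and 3, 50 (2009) and 200 nm (2014) around Johnston,
#' keyed to designation dates.
#'
#' @param features Data frame with columns `name`, `lat`, `lon`.
#' @param closure_schedule Data frame with columns `feature`, `radius_nm`,
#'   `start` (Date), `end` (Date or NA for open-ended).
#' @param spillover_nm Spillover buffer in nautical miles added beyond the
#'   seaward margin of an MPA to form its treatment zone.
#' @param archipelago_boundary Two-row data frame (`lat`, `lon`) defining the
#'   line through the island chain that separates the south control zone from
#'   the northern ones.
#' @param eastern_meridian Longitude (degrees) splitting northwest from
#'   northeast control zones.
#' @param study_box Named list with `lat` and `lon` ranges of the study area.
#' @return An object of class `zone_config`.
#' @export
zone_config <- function(features = NULL,
                        closure_schedule = NULL,
                        spillover_nm = 60,
                        archipelago_boundary = NULL,
                        eastern_meridian = -150,
                        study_box = list(lat = c(0, 40), lon = c(-180, -145))) {
  if (is.null(features)) {
    features <- data.frame(
      name = c("kingman", "palmyra", "johnston"),
      lat = c(6.3833, 5.8833, 16.7286),
      lon = c(-162.4167, -162.0833, -169.5239)
    )
  }
  if (is.null(closure_schedule)) {
    closure_schedule <- data.frame(
      feature = c("johnston", "kingman", "kingman", "palmyra",
                  "johnston", "kingman", "palmyra", "johnston"),
      radius_nm = c(3, 3, 12, 12, 50, 50, 50, 200),
      start = as.Date(c("1994-03-04", "1994-03-04", "2001-01-18", "2001-01-18",
                        "2009-01-06", "2009-01-06", "2009-01-06", "2014-09-30")),
      end = as.Date(c("2009-01-05", "2001-01-17", "2009-01-05", "2009-01-05",
                      "2014-09-29", NA, NA, NA))
    )
  }
  if (is.null(archipelago_boundary)) {
    archipelago_boundary <- data.frame(
      lat = c(28.4167, 19.5429),
      lon = c(-178.3333, -155.6659)
    )
  }
  stopifnot(all(closure_schedule$radius_nm > 0), spillover_nm >= 0)
  # closure intervals must not overlap within a feature
  for (f in unique(closure_schedule$feature)) {
    sub <- closure_schedule[closure_schedule$feature == f, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) {
      ends <- sub$end[-nrow(sub)]
      if (any(is.na(ends)) || any(ends >= sub$start[-1])) {
        stop("overlapping closure intervals for feature ", f, call. = FALSE)
      }
    }
  }
  structure(
    list(
      features = features,
      closure_schedule = closure_schedule,
      spillover_nm = spillover_nm,
      archipelago_boundary = archipelago_boundary,
      eastern_meridian = eastern_meridian,
      study_box = study_box
    ),
    class = "zone_config"
  )
}

#' @export
print.zone_config <- function(x, ...) {
  cat("<zone_config>\n")
  cat("  features:", paste(x$features$name, collapse = ", "), "\n")
  cat("  closures:", nrow(x$closure_schedule), "scheduled intervals\n")
  cat("  spillover:", x$spillover_nm, "nm; eastern meridian:",
      x$eastern_meridian, "\n")
  invisible(x)
}

# latitude of the archipelago boundary at a given longitude, by linear
# interpolation (and extrapolation) between the two configured points
boundary_lat_at <- function(lon, zones) {
  b <- zones$archipelago_boundary
  b$lat[1] + (lon - b$lon[1]) * (b$lat[2] - b$lat[1]) / (b$lon[2] - b$lon[1])
}

# distance (nm) from points to each configured feature; matrix n x features
feature_distances <- function(lat, lon, zones) {
  fs <- zones$features
  out <- vapply(seq_len(nrow(fs)), function(i) {
    haversine_nm(lat, lon, fs$lat[i], fs$lon[i])
  }, numeric(length(lat)))
  out <- matrix(out, nrow = length(lat), ncol = nrow(fs))
  colnames(out) <- fs$name
  out
}

#' Assign longline sets to treatment and control zones
#'
#' Each set receives every treatment-zone label whose buffer contains it
#' (`kp50`, `kp110` around Kingman/Palmyra; `j50`, `j110`, `j200`, `j260`
#' around Johnston; the 110/260 nm buffers are MPA radius plus the spillover
#' buffer), or else exactly one control label (`south`, `northwest`,
#' `northeast`) determined by the archipelago boundary line and the eastern
#' meridian. Points exactly on a boundary go to the zone east/south of it.
#' `inside_active_closure` tests the set date against closure designation
#' dates.
#'
#' @param sets Data frame with columns `set_id`, `lat`, `lon`, `date`.
#' @param zones A [zone_config()].
#' @return Tibble with one row per set: distances to features, logical
#'   columns per treatment label, a collapsed `treatment_labels` string,
#'   `control_label` (NA inside treatment zones), and
#'   `inside_active_closure`.
#' @export
assign_zones <- function(sets, zones = zone_config()) {
  stopifnot(all(c("set_id", "lat", "lon", "date") %in% names(sets)))
  lat <- sets$lat
  lon <- sets$lon
  date <- as.Date(sets$date)
  box <- zones$study_box
  if (any(lat < box$lat[1] | lat > box$lat[2] |
          lon < box$lon[1] | lon > box$lon[2])) {
    stop("sets outside the configured study box", call. = FALSE)
  }
  d <- feature_distances(lat, lon, zones)
  d_kp <- pmin(d[, "kingman"], d[, "palmyra"])
  d_j <- d[, "johnston"]
  sp <- zones$spillover_nm
  kp50 <- d_kp <= 50
  kp110 <- d_kp <= 50 + sp
  j50 <- d_j <= 50
  j110 <- d_j <= 50 + sp
  j200 <- d_j <= 200
  j260 <- d_j <= 200 + sp
  in_treatment <- kp110 | j260
  # control side test: strictly above the interpolated archipelago line is
  # the northern side, split at the eastern meridian; ties go south/east
  lat_b <- boundary_lat_at(lon, zones)
  northern <- lat > lat_b
  control <- rep(NA_character_, length(lat))
  control[!in_treatment & !northern] <- "south"
  control[!in_treatment & northern & lon < zones$eastern_meridian] <- "northwest"
  control[!in_treatment & northern & lon >= zones$eastern_meridian] <- "northeast"

  # active closure on the set date (designation dates govern)
  cs <- zones$closure_schedule
  inside <- rep(FALSE, length(lat))
  for (i in seq_len(nrow(cs))) {
    active <- date >= cs$start[i] &
      (is.na(cs$end[i]) | date <= cs$end[i])
    inside <- inside | (active & d[, cs$feature[i]] <= cs$radius_nm[i])
  }

  lab <- cbind(kp50 = kp50, kp110 = kp110, j50 = j50,
               j110 = j110, j200 = j200, j260 = j260)
  labels_str <- apply(lab, 1, function(r) {
    paste(toupper(colnames(lab))[r], collapse = ";")
  })
  tibble::tibble(
    set_id = sets$set_id,
    dist_kp_nm = d_kp,
    dist_johnston_nm = d_j,
    kp50 = kp50, kp110 = kp110, j50 = j50,
    j110 = j110, j200 = j200, j260 = j260,
    in_treatment = in_treatment,
    treatment_labels = labels_str,
    control_label = control,
    inside_active_closure = inside
  )
}

#' Single-set zone assignment
#'
#' Convenience scalar wrapper around [assign_zones()].
#'
#' @param lat,lon Coordinates, decimal degrees.
#' @param date Set date.
#' @param zones A [zone_config()].
#' @return One-row tibble, see [assign_zones()].
#' @export
assign_zone <- function(lat, lon, date, zones = zone_config()) {
  assign_zones(
    data.frame(set_id = "p1", lat = lat, lon = lon, date = as.Date(date)),
    zones
  )
}

#' Confidentiality filter for spatial aggregates
#'
#' Government confidentiality rules require effort by at least three
#' distinct vessels within a reported spatial aggregate. Retains aggregates
#' meeting the rule.
#'
#' @param sets Data frame with columns `bin` (aggregate id) and `vessel_id`.
#' @param min_vessels Minimum number of distinct vessels (default 3).
#' @return Tibble of retained aggregates with `bin`, `n_vessels`, `n_sets`.
#' @export
filter_confidential <- function(sets, min_vessels = 3) {
  stopifnot(all(c("bin", "vessel_id") %in% names(sets)))
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(sets), .data$bin),
    n_vessels = dplyr::n_distinct(.data$vessel_id),
    n_sets = dplyr::n(),
    .groups = "drop"
  )
  agg[agg$n_vessels >= min_vessels, ]
}

# flat-top hexagon axial coordinates for points; pitch = horizontal spacing
# between column centers in degrees of longitude (plate carree)
hex_axial <- function(lon, lat, pitch = 1) {
  s <- pitch / 1.5 # hex size so that horizontal spacing = 1.5 s = pitch
  q <- (2 / 3) * lon / s
  r <- (-1 / 3 * lon + sqrt(3) / 3 * lat) / s
  # cube rounding
  x <- q
  z <- r
  y <- -x - z
  rx <- round(x); ry <- round(y); rz <- round(z)
  dx <- abs(rx - x); dy <- abs(ry - y); dz <- abs(rz - z)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  list(q = rx, r = rz, size = s)
}

#' Hexagonal binning of fishing effort
#'
#' Aggregates sets into ~1-degree flat-top hexagonal bins (plate-carree
#' projection; display product only). Bins below the display threshold are
#' flagged rather than dropped, so counts are conserved.
#'
#' @param sets Data frame with `lat`, `lon` (and optionally `vessel_id`).
#' @param pitch Horizontal center-to-center pitch in degrees (default 1).
#' @param min_sets Display threshold: bins with fewer sets are flagged
#'   `retained = FALSE` (default 50).
#' @return Tibble with hex axial indices, bin center coordinates, `n_sets`,
#'   `n_vessels` (if available) and `retained`.
#' @export
hexbin_effort <- function(sets, pitch = 1, min_sets = 50) {
  if (nrow(sets) == 0) stop("no sets to bin", call. = FALSE)
  ax <- hex_axial(sets$lon, sets$lat, pitch)
  key <- paste(ax$q, ax$r, sep = ":")
  tab <- tibble::tibble(q = ax$q, r = ax$r, key = key,
                        vessel_id = if ("vessel_id" %in% names(sets))
                          sets$vessel_id else NA)
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$q, .data$r),
    n_sets = dplyr::n(),
    n_vessels = dplyr::n_distinct(.data$vessel_id),
    .groups = "drop"
  )
  s <- ax$size
  out$center_lon <- 1.5 * s * out$q
  out$center_lat <- sqrt(3) * s * (out$r + out$q / 2)
  out$retained <- out$n_sets >= min_sets
  out
}

# points on a spherical small circle of given radius (nm) around a center
circle_points <- function(lat0, lon0, radius_nm, n = 64) {
  R_nm <- 6371 * 1000 / 1852
  delta <- radius_nm / R_nm
  rad <- pi / 180
  brg <- seq(0, 2 * pi, length.out = n + 1)
  lat1 <- lat0 * rad
  lon1 <- lon0 * rad
  lat2 <- asin(sin(lat1) * cos(delta) + cos(lat1) * sin(delta) * cos(brg))
  lon2 <- lon1 + atan2(sin(brg) * sin(delta) * cos(lat1),
                       cos(delta) - sin(lat1) * sin(lat2))
  cbind(lon = ((lon2 / rad + 540) %% 360) - 180, lat = lat2 / rad)
}

#' Export zone buffers as GeoJSON
#'
#' Writes treatment-zone circles (MPA radii and spillover margins) as a
#' GeoJSON FeatureCollection, each circle discretized at 64 vertices.
#'
#' @param zones A [zone_config()].
#' @param path Output file path.
#' @param radii Named list mapping feature name to radii (nm) to export;
#'   defaults to the closure radii plus spillover margins.
#' @return The path, invisibly.
#' @export
zones_to_geojson <- function(zones, path, radii = NULL) {
  if (is.null(radii)) {
    cs <- zones$closure_schedule
    radii <- lapply(split(cs$radius_nm, cs$feature), function(r) {
      sort(unique(c(r, max(r) + zones$spillover_nm)))
    })
  }
  feats <- list()
  for (f in names(radii)) {
    row <- zones$features[zones$features$name == f, ]
    for (r in radii[[f]]) {
      ring <- circle_points(row$lat, row$lon, r)
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        properties = list(feature = f, radius_nm = r),
        geometry = list(
          type = "Polygon",
          coordinates = list(lapply(seq_len(nrow(ring)), function(i)
            c(ring[i, "lon"], ring[i, "lat"])))
        )
      )
    }
  }
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
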