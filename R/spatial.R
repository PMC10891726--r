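#' Thiessen (Voronoi) polygon area weights for monitoring stations
#'
#' Computes the Voronoi diagram of the station points, bounded by a padded
#' envelope of the region so outer cells are finite, clips every cell
#' against every county polygon, and returns the fraction of each county's
#' area falling in each station's cell. Cells cross county lines: a county
#' without a station of its own is covered by the cells of neighbouring
#' stations. Per county the weights sum to one.
#'
#' Longitude/latitude inputs are projected with a sinusoidal (equal-area)
#' projection about the region's central meridian before any area is
#' measured; area weighting demands an equal-area treatment. Coordinates
#' already in planar map units are used as-is.
#'
#' @param stations data.frame with columns station_id, lon, lat (as from
#'   [read_stations_csv()] or [generate_stations()]).
#' @param region A `region_polygons` object of county boundaries.
#' @param crs `"auto"` (treat as lon/lat when all coordinates fit in
#'   [-180,180] x [-90,90]), `"lonlat"`, or `"planar"`.
#' @param pad Envelope padding as a fraction of the bounding-box diagonal
#'   (default 0.25).
#' @return data.frame of class `station_weights` with columns station_id,
#'   county, area (map units^2), weight; attributes `cells` (clipped
#'   polygons, original coordinate space) for export.
#' @export
thiessen_weights <- function(stations, region, crs = c("auto", "lonlat", "planar"),
                             pad = 0.25) {
  crs <- match.arg(crs)
  stopifnot(inherits(region, "region_polygons"),
            all(c("station_id", "lon", "lat") %in% names(stations)))
  if (nrow(stations) < 1L) stop("at least one station is required")
  lon0 <- NA_real_
  all_xy <- do.call(rbind, lapply(region, function(f) do.call(rbind, f$parts)))
  if (crs == "auto") {
    pts <- rbind(all_xy, cbind(stations$lon, stations$lat))
    crs <- if (all(abs(pts[, 1]) <= 180) && all(abs(pts[, 2]) <= 90)) "lonlat" else "planar"
  }
  if (crs == "lonlat") {
    lon0 <- mean(range(all_xy[, 1]))
    proj <- function(m) project_lonlat(m[, 1], m[, 2], lon0)
  } else {
    proj <- identity
  }
  sxy <- proj(cbind(stations$lon, stations$lat))
  counties <- lapply(region, function(f) lapply(f$parts, proj))
  names(counties) <- region_names(region)
  cxy <- do.call(rbind, unlist(counties, recursive = FALSE))
  pts <- rbind(cxy, sxy)
  dg <- sqrt(diff(range(pts[, 1]))^2 + diff(range(pts[, 2]))^2)
  if (dg <= 0) stop("degenerate region: zero-extent bounding box")
  bbox <- c(min(pts[, 1]) - pad * dg, max(pts[, 1]) + pad * dg,
            min(pts[, 2]) - pad * dg, max(pts[, 2]) + pad * dg)
  dup <- duplicated(paste(sxy[, 1], sxy[, 2]))
  if (any(dup)) {
    i <- which(dup)[1]
    j <- which(sxy[, 1] == sxy[i, 1] & sxy[, 2] == sxy[i, 2])[1]
    stop("coincident stations: ", stations$station_id[j], " and ",
         stations$station_id[i])
  }
  cells <- voronoi_cells(sxy[, 1], sxy[, 2], bbox)
  county_area <- vapply(counties, function(parts) {
    sum(vapply(parts, function(r) abs(ring_area_signed(r)), numeric(1)))
  }, numeric(1))
  rows <- list()
  pieces <- list()
  for (i in seq_along(cells)) {
    for (cn in names(counties)) {
      pa <- 0
      shapes <- list()
      for (part in counties[[cn]]) {
        inter <- clip_to_convex(part, cells[[i]])
        if (nrow(inter) >= 3L) {
          a <- abs(ring_area_signed(inter))
          if (a > 1e-12 * county_area[cn]) {
            pa <- pa + a
            shapes <- c(shapes, list(inter))
          }
        }
      }
      if (pa > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          station_id = stations$station_id[i], county = cn,
          area = pa, weight = pa / county_area[cn],
          stringsAsFactors = FALSE)
        pieces[[length(pieces) + 1L]] <- shapes
      }
    }
  }
  w <- do.call(rbind, rows)
  # clipping leaves per-county sums within float noise of 1; check, then
  # renormalise so downstream conservation is exact
  sums <- tapply(w$weight, w$county, sum)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("county coverage defect: weights sum to ",
         paste(sprintf("%s=%.8f", names(sums), sums)[abs(sums - 1) > 1e-6],
               collapse = ", "))
  }
  w$weight <- as.numeric(w$weight / sums[w$county])
  rownames(w) <- NULL
  if (!is.na(lon0)) {
    pieces <- lapply(pieces, function(shapes) {
      lapply(shapes, function(m) unproject_lonlat(m[, 1], m[, 2], lon0))
    })
  }
  attr(w, "cells") <- pieces
  class(w) <- c("station_weights", "data.frame")
  w
}

#' Write station Thiessen cells to GeoJSON
#'
#' One feature per (station, county) clipped cell, with properties
#' station_id, county, weight.
#'
#' @param weights A `station_weights` object from [thiessen_weights()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights_geojson <- function(weights, path) {
  pieces <- attr(weights, "cells")
  if (is.null(pieces)) stop("weights carry no cell geometry")
  reg <- structure(lapply(seq_len(nrow(weights)), function(i) {
    list(name = paste(weights$station_id[i], weights$county[i], sep = "/"),
         parts = pieces[[i]])
  }), class = "region_polygons")
  write_region_geojson(reg, path,
                       properties = data.frame(station_id = weights$station_id,
                                               weight = weights$weight))
  invisible(path)
}

#' Allocate county-level deaths to stations by Thiessen weight
#'
#' Each station receives, per stratum (year, age group, cause), the sum
#' over counties of weight x county deaths. Values stay fractional; total
#' allocated deaths equal total input deaths.
#'
#' @param weights A `station_weights` data.frame ([thiessen_weights()]).
#' @param deaths A deaths table with an `area` column naming counties (as
#'   from [read_deaths_csv()]).
#' @return data.frame like `deaths` but with `station_id` replacing
#'   `area`, deaths summed over the contributing counties.
#' @export
allocate_deaths <- function(weights, deaths) {
  stopifnot(all(c("station_id", "county", "weight") %in% names(weights)),
            "area" %in% names(deaths), "deaths" %in% names(deaths))
  uncovered <- setdiff(unique(deaths$area), unique(weights$county))
  if (length(uncovered)) {
    stop("no station cell covers count(y/ies): ",
         paste(uncovered, collapse = ", "))
  }
  m <- merge(deaths, weights[c("station_id", "county", "weight")],
             by.x = "area", by.y = "county")
  m$deaths <- m$deaths * m$weight
  strata <- setdiff(names(deaths), c("area", "deaths"))
  key_cols <- c("station_id", strata)
  # string keys keep NA strata (the open-ended age_width) instead of the
  # NA-dropping behaviour of aggregate()
  key <- do.call(paste, c(m[key_cols], sep = "\r"))
  sums <- tapply(m$deaths, key, sum)
  out <- m[!duplicated(key), key_cols, drop = FALSE]
  out$deaths <- as.numeric(sums[do.call(paste, c(out[key_cols], sep = "\r"))])
  out <- out[do.call(order, out[key_cols]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
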