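#' Read region/county boundary polygons from GeoJSON
#'
#' Parses a GeoJSON FeatureCollection of Polygon or MultiPolygon features
#' into the package's planar polygon container. Ring orientation is
#' repaired (outer rings counter-clockwise), the redundant closing vertex
#' is dropped, self-intersecting rings and zero-area polygons are rejected,
#' and interior rings (holes) are not supported: administrative county
#' boundaries are hole-free in practice.
#'
#' @param path Path to a GeoJSON file.
#' @param name_property Feature property holding the polygon name; by
#'   default the first of `county`, `name`, `NAME` that is present.
#' @return An object of class `region_polygons`: a list of features, each
#'   with `$name` and `$parts` (list of 2-column vertex matrices).
#' @export
read_region_geojson <- function(path, name_property = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(g$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  feats <- lapply(seq_along(g$features), function(i) {
    f <- g$features[[i]]
    props <- f$properties
    key <- name_property
    if (is.null(key)) key <- intersect(c("county", "name", "NAME"), names(props))[1]
    if (is.null(key) || is.na(key) || is.null(props[[key]])) {
      stop("feature ", i, " has no name property (looked for ",
           if (is.null(name_property)) "county/name/NAME" else name_property, ")")
    }
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("feature ", i, ": unsupported geometry type ", geom$type))
    parts <- lapply(polys, function(rings) {
      if (length(rings) > 1L) {
        stop("feature ", i, " ('", props[[key]],
             "'): interior rings (holes) are not supported")
      }
      ring <- do.call(rbind, lapply(rings[[1]], function(p) c(p[[1]], p[[2]])))
      parse_ring(ring, sprintf("feature %d ('%s')", i, props[[key]]))
    })
    list(name = as.character(props[[key]]), parts = parts)
  })
  structure(feats, class = "region_polygons")
}

# validate one ring: drop closing vertex, require simple non-degenerate
# geometry, orient counter-clockwise
parse_ring <- function(ring, what) {
  if (nrow(ring) >= 2L && all(ring[1, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  ring <- ring[!duplicated(ring), , drop = FALSE]
  if (nrow(ring) < 3L) stop(what, ": degenerate ring (< 3 distinct vertices)")
  if (ring_self_intersects(ring)) stop(what, ": self-intersecting ring")
  a <- ring_area_signed(ring)
  if (abs(a) <= 0) stop(what, ": zero-area ring")
  if (a < 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  ring
}

#' Construct region polygons from vertex matrices
#'
#' @param parts Named list: one 2-column vertex matrix (or list of matrices
#'   for multi-part polygons) per named area.
#' @return A `region_polygons` object.
#' @export
region_polygons <- function(parts) {
  stopifnot(is.list(parts), !is.null(names(parts)), all(nzchar(names(parts))))
  feats <- lapply(names(parts), function(nm) {
    p <- parts[[nm]]
    if (is.matrix(p)) p <- list(p)
    list(name = nm,
         parts = lapply(p, parse_ring, what = sprintf("polygon '%s'", nm)))
  })
  structure(feats, class = "region_polygons")
}

#' @export
print.region_polygons <- function(x, ...) {
  cat(sprintf("<region_polygons> %d feature(s): %s\n", length(x),
              paste(region_names(x), collapse = ", ")))
  invisible(x)
}

#' Names of the polygons in a region
#' @param region A `region_polygons` object.
#' @return Character vector of feature names.
#' @export
region_names <- function(region) {
  vapply(region, `[[`, character(1), "name")
}

#' Polygon areas in squared map units
#' @param region A `region_polygons` object.
#' @return Named numeric vector of areas (per feature, summed over parts).
#' @export
region_areas <- function(region) {
  a <- vapply(region, function(f) {
    sum(vapply(f$parts, function(r) abs(ring_area_signed(r)), numeric(1)))
  }, numeric(1))
  names(a) <- region_names(region)
  a
}

#' Write polygons to GeoJSON
#'
#' @param region A `region_polygons` object.
#' @param path Output path.
#' @param properties Optional data.frame of extra per-feature properties
#'   (one row per feature, in the region's order).
#' @return `path`, invisibly.
#' @export
write_region_geojson <- function(region, path, properties = NULL) {
  feats <- lapply(seq_along(region), function(i) {
    f <- region[[i]]
    coords <- lapply(f$parts, function(ring) {
      closed <- rbind(ring, ring[1, , drop = FALSE])
      list(lapply(seq_len(nrow(closed)), function(k) c(closed[k, 1], closed[k, 2])))
    })
    props <- list(county = f$name)
    if (!is.null(properties)) props <- c(props, as.list(properties[i, , drop = FALSE]))
    if (length(coords) == 1L) {
      geom <- list(type = "Polygon", coordinates = coords[[1]])
    } else {
      geom <- list(type = "MultiPolygon", coordinates = coords)
    }
    list(type = "Feature", properties = props, geometry = geom)
  })
  obj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

# TRUE for points inside any part of the named feature
region_contains <- function(region, name, px, py) {
  f <- region[[match(name, region_names(region))]]
  inside <- rep(FALSE, length(px))
  for (ring in f$parts) inside <- inside | point_in_ring(px, py, ring)
  inside
}
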