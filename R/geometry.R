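# Lightweight planar geometry for station-scale spatial allocation.
# Polygons are 2-column matrices of vertices (no repeated closing vertex).
# The problem sizes here are tiny (tens of stations, a handful of county
# polygons), so simple O(n^2) algorithms are used throughout.

EARTH_RADIUS_KM <- 6371.0088

# signed shoelace area; positive for counter-clockwise rings
ring_area_signed <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

# even-odd rule, vectorised over query points
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# clip polygon `poly` to the half-plane a*x + b*y <= c (Sutherland-Hodgman
# step; exact for convex subjects, area-correct for simple subjects)
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  f <- a * poly[, 1] + b * poly[, 2] - c
  outx <- numeric(2 * n); outy <- numeric(2 * n); k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    fi <- f[i]; fj <- f[j]
    if (fi <= 0) { k <- k + 1L; outx[k] <- poly[i, 1]; outy[k] <- poly[i, 2] }
    if ((fi <= 0) != (fj <= 0)) {
      t <- fi / (fi - fj)
      k <- k + 1L
      outx[k] <- poly[i, 1] + t * (poly[j, 1] - poly[i, 1])
      outy[k] <- poly[i, 2] + t * (poly[j, 2] - poly[i, 2])
    }
  }
  cbind(outx[seq_len(k)], outy[seq_len(k)])
}

# intersection of a simple polygon `subject` with a convex polygon `clip`
clip_to_convex <- function(subject, clip) {
  if (ring_area_signed(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    # keep the left side of edge clip[i] -> clip[j] (CCW interior)
    dx <- clip[j, 1] - clip[i, 1]; dy <- clip[j, 2] - clip[i, 2]
    # left test cross >= 0  <=>  dy*x - dx*y <= dy*xi - dx*yi
    out <- clip_halfplane(out, dy, -dx, dy * clip[i, 1] - dx * clip[i, 2])
    if (nrow(out) == 0L) break
  }
  out
}

# bounded Voronoi diagram by half-plane intersection: cell i is the bounding
# rectangle intersected with the "closer to site i than to site j" half-plane
# for every other site j
voronoi_cells <- function(x, y, bbox) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  key <- paste(signif(x, 12), signif(y, 12))
  if (anyDuplicated(key)) {
    d <- which(key == key[duplicated(key)][1])
    stop("coincident stations at positions ", paste(d, collapse = " and "))
  }
  rect <- cbind(c(bbox[1], bbox[2], bbox[2], bbox[1]),
                c(bbox[3], bbox[3], bbox[4], bbox[4]))
  n <- length(x)
  lapply(seq_len(n), function(i) {
    cell <- rect
    for (j in seq_len(n)) {
      if (j == i) next
      a <- 2 * (x[j] - x[i]); b <- 2 * (y[j] - y[i])
      c <- x[j]^2 + y[j]^2 - x[i]^2 - y[i]^2
      cell <- clip_halfplane(cell, a, b, c)
      if (nrow(cell) == 0L) break
    }
    cell
  })
}

# proper-intersection test for two segments (shared endpoints excluded)
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  if (n < 4L) return(FALSE)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      j2 <- if (j == n) 1L else j + 1L
      if (segments_cross(ring[i, ], ring[i + 1L, ], ring[j, ], ring[j2, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# sinusoidal (equal-area) projection about a central meridian; km units
project_lonlat <- function(lon, lat, lon0) {
  k <- EARTH_RADIUS_KM * pi / 180
  cbind(k * (lon - lon0) * cos(lat * pi / 180), k * lat)
}

unproject_lonlat <- function(x, y, lon0) {
  k <- EARTH_RADIUS_KM * pi / 180
  lat <- y / k
  cbind(lon0 + x / (k * cos(lat * pi / 180)), lat)
}
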