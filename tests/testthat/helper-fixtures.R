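# fixtures built in code: tiny regions, series constructors, and the
# independent oracles used to cross-check the implementation

# scratch directory under the session tempdir (cleaned up by R itself)
withr_local_tempdir <- function() {
  d <- tempfile("pmhia")
  dir.create(d)
  d
}

unit_square_region <- function(name = "A") {
  p <- list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  names(p) <- name
  region_polygons(p)
}

# rectangle [0,2]x[0,1] split into two unit-square counties
two_county_region <- function() {
  region_polygons(list(
    west = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
    east = cbind(c(1, 2, 2, 1), c(0, 0, 1, 1))))
}

make_series <- function(station_id, pollutant, dates, values) {
  pm_daily(data.frame(station_id = station_id, date = as.Date(dates),
                      pollutant = pollutant, value = values,
                      stringsAsFactors = FALSE))
}

# a small fast generator configuration for structural tests
small_cfg <- function(...) {
  synthetic_config(n_stations = 4, n_years = 1, seed = 7,
                   pm25_station_fraction = 0.5, ...)
}

# independent ordinary-least-squares oracle via the normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  coef <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% coef
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = coef[1], slope = coef[2], r_squared = 1 - ss_res / ss_tot)
}

# independent abridged-life-table oracle: plain scalar recursion written
# directly from the demographic textbook formulas
lt_oracle <- function(age_start, width, P, D, radix = 1e5, a = 0.5) {
  n <- length(age_start)
  M <- D / P
  q <- l <- d <- L <- numeric(n)
  l[1] <- radix
  for (i in 1:n) {
    if (i < n) {
      m <- width[i]
      q[i] <- min(1, m * M[i] / (1 + m * (1 - a) * M[i]))
    } else {
      q[i] <- 1
    }
    d[i] <- l[i] * q[i]
    if (i < n) {
      L[i] <- width[i] * (l[i] - (1 - a) * d[i])
      l[i + 1] <- l[i] - d[i]
    } else {
      L[i] <- l[i] / M[i]
    }
  }
  Tt <- numeric(n)
  for (i in n:1) Tt[i] <- L[i] + if (i < n) Tt[i + 1] else 0
  list(q = q, l = l, d = d, L = L, T = Tt, e = Tt / l)
}

# Monte-Carlo nearest-station weight oracle on one county polygon
mc_weight_oracle <- function(sx, sy, ring, n_points, seed = 1) {
  set.seed(seed)
  # rejection-sample uniform points in the ring's bounding box
  px <- py <- numeric(0)
  while (length(px) < n_points) {
    m <- n_points
    qx <- runif(m, min(ring[, 1]), max(ring[, 1]))
    qy <- runif(m, min(ring[, 2]), max(ring[, 2]))
    keep <- pmhia:::point_in_ring(qx, qy, ring)
    px <- c(px, qx[keep]); py <- c(py, qy[keep])
  }
  px <- px[seq_len(n_points)]; py <- py[seq_len(n_points)]
  nearest <- max.col(-outer(px, sx, function(a, b) (a - b)^2) -
                       outer(py, sy, function(a, b) (a - b)^2))
  tabulate(nearest, nbins = length(sx)) / n_points
}
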