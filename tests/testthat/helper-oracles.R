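# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Classic Snyder (USGS Professional Paper 1395) transverse Mercator series —
# an independent UTM implementation, accurate to ~1 mm, used to cross-check
# the package's Krueger-series projection.
snyder_utm <- function(lat, lon, zone) {
  a <- 6378137; f <- 1 / 298.257223563
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2); k0 <- 0.9996
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  lam0 <- (zone * 6 - 183) * pi / 180
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- (lam - lam0) * cos(phi)
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
              (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
              (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
              (35 * e2^3 / 3072) * sin(6 * phi))
  easting <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
                         (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) +
    500000
  northing <- k0 * (M + N * tan(phi) *
                      (A^2 / 2 + (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
                         (61 - 58 * T + T^2 + 600 * C - 330 * ep2) *
                         A^6 / 720))
  list(easting = easting, northing = northing)
}

# Exhaustive rest-coverage oracle: mark every timepoint lying in ANY window
# of duration >= min_dur whose points fit in a disc of the given area
# (max pairwise distance <= diameter); O(n^2), tiny n only.
brute_rest_intervals <- function(t, pos, area_m2 = 100, min_dur = 120) {
  n <- length(t)
  diam <- 2 * sqrt(area_m2 / pi)
  covered <- logical(n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (t[j] - t[i] < min_dur) next
      if (max(dist(pos[i:j, , drop = FALSE])) <= diam) covered[i:j] <- TRUE
    }
  }
  if (!any(covered)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  data.frame(start = t[starts[r$values]], end = t[ends[r$values]])
}

# Monte-Carlo hull-clipped Voronoi areas: rejection-sample the hull's
# bounding box, keep points inside the hull, assign to nearest member.
mc_voronoi <- function(pts, n_samples = 200000) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  inside_hull <- function(q) {
    n <- nrow(hull)
    sgn <- vapply(seq_len(n), function(i) {
      j <- if (i == n) 1L else i + 1L
      (hull[j, 1] - hull[i, 1]) * (q[2] - hull[i, 2]) -
        (hull[j, 2] - hull[i, 2]) * (q[1] - hull[i, 1])
    }, 0)
    all(sgn >= -1e-12) || all(sgn <= 1e-12)
  }
  bb <- apply(hull, 2, range)
  qs <- cbind(runif(n_samples, bb[1, 1], bb[2, 1]),
              runif(n_samples, bb[1, 2], bb[2, 2]))
  keep <- apply(qs, 1, inside_hull)
  qs <- qs[keep, , drop = FALSE]
  box_area <- diff(bb[, 1]) * diff(bb[, 2])
  hull_area_mc <- box_area * mean(keep)
  d2 <- vapply(seq_len(nrow(pts)), function(k)
    (qs[, 1] - pts[k, 1])^2 + (qs[, 2] - pts[k, 2])^2,
    numeric(nrow(qs)))
  nearest <- max.col(-d2)
  cells <- tabulate(nearest, nbins = nrow(pts)) / nrow(qs) * hull_area_mc
  list(hull_area = hull_area_mc, cells = cells)
}

# Wasserstein-1 via the quantile-integral definition on a fine grid.
w1_quantile <- function(a, b, k = 20000) {
  u <- (seq_len(k) - 0.5) / k
  mean(abs(quantile(a, u, type = 1, names = FALSE) -
             quantile(b, u, type = 1, names = FALSE)))
}
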