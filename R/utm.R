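#' Transverse Mercator (UTM, WGS84) forward and inverse projection
#'
#' Projects geographic coordinates to UTM easting/northing in meters using the
#' Krueger series formulation (6th order in the third flattening), accurate to
#' well below a millimeter anywhere inside a zone. Used internally by
#' [to_utm()]; exposed because a planar projection is a reusable primitive.
#'
#' @param lat,lon numeric vectors of geographic coordinates in degrees.
#' @param zone UTM zone number (1-60). If `NULL`, derived from the mean
#'   longitude of the input.
#' @param hemisphere `"N"` or `"S"`; if `NULL`, derived from the mean latitude.
#' @return `utm_project`: a list with numeric vectors `easting`, `northing`
#'   (meters) and scalars `zone`, `hemisphere`.
#' @examples
#' p <- utm_project(0, 3)          # central meridian of zone 31
#' p$easting                       # 500000
#' q <- utm_unproject(p$easting, p$northing, p$zone, p$hemisphere)
#' @export
utm_project <- function(lat, lon, zone = NULL, hemisphere = NULL) {
  stopifnot(length(lat) == length(lon))
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("non-finite coordinates")
  if (any(lat < -90 | lat > 90)) stop("latitude out of [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop("longitude out of [-180, 180]")
  if (is.null(zone)) zone <- utm_zone_of(mean(lon))
  if (is.null(hemisphere)) hemisphere <- if (mean(lat) < 0) "S" else "N"
  hemisphere <- match.arg(hemisphere, c("N", "S"))

  k <- .kruger_constants()
  lon0 <- (zone * 6 - 183) * pi / 180
  phi <- lat * pi / 180
  ld <- lon * pi / 180 - lon0
  # wrap to (-pi, pi] so zone overrides near the antimeridian behave
  ld <- atan2(sin(ld), cos(ld))

  tau <- tan(phi)
  sigma <- sinh(k$e * atanh(k$e * tau / sqrt(1 + tau^2)))
  taup <- tau * sqrt(1 + sigma^2) - sigma * sqrt(1 + tau^2)  # tan(conformal lat)
  xi_p <- atan2(taup, cos(ld))
  eta_p <- asinh(sin(ld) / sqrt(taup^2 + cos(ld)^2))
  xi <- xi_p
  eta <- eta_p
  for (j in 1:6) {
    xi <- xi + k$alpha[j] * sin(2 * j * xi_p) * cosh(2 * j * eta_p)
    eta <- eta + k$alpha[j] * cos(2 * j * xi_p) * sinh(2 * j * eta_p)
  }
  easting <- 500000 + k$k0 * k$A * eta
  northing <- k$k0 * k$A * xi + if (hemisphere == "S") 1e7 else 0
  list(easting = easting, northing = northing, zone = zone,
       hemisphere = hemisphere)
}

#' @rdname utm_project
#' @param easting,northing numeric vectors in meters.
#' @export
utm_unproject <- function(easting, northing, zone, hemisphere = "N") {
  hemisphere <- match.arg(hemisphere, c("N", "S"))
  k <- .kruger_constants()
  lon0 <- (zone * 6 - 183) * pi / 180
  xi <- (northing - if (hemisphere == "S") 1e7 else 0) / (k$k0 * k$A)
  eta <- (easting - 500000) / (k$k0 * k$A)
  xi_p <- xi
  eta_p <- eta
  for (j in 1:6) {
    xi_p <- xi_p - k$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    eta_p <- eta_p - k$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  taup <- sin(xi_p) / sqrt(sinh(eta_p)^2 + cos(xi_p)^2)
  ld <- atan2(sinh(eta_p), cos(xi_p))
  # invert the conformal-latitude map by Newton iteration on tau
  tau <- taup / (1 - k$e^2)
  for (it in 1:6) {
    sigma <- sinh(k$e * atanh(k$e * tau / sqrt(1 + tau^2)))
    taup_i <- tau * sqrt(1 + sigma^2) - sigma * sqrt(1 + tau^2)
    dtau <- (taup - taup_i) * (1 + (1 - k$e^2) * tau^2) /
      ((1 - k$e^2) * sqrt((1 + taup_i^2) * (1 + tau^2)))
    tau <- tau + dtau
    if (all(abs(dtau) < 1e-15)) break
  }
  list(lat = atan(tau) * 180 / pi, lon = (ld + lon0) * 180 / pi)
}

#' @rdname utm_project
#' @export
utm_zone_of <- function(lon) {
  z <- floor((lon + 180) / 6) + 1
  as.integer(pmin(pmax(z, 1), 60))
}

# WGS84 Krueger series constants, precomputed once per call (cheap).
.kruger_constants <- function() {
  a <- 6378137
  f <- 1 / 298.257223563
  n <- f / (2 - f)
  A <- a / (1 + n) * (1 + n^2 / 4 + n^4 / 64 + n^6 / 256)
  alpha <- c(
    n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16 + 41 * n^4 / 180 - 127 * n^5 / 288 +
      7891 * n^6 / 37800,
    13 * n^2 / 48 - 3 * n^3 / 5 + 557 * n^4 / 1440 + 281 * n^5 / 630 -
      1983433 * n^6 / 1935360,
    61 * n^3 / 240 - 103 * n^4 / 140 + 15061 * n^5 / 26880 +
      167603 * n^6 / 181440,
    49561 * n^4 / 161280 - 179 * n^5 / 168 + 6601661 * n^6 / 7257600,
    34729 * n^5 / 80640 - 3418889 * n^6 / 1995840,
    212378941 * n^6 / 319334400)
  beta <- c(
    n / 2 - 2 * n^2 / 3 + 37 * n^3 / 96 - n^4 / 360 - 81 * n^5 / 512 +
      96199 * n^6 / 604800,
    n^2 / 48 + n^3 / 15 - 437 * n^4 / 1440 + 46 * n^5 / 105 -
      1118711 * n^6 / 3870720,
    17 * n^3 / 480 - 37 * n^4 / 840 - 209 * n^5 / 4480 + 5569 * n^6 / 90720,
    4397 * n^4 / 161280 - 11 * n^5 / 504 - 830251 * n^6 / 7257600,
    4583 * n^5 / 161280 - 108847 * n^6 / 3991680,
    20648693 * n^6 / 638668800)
  list(a = a, f = f, n = n, A = A, alpha = alpha, beta = beta,
       e = sqrt(f * (2 - f)), k0 = 0.9996)
}
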