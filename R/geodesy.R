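#' WGS84 <-> UTM conversion
#'
#' Transverse-Mercator projection on the WGS84 ellipsoid using the Kruger
#' series in the third flattening (forward), and Newton iteration on the
#' conformal-latitude equation for the inverse, so forward/inverse round
#' trips close to well below a millimeter.  Scale factor 0.9996, false
#' easting 500 km, false northing 10,000 km in the southern hemisphere.
#'
#' @name geodesy
NULL

.wgs84 <- local({
  a <- 6378137.0
  f <- 1 / 298.257223563
  n <- f / (2 - f)
  n2 <- n^2; n3 <- n^3; n4 <- n^4; n5 <- n^5; n6 <- n^6
  list(
    a = a, f = f, n = n,
    e = sqrt(f * (2 - f)),
    A = a / (1 + n) * (1 + n2 / 4 + n4 / 64 + n6 / 256),
    alpha = c(
      n / 2 - 2 / 3 * n2 + 5 / 16 * n3 + 41 / 180 * n4 - 127 / 288 * n5 + 7891 / 37800 * n6,
      13 / 48 * n2 - 3 / 5 * n3 + 557 / 1440 * n4 + 281 / 630 * n5 - 1983433 / 1935360 * n6,
      61 / 240 * n3 - 103 / 140 * n4 + 15061 / 26880 * n5 + 167603 / 181440 * n6,
      49561 / 161280 * n4 - 179 / 168 * n5 + 6601661 / 7257600 * n6,
      34729 / 80640 * n5 - 3418889 / 1995840 * n6,
      212378941 / 319334400 * n6),
    beta = c(
      n / 2 - 2 / 3 * n2 + 37 / 96 * n3 - 1 / 360 * n4 - 81 / 512 * n5 + 96199 / 604800 * n6,
      1 / 48 * n2 + 1 / 15 * n3 - 437 / 1440 * n4 + 46 / 105 * n5 - 1118711 / 3870720 * n6,
      17 / 480 * n3 - 37 / 840 * n4 - 209 / 4480 * n5 + 5569 / 90720 * n6,
      4397 / 161280 * n4 - 11 / 504 * n5 - 830251 / 7257600 * n6,
      4583 / 161280 * n5 - 108847 / 3991680 * n6,
      20648693 / 638668800 * n6)
  )
})

.k0 <- 0.9996

#' UTM zone for a longitude
#' @param lon longitude in degrees
#' @return integer zone 1..60
#' @export
utm_zone <- function(lon) {
  z <- floor((lon + 180) / 6) + 1
  as.integer(pmin(pmax(z, 1), 60))
}

#' Convert geographic coordinates to UTM
#'
#' @param lat,lon degrees (WGS84); `lat` must lie in (-80, 84)
#' @param zone UTM zone; defaults to the zone containing `lon`
#' @param hemisphere `"north"` or `"south"`
#' @return named numeric `c(easting, northing)` in meters
#' @export
latlon_to_utm <- function(lat, lon, zone = utm_zone(lon),
                          hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  if (lat <= -80 || lat >= 84)
    stop("latitude ", lat, " outside UTM validity (-80, 84)")
  g <- .wgs84
  phi <- lat * pi / 180
  lam0 <- (zone * 6 - 183) * pi / 180
  dlam <- lon * pi / 180 - lam0
  s <- sin(phi)
  t <- sinh(atanh(s) - (2 * sqrt(g$n) / (1 + g$n)) *
              atanh((2 * sqrt(g$n) / (1 + g$n)) * s))
  xi_p <- atan2(t, cos(dlam))
  eta_p <- asinh(sin(dlam) / sqrt(t^2 + cos(dlam)^2))
  j <- 1:6
  xi <- xi_p + sum(g$alpha * sin(2 * j * xi_p) * cosh(2 * j * eta_p))
  eta <- eta_p + sum(g$alpha * cos(2 * j * xi_p) * sinh(2 * j * eta_p))
  E <- 500000 + .k0 * g$A * eta
  N <- .k0 * g$A * xi + if (hemisphere == "south") 10000000 else 0
  c(easting = E, northing = N)
}

#' Convert UTM coordinates to geographic
#'
#' @param easting,northing meters
#' @param zone UTM zone
#' @param hemisphere `"north"` or `"south"`
#' @return named numeric `c(lat, lon)` in degrees
#' @export
utm_to_latlon <- function(easting, northing, zone,
                          hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  g <- .wgs84
  if (hemisphere == "south") northing <- northing - 10000000
  xi <- northing / (.k0 * g$A)
  eta <- (easting - 500000) / (.k0 * g$A)
  j <- 1:6
  xi_p <- xi - sum(g$beta * sin(2 * j * xi) * cosh(2 * j * eta))
  eta_p <- eta - sum(g$beta * cos(2 * j * xi) * sinh(2 * j * eta))
  tau_p <- sin(xi_p) / sqrt(sinh(eta_p)^2 + cos(xi_p)^2)
  # Newton solve tau' = tau sqrt(1+sigma^2) - sigma sqrt(1+tau^2)
  e <- g$e
  tau <- tau_p
  for (iter in 1:10) {
    sigma <- sinh(e * atanh(e * tau / sqrt(1 + tau^2)))
    f_tau <- tau * sqrt(1 + sigma^2) - sigma * sqrt(1 + tau^2) - tau_p
    df <- (sqrt((1 + sigma^2) * (1 + tau^2)) - sigma * tau) *
      (1 - e^2) * sqrt(1 + tau^2) / (1 + (1 - e^2) * tau^2)
    step <- f_tau / df
    tau <- tau - step
    if (abs(step) < 1e-15) break
  }
  phi <- atan(tau)
  lam0 <- (zone * 6 - 183) * pi / 180
  dlam <- atan2(sinh(eta_p), cos(xi_p))
  c(lat = phi * 180 / pi, lon = (lam0 + dlam) * 180 / pi)
}

#' Register a (lat, lon, altitude-ft) reading into UTM meters
#'
#' The vehicle GPS logs latitude/longitude degrees and altitude in feet;
#' every other sensor reports UTM meters, so this is the vehicle vertex's
#' restriction map into the common frame.
#'
#' @param lat,lon degrees
#' @param alt_ft altitude in feet (1 ft = 0.3048 m)
#' @param zone UTM zone (fix it for a study area spanning a zone boundary)
#' @param hemisphere `"north"` or `"south"`
#' @return numeric `c(easting, northing, elev_m)`
#' @export
latlonft_to_utm <- function(lat, lon, alt_ft, zone = utm_zone(lon),
                            hemisphere = "north") {
  en <- latlon_to_utm(lat, lon, zone = zone, hemisphere = hemisphere)
  c(en[["easting"]], en[["northing"]], alt_ft * 0.3048)
}
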