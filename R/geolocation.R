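# WGS84 ellipsoid constants used by the local transverse-Mercator frame.
.wgs84 <- list(a = 6378137, f = 1 / 298.257223563)

#' Geodetic configuration for reticle distance estimation
#'
#' Bundles the constants needed to convert a reticle drop below the horizon
#' into a radial distance: the earth radius, an atmospheric refraction
#' coefficient (handled as an effective earth radius \code{R/(1 - k)}), and
#' the angular spacing of one binocular reticle.
#'
#' The reticle spacing of 7x50 marine binoculars is an instrument property;
#' the default (0.00497 rad per reticle) is typical for that class and must
#' be overridden if the instrument is calibrated differently.
#'
#' @param earth_radius Earth radius in metres (default 6371000).
#' @param refraction_coefficient Dimensionless refraction coefficient in
#'   [0, 0.5); 0.13 is standard marine-survey practice.
#' @param reticle_spacing Radians subtended by one reticle (default 0.00497).
#' @return An object of class \code{geodetic_config}.
#' @export
geodetic_config <- function(earth_radius = 6371000,
                            refraction_coefficient = 0.13,
                            reticle_spacing = 0.00497) {
  stopifnot(earth_radius > 6e6,
            refraction_coefficient >= 0, refraction_coefficient < 0.5,
            reticle_spacing > 0)
  structure(list(earth_radius = earth_radius,
                 refraction_coefficient = refraction_coefficient,
                 reticle_spacing = reticle_spacing),
            class = "geodetic_config")
}

effective_radius <- function(cfg) {
  cfg$earth_radius / (1 - cfg$refraction_coefficient)
}

#' Observation platform
#'
#' @param id Platform label.
#' @param lon,lat Position in degrees WGS84.
#' @param height_at_LW Eye height above the sea surface at low water (m).
#' @param sector_start,sector_end Sector bounds, degrees true in [0, 360);
#'   the sector runs clockwise from start to end.
#' @param max_radius Optional named list mapping condition keys to maximum
#'   viewing radii (m).
#' @return An object of class \code{platform}.
#' @export
platform <- function(id, lon, lat, height_at_LW,
                     sector_start, sector_end, max_radius = NULL) {
  stopifnot(height_at_LW > 0,
            sector_start >= 0, sector_start < 360,
            sector_end >= 0, sector_end < 360)
  width <- (sector_end - sector_start) %% 360
  if (width == 0) width <- 360
  structure(list(id = as.character(id), lon = lon, lat = lat,
                 height_at_LW = height_at_LW,
                 sector_start = sector_start, sector_end = sector_end,
                 sector_width = width, max_radius = max_radius),
            class = "platform")
}

#' @export
print.platform <- function(x, ...) {
  cat(sprintf("<platform %s> %.5f E %.5f N, eye %.1f m at LW, sector %g-%g deg\n",
              x$id, x$lon, x$lat, x$height_at_LW,
              x$sector_start, x$sector_end))
  invisible(x)
}

#' Read a platform set from a YAML configuration file
#'
#' The file holds a list of blocks with fields \code{id, lon, lat,
#' height_at_LW, sector_start, sector_end}.
#'
#' @param path Path to a YAML file.
#' @return A named list of \code{platform} objects.
#' @export
read_platforms <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(p)
    platform(p$id, p$lon, p$lat, p$height_at_LW, p$sector_start, p$sector_end))
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write a platform set to YAML
#' @param platforms Named list of \code{platform} objects.
#' @param path Output path.
#' @export
write_platforms <- function(platforms, path) {
  yaml::write_yaml(lapply(unname(platforms), function(p)
    list(id = p$id, lon = p$lon, lat = p$lat,
         height_at_LW = p$height_at_LW,
         sector_start = p$sector_start, sector_end = p$sector_end)), path)
}

# Meridian arc length from the equator (Snyder's series, WGS84).
.meridian_arc <- function(phi, a, e2) {
  a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
       (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
       (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
       (35 * e2^3 / 3072) * sin(6 * phi))
}

#' Project geographic coordinates to the local survey frame
#'
#' Transverse Mercator on WGS84 with central meridian -4.785 and latitude of
#' origin 52.75543 (scale factor 1 on the central meridian), so that the
#' survey origin maps to (0, 0) and coordinates are metres east/north.
#' Intended for a domain of a few tens of kilometres around the origin.
#'
#' @param lon,lat Numeric vectors, degrees.
#' @param lon0,lat0 Projection origin, degrees.
#' @return A data frame with columns \code{x}, \code{y} (metres).
#' @seealso [local_to_lonlat()] for the inverse.
#' @export
project_to_local <- function(lon, lat, lon0 = -4.785, lat0 = 52.75543) {
  if (any(abs(lon - lon0) >= 1) || any(abs(lat - lat0) >= 1))
    stop("coordinates outside the local projection domain (within 1 degree of origin)")
  a <- .wgs84$a; f <- .wgs84$f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  phi <- lat * pi / 180; lam <- lon * pi / 180
  phi0 <- lat0 * pi / 180; lam0 <- lon0 * pi / 180
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- (lam - lam0) * cos(phi)
  M <- .meridian_arc(phi, a, e2)
  M0 <- .meridian_arc(phi0, a, e2)
  x <- N * (A + (1 - T + C) * A^3 / 6 +
              (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120)
  y <- (M - M0) + N * tan(phi) *
    (A^2 / 2 + (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
       (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720)
  data.frame(x = x, y = y)
}

#' Inverse of the local transverse-Mercator projection
#'
#' @param x,y Metres in the local frame.
#' @inheritParams project_to_local
#' @return A data frame with columns \code{lon}, \code{lat} (degrees).
#' @export
local_to_lonlat <- function(x, y, lon0 = -4.785, lat0 = 52.75543) {
  a <- .wgs84$a; f <- .wgs84$f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  phi0 <- lat0 * pi / 180
  M <- .meridian_arc(phi0, a, e2) + y
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  N1 <- a / sqrt(1 - e2 * sin(phi1)^2)
  R1 <- a * (1 - e2) / (1 - e2 * sin(phi1)^2)^1.5
  T1 <- tan(phi1)^2
  C1 <- ep2 * cos(phi1)^2
  D <- x / N1
  phi <- phi1 - (N1 * tan(phi1) / R1) *
    (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
       (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lam <- lon0 * pi / 180 +
    (D - (1 + 2 * T1 + C1) * D^3 / 6 +
       (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) * D^5 / 120) /
    cos(phi1)
  data.frame(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Tide-corrected observer height
#'
#' The platform eye heights are referenced to low water; a tidal height above
#' that datum lowers the observer relative to the instantaneous sea surface.
#'
#' @param height_at_LW Eye height above the sea surface at low water (m).
#' @param tidal_height_above_LW Tidal height above the low-water datum (m),
#'   expected within [0, 6].
#' @return Corrected height (m), \code{height_at_LW - tidal_height_above_LW}.
#' @export
corrected_platform_height <- function(height_at_LW, tidal_height_above_LW) {
  if (any(tidal_height_above_LW < 0 | tidal_height_above_LW > 6))
    stop("tidal_height_above_LW outside the plausible [0, 6] m range")
  h <- height_at_LW - tidal_height_above_LW
  if (any(h <= 0))
    stop("corrected observer height is not positive; check the height datum")
  h
}

# Depression angle below the observer's local horizontal of a surface point
# at central angle theta on a sphere of radius R, seen from height h.
.depression_at <- function(theta, h, R) {
  dx <- R * sin(theta)
  dy <- R * cos(theta) - (R + h)
  atan2(-dy, dx)
}

# Dip of the visible horizon below horizontal for an observer at height h.
.horizon_dip <- function(h, R) acos(R / (R + h))

#' Convert a reticle reading to a radial distance
#'
#' An observer at height \code{h} sees the horizon at a dip angle below
#' horizontal; each reticle adds a further fixed angular drop.  The line of
#' sight is intersected with a refraction-corrected sphere of effective
#' radius \code{R/(1 - k)} and the distance returned is the arc length along
#' the sea surface.  Zero reticles returns the horizon distance.
#'
#' @param observer_height Tide-corrected eye height (m), > 0.
#' @param reticles Reticle reading (non-negative; typically multiples of 0.5).
#' @param cfg A [geodetic_config()].
#' @return Distance in metres (vectorised over both arguments).
#' @export
reticle_to_distance <- function(observer_height, reticles,
                                cfg = geodetic_config()) {
  stopifnot(all(observer_height > 0), all(reticles >= 0))
  R <- effective_radius(cfg)
  n <- max(length(observer_height), length(reticles))
  h <- rep_len(observer_height, n)
  r <- rep_len(reticles, n)
  dip <- .horizon_dip(h, R)
  beta <- dip + r * cfg$reticle_spacing
  if (any(beta > pi / 2))
    stop("sight line drops past vertical; no intersection with the sea surface")
  # closed-form ray-sphere intersection: perpendicular distance from the
  # earth's centre to the sight line is (R+h) cos(beta)
  p <- (R + h) * cos(beta)
  if (any(p > R))
    stop("sight line above the horizon; no intersection with the sea surface")
  t_near <- (R + h) * sin(beta) - sqrt(R^2 - p^2)
  # central angle of the near intersection via the law of cosines
  costheta <- ((R + h)^2 + R^2 - t_near^2) / (2 * R * (R + h))
  theta <- acos(pmin(1, pmax(-1, costheta)))
  R * theta
}

#' Reticle reading corresponding to a distance
#'
#' Inverse of [reticle_to_distance()]: the (continuous) reticle drop at which
#' a surface point at arc distance \code{distance} appears below the horizon.
#'
#' @param observer_height Eye height (m).
#' @param distance Arc distance along the sea surface (m); must not exceed
#'   the horizon distance.
#' @param cfg A [geodetic_config()].
#' @return Continuous reticle values (quantize externally if needed).
#' @export
distance_to_reticle <- function(observer_height, distance,
                                cfg = geodetic_config()) {
  R <- effective_radius(cfg)
  n <- max(length(observer_height), length(distance))
  h <- rep_len(observer_height, n)
  d <- rep_len(distance, n)
  theta <- d / R
  beta <- .depression_at(theta, h, R)
  r <- (beta - .horizon_dip(h, R)) / cfg$reticle_spacing
  if (any(r < -1e-9))
    stop("distance beyond the horizon for this observer height")
  pmax(r, 0)
}

#' Displace a platform position along a bearing
#'
#' Positions are computed with plane trigonometry in the local metric frame;
#' at survey scale grid north and true north coincide to well within the
#' reticle rounding error.
#'
#' @param platform A [platform()] object.
#' @param bearing Degrees true in [0, 360).
#' @param distance Metres, > 0.
#' @param flag_outside If TRUE (default) an attribute \code{outside_sector}
#'   marks bearings outside the platform sector; points are never dropped.
#' @param sector_tolerance Degrees of slack allowed on the sector bounds.
#' @return A data frame with columns \code{x}, \code{y} and logical column
#'   \code{outside_sector}.
#' @export
sighting_position <- function(platform, bearing, distance,
                              flag_outside = TRUE, sector_tolerance = 2) {
  stopifnot(all(distance > 0), all(bearing >= 0), all(bearing < 360))
  origin <- project_to_local(platform$lon, platform$lat)
  b <- bearing * pi / 180
  out <- data.frame(x = origin$x + distance * sin(b),
                    y = origin$y + distance * cos(b))
  if (flag_outside) {
    rel <- (bearing - platform$sector_start) %% 360
    out$outside_sector <- rel > platform$sector_width + sector_tolerance &
      rel < 360 - sector_tolerance
  }
  out
}

#' Geolocate a sighting log
#'
#' End-to-end position estimation for a set of sightings: joins each
#' sighting to its scan, corrects the platform height for the tidal height
#' at scan time, converts the reticle reading to a radial distance and
#' displaces the platform position along the recorded bearing.
#'
#' @param sightings Data frame with scan_id, bearing, reticles (and any
#'   other columns, carried through).
#' @param scans Data frame with scan_id, site, start_time.
#' @param platforms Named list of [platform()]s keyed by site.
#' @param tide A [tide_table()] (NULL for no tidal height correction).
#' @param cfg A [geodetic_config()].
#' @return \code{sightings} with added columns x, y, distance_m,
#'   observer_height_m and outside_sector.
#' @export
geolocate_sightings <- function(sightings, scans, platforms, tide = NULL,
                                cfg = geodetic_config()) {
  m <- match(sightings$scan_id, scans$scan_id)
  if (any(is.na(m))) stop("sighting references an unknown scan_id")
  site <- scans$site[m]
  pf <- platforms[site]
  if (any(vapply(pf, is.null, TRUE)))
    stop("no platform definition for site(s): ",
         paste(setdiff(unique(site), names(platforms)), collapse = ", "))
  h_lw <- vapply(pf, `[[`, 0, "height_at_LW")
  th <- if (is.null(tide)) 0 else
    pmin(pmax(tide_height_at(tide, as.POSIXct(scans$start_time[m], tz = "UTC")), 0), 6)
  h <- corrected_platform_height(h_lw, th)
  d <- reticle_to_distance(h, sightings$reticles, cfg)
  out <- sightings
  out$observer_height_m <- h
  out$distance_m <- d
  xy <- t(vapply(seq_along(m), function(i) {
    p <- sighting_position(pf[[i]], sightings$bearing[i], d[i])
    c(p$x, p$y, p$outside_sector)
  }, c(0, 0, 0)))
  out$x <- xy[, 1]; out$y <- xy[, 2]
  out$outside_sector <- xy[, 3] > 0
  out
}

#' Spacing error between consecutive half-reticle steps
#'
#' Tabulates, for one observer height, the distance of every half-reticle
#' step from the horizon downward and the gap to the next step: the distance
#' resolution available to an observer rounding to the nearest half reticle.
#'
#' @param observer_height Eye height (m).
#' @param cfg A [geodetic_config()].
#' @param max_reticles Deepest reticle value tabulated (default 20).
#' @return A data frame with columns \code{reticles}, \code{distance_m} and
#'   \code{gap_to_next_m} (gap below each step; NA on the last row).
#' @export
half_reticle_spacing_error <- function(observer_height,
                                       cfg = geodetic_config(),
                                       max_reticles = 20) {
  stopifnot(observer_height > 0)
  r <- seq(0, max_reticles, by = 0.5)
  d <- reticle_to_distance(observer_height, r, cfg)
  data.frame(reticles = r, distance_m = d,
             gap_to_next_m = c(-diff(d), NA))
}
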