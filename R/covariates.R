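# Tidal, temporal and hydrographic covariate engineering.  All timestamps
# are POSIXct in UTC; tidal state is hours relative to the nearest high
# water (period 12.42 h) and the lunar index is days relative to the nearest
# neap date (period 14.77 d), both signed and treated as circular downstream.

TIDAL_PERIOD_H <- 12.42
LUNAR_PERIOD_D <- 14.77

#' Construct a tide table
#'
#' @param hw_time POSIXct vector of high-water instants, strictly increasing
#'   with spacing close to 12.42 h.
#' @param hw_height High-water heights (m above the low-water datum), > 0.
#' @param neap_dates Optional Date vector of neap days; derived from the
#'   heights with [derive_neap_dates()] when omitted.
#' @return An object of class \code{tide_table}.
#' @export
tide_table <- function(hw_time, hw_height, neap_dates = NULL) {
  stopifnot(inherits(hw_time, "POSIXct"), length(hw_time) == length(hw_height),
            all(hw_height > 0))
  dt <- diff(as.numeric(hw_time)) / 3600
  if (any(dt <= 0)) stop("high-water times must be strictly increasing")
  if (any(abs(dt - TIDAL_PERIOD_H) > 1.5))
    warning("high-water spacing departs from the semidiurnal period by > 1.5 h")
  tt <- structure(list(hw_time = hw_time, hw_height = hw_height),
                  class = "tide_table")
  tt$neap_dates <- if (is.null(neap_dates)) derive_neap_dates(tt) else neap_dates
  tt
}

#' @export
print.tide_table <- function(x, ...) {
  cat(sprintf("<tide_table> %d high waters, %s to %s, %d neap dates\n",
              length(x$hw_time), format(min(x$hw_time)), format(max(x$hw_time)),
              length(x$neap_dates)))
  invisible(x)
}

#' Derive neap dates from a tide table
#'
#' The daily mean high-water height tracks the spring-neap modulation of the
#' tidal range; neap days are its local minima, with one neap retained per
#' half spring-neap cycle (minima closer than 10 days are merged).
#'
#' @param tide A [tide_table()].
#' @return A Date vector of neap days.
#' @export
derive_neap_dates <- function(tide) {
  d <- as.Date(tide$hw_time, tz = "UTC")
  daily <- tapply(tide$hw_height, d, mean)
  days <- as.Date(names(daily))
  h <- as.numeric(daily)
  n <- length(h)
  if (n < 3) return(days[which.min(h)])
  is_min <- c(FALSE, h[2:(n - 1)] <= h[1:(n - 2)] & h[2:(n - 1)] <= h[3:n], FALSE)
  cand <- days[is_min]
  if (length(cand) == 0) return(days[which.min(h)])
  keep <- cand[1]
  for (i in seq_along(cand)[-1])
    if (as.numeric(cand[i] - keep[length(keep)]) >= 10)
      keep <- c(keep, cand[i])
  keep
}

#' Read/write a tide table as CSV
#'
#' Columns \code{time} (ISO-8601, UTC) and \code{height}.
#' @param path CSV path.
#' @return A [tide_table()].
#' @export
read_tide_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tide_table(as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
             df$height)
}

#' @rdname read_tide_table
#' @param tide A [tide_table()].
#' @export
write_tide_table <- function(tide, path) {
  utils::write.csv(data.frame(
    time = format(tide$hw_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    height = tide$hw_height), path, row.names = FALSE)
}

# Signed offset of t to the nearest event time, hours.
.signed_hours_to_nearest <- function(t, events) {
  tn <- as.numeric(t); en <- sort(as.numeric(events))
  idx <- findInterval(tn, en)
  lo <- pmax(idx, 1); hi <- pmin(idx + 1, length(en))
  d_lo <- tn - en[lo]; d_hi <- tn - en[hi]
  ifelse(abs(d_lo) <= abs(d_hi), d_lo, d_hi) / 3600
}

#' Temporal and tidal covariates for timestamps
#'
#' @param t POSIXct vector within the span of the tide table.
#' @param tide A [tide_table()].
#' @return Data frame with \code{tidal_state} (signed hours to the nearest
#'   high water, within about half a tidal period), \code{lunar_cycle}
#'   (signed days to the nearest neap date, negative before), plus
#'   \code{day_of_year}, \code{hour_of_day} (decimal) and \code{year}.
#' @export
temporal_covariates <- function(t, tide) {
  stopifnot(inherits(t, "POSIXct"))
  span <- range(as.numeric(tide$hw_time))
  tn <- as.numeric(t)
  if (any(tn < span[1] - TIDAL_PERIOD_H * 3600 / 2 |
          tn > span[2] + TIDAL_PERIOD_H * 3600 / 2))
    stop("timestamp outside the span of the tide table")
  ts <- .signed_hours_to_nearest(t, tide$hw_time)
  neap_noon <- if (inherits(tide$neap_dates, "POSIXct")) tide$neap_dates
  else as.POSIXct(paste(tide$neap_dates, "12:00:00"), tz = "UTC")
  lc <- .signed_hours_to_nearest(t, neap_noon) / 24
  lt <- as.POSIXlt(t, tz = "UTC")
  data.frame(tidal_state = ts, lunar_cycle = lc,
             day_of_year = lt$yday + 1,
             hour_of_day = lt$hour + lt$min / 60 + lt$sec / 3600,
             year = lt$year + 1900)
}

#' Current snapshot at one tidal state
#'
#' @param tidal_state Hours relative to high water, in [-6.5, 6.5].
#' @param u,v East and north velocity component [raster_grid()]s (m/s) on a
#'   shared geometry (typically 300 m cells).
#' @return An object of class \code{current_snapshot}.
#' @export
current_snapshot <- function(tidal_state, u, v) {
  stopifnot(abs(tidal_state) <= 6.5, identical(dim(u$values), dim(v$values)))
  spd <- sqrt(u$values^2 + v$values^2)
  if (any(spd >= 5, na.rm = TRUE))
    stop("current speeds of 5 m/s or more are not plausible here")
  structure(list(tidal_state = tidal_state, u = u, v = v),
            class = "current_snapshot")
}

#' Decompose a current into east/north components
#'
#' Directions are degrees clockwise from true north in the oceanographic
#' "toward" convention (the direction the water moves to).
#'
#' @param speed Speed (m/s), >= 0.
#' @param direction_toward Direction of flow, degrees true.
#' @return List with numeric \code{u_east} and \code{v_north}.
#' @export
decompose_current <- function(speed, direction_toward) {
  stopifnot(all(speed >= 0, na.rm = TRUE))
  rad <- direction_toward * pi / 180
  list(u_east = speed * sin(rad), v_north = speed * cos(rad))
}

#' Spatial variation in current speed
#'
#' Neighbourhood standard deviation of each velocity component, combined by
#' the Pythagorean rule \code{sqrt(SD_x^2 + SD_y^2)}.
#'
#' @param u,v Component [raster_grid()]s.
#' @param k_neighbors Passed to [neighborhood_sd()].
#' @return A [raster_grid()].
#' @export
spatial_sd_speed <- function(u, v, k_neighbors = 5) {
  stopifnot(identical(dim(u$values), dim(v$values)))
  sdx <- neighborhood_sd(u, k_neighbors)$values
  sdy <- neighborhood_sd(v, k_neighbors)$values
  raster_grid(sqrt(sdx^2 + sdy^2), u$xll, u$yll, u$cell_size, u$nodata)
}

#' Tidal stratification parameter
#'
#' \code{log10(h / U^3)} with the current amplitude floored to avoid the
#' singularity at slack water: low values indicate tidally mixed water,
#' values near 2.75 mark frontal boundaries, high values stratified water.
#'
#' @param h Depth (m), > 0; vector or matrix.
#' @param U Tidal current amplitude (m/s).
#' @param floor_U Minimum current speed used (default 0.01 m/s).
#' @return \code{log10(h / max(U, floor_U)^3)}, same shape as the inputs.
#' @export
tidal_stratification <- function(h, U, floor_U = 0.01) {
  if (any(h <= 0, na.rm = TRUE)) stop("depth must be positive")
  log10(h / pmax(U, floor_U)^3)
}

#' Mean stratification surface
#'
#' Stratification computed from the mean current speed over a full tidal
#' cycle of snapshots, resampled onto the depth grid.
#'
#' @param depth Depth [raster_grid()].
#' @param snapshots List of [current_snapshot()]s spanning the cycle.
#' @param floor_U Passed to [tidal_stratification()].
#' @return A [raster_grid()] of \code{log10(h / Ubar^3)}.
#' @export
mean_stratification <- function(depth, snapshots, floor_U = 0.01) {
  stopifnot(length(snapshots) >= 2)
  speeds <- lapply(snapshots, function(s) sqrt(s$u$values^2 + s$v$values^2))
  ubar <- Reduce(`+`, speeds) / length(speeds)
  ug <- raster_grid(ubar, snapshots[[1]]$u$xll, snapshots[[1]]$u$yll,
                    snapshots[[1]]$u$cell_size)
  ubar50 <- resample_to(ug, depth)
  vals <- tidal_stratification(depth$values, ubar50$values, floor_U)
  raster_grid(vals, depth$xll, depth$yll, depth$cell_size, depth$nodata)
}

#' Classify a stratification value
#'
#' Bins of the \code{log10(h/U^3)} parameter: below 2.3 tidally mixed,
#' 2.3-2.75 switching between mixed and stratified, 2.75 the frontal
#' boundary, 2.75-3.5 seasonally stratified, above 3.5 strongly stratified.
#'
#' @param value Numeric vector of stratification values.
#' @return Factor with levels mixed, switching, frontal_boundary,
#'   stratified, strongly_stratified.
#' @export
stratification_regime <- function(value) {
  lv <- c("mixed", "switching", "frontal_boundary", "stratified",
          "strongly_stratified")
  out <- ifelse(value < 2.3, "mixed",
         ifelse(value < 2.75, "switching",
         ifelse(value == 2.75, "frontal_boundary",
         ifelse(value <= 3.5, "stratified", "strongly_stratified"))))
  factor(out, levels = lv)
}

#' Interpolate current fields to an arbitrary tidal state
#'
#' Linear interpolation of the u and v component grids between the two
#' snapshots bracketing the requested tidal state; states outside the
#' snapshot range are clamped with a warning.
#'
#' @param snapshots List of [current_snapshot()]s.
#' @param tidal_state Hours relative to high water.
#' @return A [current_snapshot()] at the requested state.
#' @export
interpolate_current <- function(snapshots, tidal_state) {
  states <- vapply(snapshots, `[[`, 0, "tidal_state")
  o <- order(states); states <- states[o]; snapshots <- snapshots[o]
  if (tidal_state < states[1] || tidal_state > states[length(states)]) {
    warning("tidal state outside snapshot range; clamping")
    tidal_state <- min(max(tidal_state, states[1]), states[length(states)])
  }
  i <- findInterval(tidal_state, states, rightmost.closed = TRUE)
  i <- min(max(i, 1), length(states) - 1)
  if (length(states) == 1) return(snapshots[[1]])
  w <- (tidal_state - states[i]) / (states[i + 1] - states[i])
  mix <- function(f) {
    a <- snapshots[[i]][[f]]; b <- snapshots[[i + 1]][[f]]
    raster_grid((1 - w) * a$values + w * b$values, a$xll, a$yll, a$cell_size,
                a$nodata)
  }
  current_snapshot(tidal_state, mix("u"), mix("v"))
}

#' Bundle the environmental surfaces used for covariate sampling
#'
#' Precomputes the derived terrain surfaces (slope, aspect, SD of slope),
#' the per-snapshot spatial SD of current speed, and the mean-stratification
#' surface, so that repeated point sampling is cheap.
#'
#' @param depth Depth [raster_grid()] (50 m cells).
#' @param snapshots List of [current_snapshot()]s over the tidal cycle.
#' @param tide A [tide_table()].
#' @param k_neighbors Neighbourhood size for the SD surfaces.
#' @param floor_U Current floor for stratification.
#' @return An object of class \code{env_bundle}.
#' @export
environment_bundle <- function(depth, snapshots, tide, k_neighbors = 5,
                               floor_U = 0.01) {
  states <- vapply(snapshots, `[[`, 0, "tidal_state")
  o <- order(states)
  snapshots <- snapshots[o]
  structure(list(
    depth = depth,
    slope = terrain_slope(depth),
    aspect = terrain_aspect(depth),
    sd_slope = neighborhood_sd(terrain_slope(depth), k_neighbors),
    snapshots = snapshots,
    states = states[o],
    sd_speed = lapply(snapshots, function(s)
      spatial_sd_speed(s$u, s$v, k_neighbors)),
    mean_strat = mean_stratification(depth, snapshots, floor_U),
    tide = tide, floor_U = floor_U), class = "env_bundle")
}

#' @export
print.env_bundle <- function(x, ...) {
  cat(sprintf("<env_bundle> depth %d x %d @ %g m; %d current snapshots; tide %s - %s\n",
              nrow(x$depth$values), ncol(x$depth$values), x$depth$cell_size,
              length(x$snapshots), format(min(x$tide$hw_time), "%Y-%m-%d"),
              format(max(x$tide$hw_time), "%Y-%m-%d")))
  invisible(x)
}

#' Sample the full covariate vector at points in space-time
#'
#' Raster surfaces are sampled bilinearly; temporal covariates come from the
#' tide table; the current field is interpolated between the snapshots
#' bracketing each record's tidal state (the SD-of-speed surface uses the
#' nearest snapshot, consistent with its half-hourly resolution).  Records
#' whose spatial covariates hit missing data are flagged via the
#' \code{missing_env} column so callers can exclude and count them.
#'
#' @param x,y Point coordinates in the local frame (m).
#' @param t POSIXct timestamps, same length (or length 1, recycled).
#' @param env An [environment_bundle()].
#' @return Data frame: one row per point with depth, slope, sd_slope, aspect,
#'   current_speed, current_direction, sd_current_speed, tidal_stratification,
#'   mean_stratification, the temporal covariates, x, y, and a
#'   \code{missing_env} flag.
#' @export
sample_covariates <- function(x, y, t, env) {
  n <- length(x)
  t <- rep_len(t, n)
  tc <- temporal_covariates(t, env$tide)
  out <- data.frame(x = x, y = y,
                    depth = sample_raster(env$depth, x, y),
                    slope = sample_raster(env$slope, x, y),
                    sd_slope = sample_raster(env$sd_slope, x, y),
                    aspect = sample_raster(env$aspect, x, y))
  # group records by rounded tidal state so each distinct field is
  # interpolated once
  uv_u <- uv_v <- sds <- rep(NA_real_, n)
  key <- round(tc$tidal_state, 2)
  for (k in unique(key)) {
    sel <- key == k
    snap <- suppressWarnings(interpolate_current(env$snapshots, k))
    uv_u[sel] <- sample_raster(snap$u, x[sel], y[sel])
    uv_v[sel] <- sample_raster(snap$v, x[sel], y[sel])
    nearest <- which.min(abs(env$states - k))
    sds[sel] <- sample_raster(env$sd_speed[[nearest]], x[sel], y[sel])
  }
  out$current_speed <- sqrt(uv_u^2 + uv_v^2)
  out$current_direction <- (atan2(uv_u, uv_v) * 180 / pi) %% 360
  out$sd_current_speed <- sds
  out$tidal_stratification <- ifelse(
    !is.na(out$depth) & out$depth > 0 & !is.na(out$current_speed),
    log10(out$depth / pmax(out$current_speed, env$floor_U)^3), NA_real_)
  out$mean_stratification <- sample_raster(env$mean_strat, x, y)
  out <- cbind(out, tc)
  spatial <- c("depth", "slope", "sd_slope", "current_speed",
               "sd_current_speed", "tidal_stratification",
               "mean_stratification")
  out$missing_env <- rowSums(is.na(out[spatial])) > 0
  out
}
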