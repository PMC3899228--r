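# Independent oracles and small fixture builders shared across tests.

# Ray-sphere oracle for reticle distances, independent of the package's
# closed-form path: parameterise the target by central angle and solve the
# depression-angle equation numerically.
oracle_reticle_distance <- function(h, r, R = 6371000, k = 0.13,
                                    spacing = 0.00497) {
  Reff <- R / (1 - k)
  depression <- function(theta) {
    dx <- Reff * sin(theta)
    dy <- Reff * cos(theta) - (Reff + h)
    atan2(-dy, dx)
  }
  dip <- acos(Reff / (Reff + h))
  target <- dip + r * spacing
  theta_t <- acos(Reff / (Reff + h))
  sol <- stats::uniroot(function(th) depression(th) - target,
                        c(1e-12, theta_t * (1 - 1e-9)), tol = 1e-15)
  Reff * sol$root
}

# A platform sitting exactly at the projection origin.
origin_platform <- function(height = 20, start = 0, end = 359.999) {
  platform("T", -4.785, 52.75543, height, start, end)
}

# Distances whose empirical cdf follows a two-segment detection profile:
# constant sighting rate to r0, then rate declining to frac at r1.
two_segment_distances <- function(n, r0 = 1500, r1 = 3000, rate2 = 0.2) {
  # piecewise-linear cdf: slope 1 on [0, r0], slope rate2 on [r0, r1]
  total <- r0 + rate2 * (r1 - r0)
  p_break <- r0 / total
  p <- (seq_len(n) - 0.5) / n
  ifelse(p <= p_break, p * total, r0 + (p * total - r0) / rate2)
}

# Synthetic harmonic tide table with exact neap spacing (POSIXct neaps).
harmonic_tide <- function(days = 40, t0 = as.POSIXct("2005-07-01 00:00:00",
                                                     tz = "UTC")) {
  n <- ceiling(days * 24 / 12.42)
  hw <- t0 + (seq_len(n) - 1) * 12.42 * 3600
  phase <- as.numeric(hw - t0, units = "days") / 14.77
  amp <- 3.2 + 1.2 * cos(2 * pi * phase)
  neaps <- t0 + (14.77 / 2 + (0:2) * 14.77) * 86400
  tide_table(hw, amp, neap_dates = neaps)
}

# Small constant-depth environment bundle over [-L, L]^2.
toy_env <- function(depth_value = 20, L = 3000, cell = 100,
                    current_speed = 1, tide = harmonic_tide()) {
  n <- 2 * L / cell
  depth <- raster_grid(matrix(depth_value, n, n), -L, -L, cell)
  uv <- decompose_current(current_speed, 315)
  snaps <- lapply(seq(-6, 6, by = 3), function(ts)
    current_snapshot(ts,
                     raster_grid(matrix(uv$u_east, n, n), -L, -L, cell),
                     raster_grid(matrix(uv$v_north, n, n), -L, -L, cell)))
  environment_bundle(depth, snaps, tide)
}

# Hand-rolled use/availability records with a single binary covariate and
# equal availability mass per stratum (closed-form IPP coefficient log 3).
two_stratum_records <- function(n1 = 30, n0 = 10, n_avail = 100, W = 1000) {
  pres <- data.frame(response = 1L,
                     xbin = rep(c(1, 0), c(n1, n0)),
                     day_id = rep(c("d1", "d2"), length.out = n1 + n0))
  avail <- data.frame(response = 0L,
                      xbin = rep(c(1, 0), each = n_avail),
                      day_id = rep(c("d1", "d2"), length.out = 2 * n_avail))
  rec <- rbind(pres, avail)
  rec$case_weight <- ifelse(rec$response == 1, 1, W)
  rec
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "shorewatch", mustWork = TRUE)
}
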