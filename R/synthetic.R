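# Synthetic shore-based surveys with known truth: a tidal island domain
# (semidiurnal rectilinear currents with spring-neap modulation, an island
# with a shallow gully to its east), four elevated platforms with sector
# viewsheds, a seeded effort schedule, and a ground-truth inhomogeneous
# Poisson sighting process thinned by a sea-state-dependent detection
# function.  Every generated object is readable by the analysis modules.

#' Define a synthetic study scenario
#'
#' Defaults describe a desk-scale study: a 10 x 10 km domain around a
#' 2.6 x 1 km island, four platforms at 17/17/38/60 m, 30 survey days of
#' 10-minute scans, spring-neap modulated semidiurnal tides with currents up
#' to 3 m/s, and a sighting process with about 800 expected detections whose
#' log-intensity combines a linear depth effect and a cyclic tidal-state
#' effect.
#'
#' @param seed Integer seed; fixed seed gives identical output.
#' @param days Number of survey days (>= 15 so the schedule spans a neap).
#' @param start First survey day (UTC date string).
#' @param extent_m Square domain side (m).
#' @param cell_size Depth-grid cell size (m, default 50).
#' @param target_presences Expected number of detected sightings; the
#'   process intercept is calibrated to reach it (ignored when
#'   \code{intercept} is given).
#' @param intercept Optional fixed log-intensity intercept (per m^2 per
#'   scan).
#' @param beta_depth Linear depth effect (per metre, about a 20 m centre).
#' @param tidal_amplitude,tidal_peak Amplitude (log scale) and peak (hours
#'   relative to HW) of the cyclic tidal-state effect.
#' @param inflection_radii Named vector of detection inflection radii (m)
#'   per sea state 0-4; detection is certain inside, declining linearly to
#'   zero at twice the radius.
#' @param resight_rate Probability that a detected animal is logged twice
#'   within its scan (exercises the de-duplication rule).
#' @param decline Shape of the detection decline beyond the inflection
#'   radius: \code{"linear_distance"} (default; linear in distance, zero at
#'   twice the radius), \code{"linear_area"} (linear in surveyed area, zero
#'   at twice the radius) or \code{"step"} (a constant 0.4 out to twice the
#'   radius, then zero; the regime in which a broken-stick accumulation
#'   analysis is exactly consistent).
#' @param hw_amp_mean,hw_amp_spring Semidiurnal high-water amplitude and its
#'   spring-neap modulation (m above the low-water datum).
#' @return Object of class \code{scenario}.
#' @export
make_scenario <- function(seed = 1, days = 30, start = "2005-07-01",
                          extent_m = 10000, cell_size = 50,
                          target_presences = 800, intercept = NULL,
                          beta_depth = 0.06,
                          tidal_amplitude = 0.6, tidal_peak = -3,
                          inflection_radii = c(`0` = 2500, `1` = 2000,
                                               `2` = 1400, `3` = 900,
                                               `4` = 600),
                          resight_rate = 0.05,
                          hw_amp_mean = 3.2, hw_amp_spring = 1.2,
                          scans_per_day = 48,
                          decline = c("linear_distance", "linear_area",
                                      "step")) {
  decline <- match.arg(decline)
  stopifnot(days >= 15, extent_m >= 4000)
  # local frame centred on the projection origin: the island sits at (0, 0)
  cx <- 0; cy <- 0
  platforms_local <- data.frame(
    id = c("A", "B", "C", "D"),
    x = c(cx - 250, cx - 650, cx - 400, cx + 700),
    y = c(cy - 480, cy - 420, cy + 480, cy + 420),
    height_at_LW = c(17, 17, 38, 60),
    sector_start = c(95, 200, 250, 10),
    sector_end = c(205, 290, 5, 125))
  structure(list(
    seed = seed, days = days, start = start,
    extent_m = extent_m, cell_size = cell_size,
    island = list(cx = cx, cy = cy, semi_x = 1300, semi_y = 500),
    platforms_local = platforms_local,
    tide = list(hw_amp_mean = hw_amp_mean, hw_amp_spring = hw_amp_spring,
                period_h = 12.42, spring_neap_d = 14.77),
    current = list(axis_deg = 315, max_speed = 3, eddy_strength = 0.8),
    schedule = list(scans_per_day = scans_per_day, day_start_h = 8,
                    p_up = 0.08, p_down = 0.12, p_platform_gap = 0.08),
    truth = list(intercept = intercept,
                 target_presences = target_presences,
                 effects = list(
                   depth = list(type = "linear", beta = beta_depth,
                                center = 20),
                   tidal_state = list(type = "cos",
                                      amplitude = tidal_amplitude,
                                      peak = tidal_peak,
                                      period = 12.42))),
    detection = list(inflection_radii = inflection_radii,
                     zero_at_multiple = 2, decline = decline),
    resight_rate = resight_rate), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> seed %d: %d days from %s, %g km domain, %d platforms\n",
              x$seed, x$days, x$start, x$extent_m / 1000,
              nrow(x$platforms_local)))
  invisible(x)
}

#' Synthetic tide table for a scenario
#'
#' High waters every 12.42 h with heights modulated by a 14.77-day
#' spring-neap sinusoid; neap dates fall at the minima of the daily range.
#'
#' @param scenario A [make_scenario()].
#' @return A [tide_table()] spanning the schedule plus a one-day margin.
#' @export
make_tide_table <- function(scenario) {
  t0 <- as.POSIXct(paste(scenario$start, "00:00:00"), tz = "UTC") - 86400
  n <- ceiling((scenario$days + 2) * 24 / scenario$tide$period_h)
  hw <- t0 + (seq_len(n) - 1) * scenario$tide$period_h * 3600
  phase <- as.numeric(hw - t0, units = "days") / scenario$tide$spring_neap_d
  amp <- scenario$tide$hw_amp_mean +
    scenario$tide$hw_amp_spring * cos(2 * pi * phase)
  tide_table(hw, amp)
}

# Instantaneous tidal height above the low-water datum: a cosine between 0
# and the bracketing high-water height.
tide_height_at <- function(tide, t) {
  dt <- .signed_hours_to_nearest(t, tide$hw_time)
  idx <- vapply(as.numeric(t), function(tt)
    which.min(abs(as.numeric(tide$hw_time) - tt)), 0L)
  hw <- tide$hw_height[idx]
  (hw / 2) * (1 + cos(2 * pi * dt / TIDAL_PERIOD_H))
}

# Elliptical island coordinate: <= 1 inside the island.
.island_r <- function(scenario, x, y) {
  isl <- scenario$island
  sqrt(((x - isl$cx) / isl$semi_x)^2 + ((y - isl$cy) / isl$semi_y)^2)
}

#' Synthetic bathymetry
#'
#' Depth (m, positive down) on the scenario grid: an island nodata mask,
#' depths increasing offshore to about 35 m, a shallow (about 12 m) plateau
#' east of the island carrying a gully reaching 10-20 m, and smooth seeded
#' large-scale relief.
#'
#' @param scenario A [make_scenario()].
#' @return A [raster_grid()] of depth.
#' @export
make_bathymetry <- function(scenario) {
  .with_seed(scenario$seed + 101L, {
    cs <- scenario$cell_size
    n <- scenario$extent_m / cs
    xs <- (seq_len(n) - 0.5) * cs - scenario$extent_m / 2
    ys <- rev(xs)
    X <- matrix(xs, n, n, byrow = TRUE)
    Y <- matrix(ys, n, n)
    r <- .island_r(scenario, X, Y)
    depth <- 10 + 25 * (1 - exp(-pmax(r - 1, 0) / 1.2))
    # smooth seeded relief: a few large-scale sinusoids
    for (i in 1:4) {
      kx <- stats::runif(1, 0.2, 1) * 2 * pi / scenario$extent_m
      ky <- stats::runif(1, 0.2, 1) * 2 * pi / scenario$extent_m
      ph <- stats::runif(2, 0, 2 * pi)
      depth <- depth + 0.6 * sin(kx * X + ph[1]) * sin(ky * Y + ph[2])
    }
    # shallow (about 12 m) plateau east of the island
    isl <- scenario$island
    we <- 0.9 * exp(-((X - (isl$cx + 2300)) / 1500)^2 -
                      ((Y - isl$cy) / 1100)^2)
    depth <- depth * (1 - we) + 12 * we
    # the gully: a narrow dip in the plateau, about 18 m at its axis
    gw <- exp(-((Y - isl$cy) / 220)^2 - ((X - (isl$cx + 2300)) / 700)^2)
    depth <- depth * (1 - gw) + 18 * gw
    depth <- pmin(pmax(depth, 6), 60)
    depth[r <= 1] <- NA
    raster_grid(depth, -scenario$extent_m / 2, -scenario$extent_m / 2, cs)
  })
}

#' Synthetic tidal current cycle
#'
#' 25 half-hourly snapshots from HW-6 to HW+6 on a 300 m grid: rectilinear
#' flow along the scenario axis with speed peaking at high water and
#' reversing at the slack states, a wake eddy west of the island during
#' flood, and speeds capped at 3 m/s.
#'
#' @param scenario A [make_scenario()].
#' @return List of 25 [current_snapshot()]s.
#' @export
make_current_cycle <- function(scenario) {
  cs <- 300
  n <- ceiling(scenario$extent_m / cs)
  xs <- (seq_len(n) - 0.5) * cs - scenario$extent_m / 2
  ys <- rev(xs)
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)
  isl <- scenario$island
  amp <- 1.1 + 1.7 * exp(-((X - isl$cx) / 2600)^2 -
                           ((Y - (isl$cy + 1100)) / 900)^2)
  amp <- amp * (1 - 0.55 * exp(-((X - (isl$cx + 2300)) / 1400)^2 -
                                 ((Y - isl$cy) / 1000)^2))
  axis <- scenario$current$axis_deg * pi / 180
  states <- seq(-6, 6, by = 0.5)
  lapply(states, function(ts) {
    speed <- amp * cos(2 * pi * ts / scenario$tide$period_h)
    u <- speed * sin(axis)
    v <- speed * cos(axis)
    flood <- max(cos(2 * pi * ts / scenario$tide$period_h), 0)
    if (flood > 0) {
      ecx <- isl$cx - 2300; ecy <- isl$cy
      dx <- X - ecx; dy <- Y - ecy
      rr <- sqrt(dx^2 + dy^2) / 700
      tang <- scenario$current$eddy_strength * flood * rr * exp(-rr^2)
      u <- u + tang * (-dy / pmax(rr * 700, 1))
      v <- v + tang * (dx / pmax(rr * 700, 1))
    }
    spd <- sqrt(u^2 + v^2)
    over <- spd > scenario$current$max_speed
    scale <- ifelse(over, scenario$current$max_speed / spd, 1)
    xll <- -scenario$extent_m / 2
    current_snapshot(ts,
                     raster_grid(u * scale, xll, xll, cs),
                     raster_grid(v * scale, xll, xll, cs))
  })
}

#' Synthetic effort schedule
#'
#' Ten-minute scans through each survey day; sea state follows a seeded
#' birth-death Markov chain on 0-4 shared across platforms (weather is
#' common to the island), and each platform drops out in occasional blocks.
#'
#' @param scenario A [make_scenario()].
#' @return Data frame of scans: scan_id, site, start_time, sea_state,
#'   visibility, day_id.
#' @export
make_effort_schedule <- function(scenario) {
  .with_seed(scenario$seed + 202L, {
    sch <- scenario$schedule
    nslot <- sch$scans_per_day
    npl <- nrow(scenario$platforms_local)
    t0 <- as.POSIXct(paste(scenario$start, "00:00:00"), tz = "UTC")
    P <- sea_state_transition(scenario)
    # one shared sea-state chain over all slots of the schedule
    total <- scenario$days * nslot
    ss <- integer(total)
    ss[1] <- sample(0:4, 1, prob = sea_state_stationary(scenario))
    for (k in 2:total) ss[k] <- sample(0:4, 1, prob = P[ss[k - 1] + 1, ])
    slot_time <- rep(t0, total) +
      rep((seq_len(scenario$days) - 1) * 86400 + sch$day_start_h * 3600,
          each = nslot) + (seq_len(nslot) - 1) * 600
    active <- matrix(TRUE, total, npl)
    for (d in seq_len(scenario$days)) for (p in seq_len(npl)) {
      if (stats::runif(1) < sch$p_platform_gap) {
        gap0 <- sample(seq_len(nslot), 1)
        gap1 <- min(gap0 + sample(6:18, 1), nslot)
        active[(d - 1) * nslot + (gap0:gap1), p] <- FALSE
      }
    }
    idx <- which(active, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    scans <- data.frame(
      scan_id = seq_len(nrow(idx)),
      site = scenario$platforms_local$id[idx[, 2]],
      start_time = slot_time[idx[, 1]],
      sea_state = ss[idx[, 1]],
      visibility = "good")
    scans$day_id <- format(scans$start_time, "%Y-%m-%d")
    scans
  })
}

#' Sea-state transition matrix of a scenario
#' @param scenario A [make_scenario()].
#' @return 5 x 5 row-stochastic matrix over sea states 0-4.
#' @export
sea_state_transition <- function(scenario) {
  pu <- scenario$schedule$p_up; pd <- scenario$schedule$p_down
  P <- matrix(0, 5, 5)
  for (i in 1:5) {
    if (i < 5) P[i, i + 1] <- pu
    if (i > 1) P[i, i - 1] <- pd
    P[i, i] <- 1 - sum(P[i, ])
  }
  P
}

#' Stationary law of the sea-state chain
#' @param scenario A [make_scenario()].
#' @return Probability vector over sea states 0-4.
#' @export
sea_state_stationary <- function(scenario) {
  P <- sea_state_transition(scenario)
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Sector wedges of a scenario
#'
#' @param scenario A [make_scenario()].
#' @param radius Wedge radius (m); default twice the largest inflection
#'   radius (the range beyond which detection probability is zero).
#' @return Named list of [sector_wedge()]s keyed by site.
#' @export
scenario_wedges <- function(scenario, radius = NULL) {
  if (is.null(radius))
    radius <- scenario$detection$zero_at_multiple *
      max(scenario$detection$inflection_radii)
  pl <- scenario$platforms_local
  out <- lapply(seq_len(nrow(pl)), function(i)
    sector_wedge(pl$id[i], pl$x[i], pl$y[i],
                 pl$sector_start[i], pl$sector_end[i], radius))
  names(out) <- pl$id
  out
}

#' Platform objects of a scenario (geographic coordinates)
#' @param scenario A [make_scenario()].
#' @param lon0,lat0 Projection origin anchoring the local frame; the local
#'   domain is centred on it.
#' @return Named list of [platform()]s.
#' @export
scenario_platforms <- function(scenario, lon0 = -4.785, lat0 = 52.75543) {
  pl <- scenario$platforms_local
  ll <- local_to_lonlat(pl$x, pl$y, lon0, lat0)
  out <- lapply(seq_len(nrow(pl)), function(i)
    platform(pl$id[i], ll$lon[i], ll$lat[i], pl$height_at_LW[i],
             pl$sector_start[i], pl$sector_end[i]))
  names(out) <- pl$id
  out
}

# detection probability at distance d under sea state ss
.detect_prob <- function(scenario, d, ss) {
  r0 <- scenario$detection$inflection_radii[as.character(ss)]
  r1 <- scenario$detection$zero_at_multiple * r0
  switch(scenario$detection$decline,
         linear_area = ifelse(d <= r0, 1,
                              pmax(0, (r1^2 - d^2) / (r1^2 - r0^2))),
         step = ifelse(d <= r0, 1, ifelse(d <= r1, 0.4, 0)),
         ifelse(d <= r0, 1, pmax(0, (r1 - d) / (r1 - r0))))
}

# static log-intensity component on covariate values
.static_effect <- function(scenario, depth) {
  ef <- scenario$truth$effects$depth
  ef$beta * (depth - ef$center)
}

.temporal_effect <- function(scenario, tidal_state) {
  ef <- scenario$truth$effects$tidal_state
  ef$amplitude * cos(2 * pi * (tidal_state - ef$peak) / ef$period)
}

#' Simulate a complete synthetic survey
#'
#' Generates the environment, tides and effort for a scenario, then draws
#' sightings from an inhomogeneous Poisson process whose log-intensity is
#' the scenario's intercept plus its depth and tidal-state effects, thinned
#' by the sector viewshed and the sea-state-dependent detection function.
#' Observed bearings are quantized to one degree and reticle readings to
#' half a reticle, reproducing the step-wise distance artefact of real
#' reticle data; the truth record keeps the exact positions.
#'
#' @param scenario A [make_scenario()].
#' @param quantize Quantize bearings/reticles (default TRUE).
#' @param cfg A [geodetic_config()] used to express distances as reticles.
#' @return List with \code{scans}, \code{sightings}, \code{env}
#'   ([environment_bundle()]), \code{tide}, \code{platforms},
#'   \code{wedges} and a \code{truth} record (intercept, effects, expected
#'   count, exact positions).
#' @export
simulate_dataset <- function(scenario, quantize = TRUE,
                             cfg = geodetic_config()) {
  tide <- make_tide_table(scenario)
  depth <- make_bathymetry(scenario)
  snaps <- make_current_cycle(scenario)
  env <- environment_bundle(depth, snaps, tide)
  scans <- make_effort_schedule(scenario)
  wedges <- scenario_wedges(scenario)
  pl <- scenario$platforms_local

  # per-(site, sea state) cell table: exp(static effect) * detection prob
  cellinfo <- list()
  xs <- grid_x(depth); ys <- grid_y(depth)
  XY <- expand.grid(x = xs, y = rev(ys))
  dvals <- sample_raster(depth, XY$x, XY$y)
  ok <- !is.na(dvals)
  for (i in seq_len(nrow(pl))) {
    w <- wedges[[pl$id[i]]]
    ins <- ok & in_sector(w, XY$x, XY$y)
    d <- sqrt((XY$x[ins] - w$x)^2 + (XY$y[ins] - w$y)^2)
    g <- exp(.static_effect(scenario, dvals[ins]))
    for (ss in 0:4) {
      p <- .detect_prob(scenario, d, ss)
      cellinfo[[paste(pl$id[i], ss)]] <- list(
        x = XY$x[ins], y = XY$y[ins], dist = d,
        mass = g * p * scenario$cell_size^2)
    }
  }

  ts <- temporal_covariates(as.POSIXct(scans$start_time, tz = "UTC"),
                            tide)$tidal_state
  tmul <- exp(.temporal_effect(scenario, ts))
  smass <- vapply(paste(scans$site, scans$sea_state), function(k)
    sum(cellinfo[[k]]$mass), 0)
  base_total <- sum(tmul * smass)
  intercept <- scenario$truth$intercept
  if (is.null(intercept))
    intercept <- log(scenario$truth$target_presences / base_total)
  expected <- exp(intercept) * base_total
  if (expected > 1e6)
    stop(sprintf(paste0("expected sighting count %.3g exceeds 1e6; reduce ",
                        "the intercept, effects or schedule"), expected))

  sightings <- .with_seed(scenario$seed + 303L, {
    lam <- exp(intercept) * tmul * smass
    N <- stats::rpois(length(lam), lam)
    hits <- which(N > 0)
    rows <- lapply(hits, function(si) {
      ci <- cellinfo[[paste(scans$site[si], scans$sea_state[si])]]
      j <- sample.int(length(ci$mass), N[si], replace = TRUE,
                      prob = ci$mass)
      jit <- (stats::runif(2 * N[si]) - 0.5) * scenario$cell_size
      data.frame(scan_id = scans$scan_id[si],
                 x_true = ci$x[j] + jit[seq_len(N[si])],
                 y_true = ci$y[j] + jit[N[si] + seq_len(N[si])])
    })
    if (length(rows) == 0) {
      empty <- data.frame(scan_id = integer(), x_true = numeric(),
                          y_true = numeric(), species = character(),
                          bearing = numeric(), reticles = numeric(),
                          group_size = integer(), calves = integer(),
                          surfacing_speed = character())
      s <- empty
    } else {
    s <- do.call(rbind, rows)
    m <- match(s$scan_id, scans$scan_id)
    pi_ <- match(scans$site[m], pl$id)
    dx <- s$x_true - pl$x[pi_]; dy <- s$y_true - pl$y[pi_]
    dist <- sqrt(dx^2 + dy^2)
    bearing <- (atan2(dx, dy) * 180 / pi) %% 360
    hts <- corrected_platform_height(
      pl$height_at_LW[pi_],
      pmin(tide_height_at(tide, as.POSIXct(scans$start_time[m], tz = "UTC")), 6))
    ret <- distance_to_reticle(hts, pmin(dist, 0.95 *
      reticle_to_distance(hts, 0, cfg)), cfg)
    if (quantize) {
      bearing <- round(bearing) %% 360
      ret <- round(ret * 2) / 2
    }
    s$species <- "porpoise"
    s$bearing <- bearing
    s$reticles <- ret
    s$group_size <- 1L + stats::rpois(nrow(s), 0.3)
    s$calves <- stats::rbinom(nrow(s), 1, 0.1)
    s$surfacing_speed <- sample(c("slow", "moderate", "fast"), nrow(s),
                                replace = TRUE, prob = c(0.3, 0.5, 0.2))
    # occasional double-logging of one animal within a scan
    dup <- stats::runif(nrow(s)) < scenario$resight_rate
    if (any(dup)) s <- rbind(s, s[dup, , drop = FALSE])
    s <- s[order(s$scan_id), , drop = FALSE]
    }
    s
  })
  truth_pos <- sightings[c("scan_id", "x_true", "y_true")]
  sightings$x_true <- NULL; sightings$y_true <- NULL
  list(scans = scans, sightings = sightings, env = env, tide = tide,
       platforms = scenario_platforms(scenario), wedges = wedges,
       truth = list(intercept = intercept,
                    effects = scenario$truth$effects,
                    expected_count = expected,
                    positions = truth_pos))
}

#' Write a simulated study to disk in the pipeline's file formats
#'
#' Scans and sightings as CSV, depth as ESRI ASCII, the current cycle as u/v
#' ASCII pairs with a YAML manifest, the tide table as CSV and the platforms
#' as YAML.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scans <- sim$scans
  scans$start_time <- format(scans$start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(scans, file.path(dir, "scans.csv"), row.names = FALSE)
  utils::write.csv(sim$sightings, file.path(dir, "sightings.csv"),
                   row.names = FALSE)
  write_ascii_grid(sim$env$depth, file.path(dir, "depth.asc"))
  write_tide_table(sim$tide, file.path(dir, "tide.csv"))
  write_platforms(sim$platforms, file.path(dir, "platforms.yaml"))
  cur <- file.path(dir, "currents")
  dir.create(cur, showWarnings = FALSE)
  manifest <- lapply(sim$env$snapshots, function(s) {
    tag <- sprintf("state_%+05.1f", s$tidal_state)
    write_ascii_grid(s$u, file.path(cur, paste0(tag, "_u.asc")))
    write_ascii_grid(s$v, file.path(cur, paste0(tag, "_v.asc")))
    list(tidal_state = s$tidal_state,
         u = paste0("currents/", tag, "_u.asc"),
         v = paste0("currents/", tag, "_v.asc"))
  })
  yaml::write_yaml(manifest, file.path(dir, "currents.yaml"))
  invisible(dir)
}

#' Read a current cycle written by [write_dataset()]
#' @param dir Study directory holding currents.yaml.
#' @return List of [current_snapshot()]s.
#' @export
read_current_cycle <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "currents.yaml"))
  lapply(manifest, function(m)
    current_snapshot(m$tidal_state,
                     read_ascii_grid(file.path(dir, m$u)),
                     read_ascii_grid(file.path(dir, m$v))))
}
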