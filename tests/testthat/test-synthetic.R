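sc_small <- make_scenario(seed = 5, days = 16, target_presences = 120,
                          scans_per_day = 24)

test_that("the synthetic tide is semidiurnal with a spring-neap envelope", {
  tide <- make_tide_table(sc_small)
  dt <- diff(as.numeric(tide$hw_time)) / 3600
  expect_true(all(abs(dt - 12.42) < 1e-9))
  expect_equal(max(tide$hw_height),
               sc_small$tide$hw_amp_mean + sc_small$tide$hw_amp_spring,
               tolerance = 0.01)
  expect_equal(min(tide$hw_height),
               sc_small$tide$hw_amp_mean - sc_small$tide$hw_amp_spring,
               tolerance = 0.01)
  expect_gte(length(tide$neap_dates), 1)
})

test_that("the bathymetry has an island mask and a 10-20 m gully", {
  depth <- make_bathymetry(sc_small)
  isl <- sc_small$island
  expect_true(is.na(sample_raster(depth, isl$cx, isl$cy)))
  # profile along the gully axis within the eastern plateau
  xs <- seq(isl$cx + 1700, isl$cx + 2900, by = 50)
  prof <- sample_raster(depth, xs, rep(isl$cy, length(xs)))
  deepest <- max(prof, na.rm = TRUE)
  expect_gte(deepest, 10); expect_lte(deepest, 20)
  # the gully is a local deep relative to the plateau beside it
  beside <- sample_raster(depth, xs, rep(isl$cy + 500, length(xs)))
  expect_gt(deepest, max(beside, na.rm = TRUE))
  # seeded determinism
  expect_identical(make_bathymetry(sc_small)$values, depth$values)
})

test_that("the current cycle reverses across slack and respects the cap", {
  snaps <- make_current_cycle(sc_small)
  expect_length(snaps, 25)
  states <- vapply(snaps, `[[`, 0, "tidal_state")
  expect_equal(states, seq(-6, 6, by = 0.5))
  speed <- function(s) sqrt(s$u$values^2 + s$v$values^2)
  expect_true(all(vapply(snaps, function(s) max(speed(s)), 0) <=
                    sc_small$current$max_speed + 1e-9))
  # rectilinear reversal: HW-4 flow opposes HW+2 flow
  s1 <- snaps[[which(states == -4)]]
  s2 <- snaps[[which(states == 2)]]
  dot <- s1$u$values * s2$u$values + s1$v$values * s2$v$values
  expect_true(mean(dot < 0) > 0.95)
  # speed peaks near high water
  mean_speed <- vapply(snaps, function(s) mean(speed(s)), 0)
  expect_equal(states[which.max(mean_speed)], 0)
})

test_that("the effort schedule is 10-minute scans with a stationary sea state", {
  scans <- make_effort_schedule(sc_small)
  expect_true(all(as.numeric(scans$start_time) %% 600 == 0))
  expect_identical(make_effort_schedule(sc_small), scans)
  # marginal sea-state distribution over many slots approaches the
  # stationary law of the chain
  sc_long <- make_scenario(seed = 9, days = 220, scans_per_day = 48)
  long <- make_effort_schedule(sc_long)
  slots <- long[!duplicated(long$start_time), ]
  expect_gte(nrow(slots), 10000)
  emp <- as.numeric(table(factor(slots$sea_state, 0:4))) / nrow(slots)
  expect_lt(max(abs(emp - sea_state_stationary(sc_long))), 0.05)
})

test_that("a zero-intensity scenario yields no sightings", {
  sc0 <- make_scenario(seed = 6, days = 16, intercept = -60,
                       scans_per_day = 12)
  sim <- simulate_dataset(sc0)
  expect_equal(nrow(sim$sightings), 0)
})

test_that("a flat scenario obeys Poisson count statistics", {
  # constant intensity, no effects: expected count is analytic
  sc_flat <- make_scenario(seed = 12, days = 16, beta_depth = 0,
                           tidal_amplitude = 0, target_presences = 200,
                           scans_per_day = 24, resight_rate = 0)
  sim <- simulate_dataset(sc_flat)
  lam <- sim$truth$expected_count
  expect_equal(lam, 200, tolerance = 1e-6)
  expect_lt(abs(nrow(sim$sightings) - lam), 3 * sqrt(lam) + 1)
})

test_that("doubling the log-intensity intercept doubles expected counts", {
  sc1 <- make_scenario(seed = 13, days = 16, target_presences = 100,
                       scans_per_day = 12, resight_rate = 0)
  sim1 <- simulate_dataset(sc1)
  sc2 <- sc1; sc2$truth$intercept <- sim1$truth$intercept + log(2)
  sc2$truth$target_presences <- NULL
  sim2 <- simulate_dataset(sc2)
  expect_equal(sim2$truth$expected_count, 2 * sim1$truth$expected_count,
               tolerance = 1e-9)
})

test_that("simulated sightings reproduce the scenario's inflection radius", {
  # closed loop with the detection module: single sea state, plenty of data
  # domain wide enough that no viewshed is clipped by the grid edge
  sc <- make_scenario(seed = 21, days = 20, target_presences = 1500,
                      scans_per_day = 36, beta_depth = 0,
                      tidal_amplitude = 0, resight_rate = 0,
                      decline = "step", extent_m = 13000)
  sc$schedule$p_up <- 0; sc$schedule$p_down <- 1  # pin sea state at 0
  sim <- simulate_dataset(sc, quantize = FALSE)
  geo <- geolocate_sightings(sim$sightings, sim$scans, sim$platforms,
                             sim$tide)
  # sightings are uniform per unit area, so fit on the area axis
  est <- estimate_inflection(accumulation_curve(geo$distance_m),
                             domain = "area")
  step <- max(diff(sort(attr(est, "candidates"))))
  expect_lt(abs(as.numeric(est) - sc$detection$inflection_radii["0"]),
            step + 1e-9)
})

test_that("generated studies round-trip losslessly through their files", {
  sim <- simulate_dataset(sc_small)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  depth2 <- read_ascii_grid(file.path(dir, "depth.asc"))
  expect_equal(depth2$values, sim$env$depth$values, tolerance = 1e-6)
  tide2 <- read_tide_table(file.path(dir, "tide.csv"))
  expect_equal(as.numeric(tide2$hw_time), as.numeric(sim$tide$hw_time))
  expect_equal(tide2$hw_height, sim$tide$hw_height, tolerance = 1e-9)
  snaps2 <- read_current_cycle(dir)
  expect_length(snaps2, length(sim$env$snapshots))
  expect_equal(snaps2[[13]]$u$values, sim$env$snapshots[[13]]$u$values,
               tolerance = 1e-6)
  pf2 <- read_platforms(file.path(dir, "platforms.yaml"))
  expect_equal(names(pf2), names(sim$platforms))
  expect_equal(pf2$C$height_at_LW, sim$platforms$C$height_at_LW)
  scans2 <- utils::read.csv(file.path(dir, "scans.csv"))
  expect_equal(nrow(scans2), nrow(sim$scans))
})

test_that("the full pipeline closure recovers the simulated coefficients", {
  # simulate with quantized reticles/bearings, re-estimate positions,
  # filter, and fit the IWLR with the true functional forms
  sc <- make_scenario(seed = 31, days = 24, target_presences = 900,
                      scans_per_day = 36, resight_rate = 0.05)
  sim <- simulate_dataset(sc)
  geo <- geolocate_sightings(sim$sightings, sim$scans, sim$platforms,
                             sim$tide)
  radii <- sc$detection$inflection_radii
  lim <- detection_limits(
    rep(sc$platforms_local$id, each = length(radii)),
    "porpoise",
    rep(as.integer(names(radii)), times = nrow(sc$platforms_local)),
    rep(unname(radii), times = nrow(sc$platforms_local)))
  filt <- apply_detection_filter(geo, sim$scans, lim,
                                 c(porpoise = 4L))
  expect_lt(nrow(filt), nrow(geo))  # tail and duplicates removed
  m <- match(filt$scan_id, sim$scans$scan_id)
  pres <- sample_covariates(filt$x, filt$y,
                            sim$scans$start_time[m], sim$env)
  pres$day_id <- sim$scans$day_id[m]
  pres$site <- sim$scans$site[m]
  pres$sea_state <- sim$scans$sea_state[m]
  pres <- pres[!pres$missing_env, ]
  rfn <- function(site, ss) radii[as.character(ss)]
  avail <- sample_availability(sim$scans, sim$wedges, sim$env,
                               n_per_scan = 2, seed = 99, radius_fn = rfn)
  rec <- assemble_use_availability(pres, avail, W = 1000)
  rec$depth_c <- rec$depth - sc$truth$effects$depth$center
  rec$ts_cos <- cos(2 * pi * rec$tidal_state / 12.42)
  rec$ts_sin <- sin(2 * pi * rec$tidal_state / 12.42)
  # site and sea-state factors absorb the varying availability-window
  # density (2 points per scan over windows of different size)
  fit <- fit_iwlr(rec, list(smooth_term("depth_c", "linear"),
                            smooth_term("ts_cos", "linear"),
                            smooth_term("ts_sin", "linear"),
                            smooth_term("site", "factor"),
                            smooth_term("sea_state", "factor")), W = 1000)
  cf <- coef(fit)
  beta_hat <- unname(cf["depth_c"])
  amp_hat <- unname(sqrt(cf["ts_cos"]^2 + cf["ts_sin"]^2))
  expect_lt(abs(beta_hat - sc$truth$effects$depth$beta) /
              abs(sc$truth$effects$depth$beta), 0.2)
  expect_lt(abs(amp_hat - sc$truth$effects$tidal_state$amplitude) /
              sc$truth$effects$tidal_state$amplitude, 0.2)
})
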