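make_plane_depth <- function(dzdx, dzdy, n = 9, cell = 10) {
  xs <- (seq_len(n) - 0.5) * cell
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(rev(xs), n, n)
  # depth = -elevation
  raster_grid(-(dzdx * X + dzdy * Y), 0, 0, cell)
}

test_that("slope is zero on a flat bed and analytic on a plane", {
  flat <- raster_grid(matrix(25, 6, 6), 0, 0, 50)
  s <- terrain_slope(flat)
  expect_true(all(s$values[2:5, 2:5] == 0))
  # seabed rising 1 m per 10 m horizontally
  plane <- make_plane_depth(0.1, 0)
  s2 <- terrain_slope(plane)
  expect_equal(s2$values[5, 5], atan(0.1) * 180 / pi, tolerance = 0.01)
})

test_that("a printed 3x3 window reproduces the hand-computed Horn value", {
  z <- matrix(c(10, 11, 12, 13, 14, 15, 17, 18, 20), 3, byrow = TRUE)
  g <- raster_grid(z, 0, 0, 50)
  # hand calculation on the elevation surface (frozen):
  # dz/dx = -0.0225, dz/dy = 0.0725 -> slope 4.34106 deg, aspect 162.759 deg
  expect_equal(terrain_slope(g)$values[2, 2], 4.34106, tolerance = 1e-4)
  expect_equal(terrain_aspect(g)$values[2, 2], 162.759, tolerance = 1e-2)
})

test_that("aspect gives the downslope azimuth with axis-aligned planes", {
  north <- make_plane_depth(0, -0.05)  # deeper to the north
  expect_equal(terrain_aspect(north)$values[5, 5], 0, tolerance = 1e-9)
  east <- make_plane_depth(-0.05, 0)
  expect_equal(terrain_aspect(east)$values[5, 5], 90, tolerance = 1e-9)
  # plane dipping toward azimuth 37
  az <- 37 * pi / 180
  tilted <- make_plane_depth(-0.05 * sin(az), -0.05 * cos(az))
  expect_equal(terrain_aspect(tilted)$values[5, 5], 37, tolerance = 0.5)
  flat <- raster_grid(matrix(25, 5, 5), 0, 0, 50)
  expect_true(is.nan(terrain_aspect(flat)$values[3, 3]))
})

test_that("neighbourhood SD follows the fixed N-E-S-W-NE ordering", {
  const <- raster_grid(matrix(7, 6, 6), 0, 0, 50)
  expect_true(all(neighborhood_sd(const)$values[2:5, 2:5] == 0))
  # centre 10 with N=2, E=4, S=6, W=8, NE=10 -> sd of {10,2,4,6,8,10}
  m <- matrix(0, 3, 3)
  m[2, 2] <- 10; m[1, 2] <- 2; m[2, 3] <- 4; m[3, 2] <- 6; m[2, 1] <- 8
  m[1, 3] <- 10
  # remaining diagonals must not enter at k = 5
  m[1, 1] <- 999; m[3, 1] <- 999; m[3, 3] <- 999
  g <- raster_grid(m, 0, 0, 50)
  expect_equal(neighborhood_sd(g, 5)$values[2, 2], 3.265986, tolerance = 1e-5)
  # homogeneity: scaling values scales the SD
  g3 <- raster_grid(3 * m, 0, 0, 50)
  expect_equal(neighborhood_sd(g3, 5)$values[2, 2], 3 * 3.265986,
               tolerance = 1e-5)
  # border cells lack neighbours -> NA
  expect_true(is.na(neighborhood_sd(g, 5)$values[1, 1]))
})

test_that("current decomposition and recomposition are exact", {
  expect_equal(decompose_current(1, 0), list(u_east = 0, v_north = 1),
               tolerance = 1e-12)
  expect_equal(decompose_current(2, 90), list(u_east = 2, v_north = 0),
               tolerance = 1e-12)
  d <- decompose_current(3, 225)
  expect_equal(d$u_east, -2.121, tolerance = 1e-3)
  expect_equal(d$v_north, -2.121, tolerance = 1e-3)
  for (sp in c(0.2, 1.5, 2.9)) for (dir in c(0, 37, 180, 315)) {
    uv <- decompose_current(sp, dir)
    expect_equal(sqrt(uv$u_east^2 + uv$v_north^2), sp, tolerance = 1e-9)
    if (sp > 0)
      expect_equal((atan2(uv$u_east, uv$v_north) * 180 / pi) %% 360, dir,
                   tolerance = 1e-9)
  }
})

test_that("spatial SD of speed combines component SDs by Pythagoras", {
  n <- 5
  uniform_u <- raster_grid(matrix(1.2, n, n), 0, 0, 300)
  uniform_v <- raster_grid(matrix(-0.4, n, n), 0, 0, 300)
  expect_lt(max(spatial_sd_speed(uniform_u, uniform_v)$values[2:4, 2:4]),
            1e-12)
  # scale one known pattern to SD 3 in u and 4 in v at the centre
  m <- matrix(0, 3, 3)
  m[2, 2] <- 10; m[1, 2] <- 2; m[2, 3] <- 4; m[3, 2] <- 6; m[2, 1] <- 8
  m[1, 3] <- 10
  base_sd <- sd(c(10, 2, 4, 6, 8, 10))
  u <- raster_grid(m * (3 / base_sd) / 10, 0, 0, 300)   # keep speeds < 5
  v <- raster_grid(m * (4 / base_sd) / 10, 0, 0, 300)
  got <- spatial_sd_speed(u, v)$values[2, 2]
  expect_equal(got, 5 / 10, tolerance = 1e-9)
  sdx <- neighborhood_sd(u)$values[2, 2]
  sdy <- neighborhood_sd(v)$values[2, 2]
  expect_gte(got + 1e-12, max(sdx, sdy))
})

test_that("stratification arithmetic, floor and regime bins are exact", {
  expect_equal(tidal_stratification(10, 1), 1)
  expect_equal(tidal_stratification(50, 0.5), log10(400), tolerance = 1e-6)
  expect_equal(tidal_stratification(50, 0.5), 2.602, tolerance = 1e-3)
  expect_equal(tidal_stratification(10, 0), 7)  # floor 0.01 engaged
  expect_error(tidal_stratification(-3, 1), "positive")
  expect_equal(as.character(stratification_regime(c(1, 2.5, 2.75, 3.3, 4))),
               c("mixed", "switching", "frontal_boundary", "stratified",
                 "strongly_stratified"))
  # monotone in its input, and stratification decreasing in U
  expect_true(all(diff(tidal_stratification(10, c(0.5, 1, 2, 3))) < 0))
  expect_true(all(diff(tidal_stratification(c(10, 20, 40), 1)) > 0))
})

test_that("mean stratification reduces to the pointwise formula", {
  n <- 6
  depth <- raster_grid(matrix(32, n, n), 0, 0, 50)
  mk <- function(speed) {
    cs <- 300 / (n / 2)
    current_snapshot(0, raster_grid(matrix(speed, n, n), 0, 0, 50),
                     raster_grid(matrix(0, n, n), 0, 0, 50))
  }
  snaps <- list(current_snapshot(-3, raster_grid(matrix(1, n, n), 0, 0, 50),
                                 raster_grid(matrix(0, n, n), 0, 0, 50)),
                current_snapshot(3, raster_grid(matrix(3, n, n), 0, 0, 50),
                                 raster_grid(matrix(0, n, n), 0, 0, 50)))
  ms <- mean_stratification(depth, snaps)
  # mean speed 2 -> log10(32/8) = log10(4)
  expect_equal(ms$values[3, 3], log10(4), tolerance = 1e-9)
  # constant field is unchanged by resampling
  expect_true(all(abs(ms$values - log10(4)) < 1e-9))
})

test_that("temporal covariates track the tide table and its neaps", {
  tide <- harmonic_tide()
  tc0 <- temporal_covariates(tide$hw_time[10], tide)
  expect_equal(tc0$tidal_state, 0)
  tc3 <- temporal_covariates(tide$hw_time[10] + 3 * 3600, tide)
  expect_equal(tc3$tidal_state, 3)
  neap <- tide$neap_dates[2]
  expect_equal(temporal_covariates(neap, tide)$lunar_cycle, 0)
  expect_equal(temporal_covariates(neap + 3 * 86400, tide)$lunar_cycle, 3)
  expect_lt(temporal_covariates(neap - 2 * 86400, tide)$lunar_cycle, 0)
  expect_error(temporal_covariates(min(tide$hw_time) - 10 * 86400, tide),
               "outside")
})

test_that("tidal and lunar covariates are periodic on a harmonic table", {
  tide <- harmonic_tide()
  t <- as.POSIXct("2005-07-10 09:30:00", tz = "UTC") + (0:20) * 8 * 3600
  a <- temporal_covariates(t, tide)
  b <- temporal_covariates(t + 12.42 * 3600, tide)
  expect_lt(max(abs(a$tidal_state - b$tidal_state)), 1 / 60)
  tl <- as.POSIXct("2005-07-08 12:00:00", tz = "UTC") + (0:5) * 86400
  la <- temporal_covariates(tl, tide)$lunar_cycle
  lb <- temporal_covariates(tl + 14.77 * 86400, tide)$lunar_cycle
  expect_lt(max(abs(la - lb)), 0.05)
})

test_that("neap dates derived from daily heights sit a half cycle apart", {
  sc <- make_scenario(seed = 2, days = 40)
  tide <- make_tide_table(sc)
  neaps <- derive_neap_dates(tide)
  expect_gte(length(neaps), 2)
  gaps <- as.numeric(diff(neaps))
  expect_true(all(abs(gaps - 14.77) < 1.6))
})

test_that("current interpolation is linear between snapshots", {
  n <- 4
  mk <- function(ts, val) current_snapshot(
    ts, raster_grid(matrix(val, n, n), 0, 0, 300),
    raster_grid(matrix(-val / 2, n, n), 0, 0, 300))
  snaps <- list(mk(-2, 0), mk(0, 1), mk(2, 3))
  at0 <- interpolate_current(snaps, 0)
  expect_equal(at0$u$values[1, 1], 1)
  mid <- interpolate_current(snaps, -1)
  expect_equal(mid$u$values[2, 2], 0.5)
  q <- interpolate_current(snaps, 0.5)  # 0.75/0.25 blend of 1 and 3
  expect_equal(q$u$values[3, 3], 0.75 * 1 + 0.25 * 3)
  expect_equal(q$v$values[3, 3], -(0.75 * 1 + 0.25 * 3) / 2)
  expect_warning(interpolate_current(snaps, 5), "clamp")
})

test_that("covariate sampling is bilinear and composes the field formulas", {
  env <- toy_env(depth_value = 20)
  t <- env$tide$hw_time[5] + 2 * 3600
  s <- sample_covariates(0, 0, t, env)
  expect_equal(s$depth, 20)
  expect_equal(s$slope, 0)
  expect_equal(s$current_speed, 1, tolerance = 1e-9)
  expect_equal(s$current_direction, 315, tolerance = 1e-9)
  expect_equal(s$tidal_stratification, log10(20), tolerance = 1e-9)
  expect_equal(s$mean_stratification, log10(20), tolerance = 1e-9)
  expect_equal(s$tidal_state, 2, tolerance = 1e-9)
  expect_false(s$missing_env)
  # bilinear midpoint between cells of depth 10 and 30
  m <- matrix(10, 4, 4); m[, 3:4] <- 30
  g <- raster_grid(m, 0, 0, 100)
  mid_x <- 100 * 2  # halfway between centres of columns 2 and 3
  expect_equal(sample_raster(g, mid_x, 150), 20)
  expect_true(is.na(sample_raster(g, 1e6, 150)))
})

test_that("derived rasters are invariant to translating the grid origin", {
  set.seed(11)
  m <- matrix(20 + rnorm(100), 10, 10)
  a <- raster_grid(m, 0, 0, 50)
  b <- raster_grid(m, 12345, -9876, 50)
  expect_equal(terrain_slope(a)$values, terrain_slope(b)$values)
  expect_equal(terrain_aspect(a)$values, terrain_aspect(b)$values)
  expect_equal(neighborhood_sd(a)$values, neighborhood_sd(b)$values)
})

test_that("ESRI ASCII grids round-trip through disk", {
  set.seed(3)
  m <- matrix(rnorm(30), 5, 6)
  m[2, 3] <- NA
  g <- raster_grid(m, -250, 100, 50)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, path, digits = 10)
  back <- read_ascii_grid(path)
  expect_equal(back$values, g$values, tolerance = 1e-8)
  expect_equal(back$xll, g$xll)
  expect_equal(back$yll, g$yll)
  expect_equal(back$cell_size, g$cell_size)
})
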