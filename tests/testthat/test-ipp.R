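test_that("availability points are uniform by area over the sector wedge", {
  env <- toy_env(depth_value = 20, L = 3000, cell = 100)
  t0 <- env$tide$hw_time[4]
  scans <- data.frame(scan_id = 1:50, site = "S",
                      start_time = t0 + (1:50) * 600, sea_state = 1)
  wedges <- list(S = sector_wedge("S", 0, 0, 30, 150, 2000))
  av <- sample_availability(scans, wedges, env, n_per_scan = 2, seed = 10)
  expect_equal(nrow(av), 100)  # two per scan
  d <- sqrt(av$x^2 + av$y^2)
  b <- (atan2(av$x, av$y) * 180 / pi) %% 360
  expect_true(all(d <= 2000))
  expect_true(all(b >= 30 - 1e-9 & b <= 150 + 1e-9))
  expect_true(all(av$response == 0))
  # chi-square uniformity across ten equal-area annuli on a larger draw
  scans2 <- data.frame(scan_id = 1:500, site = "S",
                       start_time = t0 + (1:500) * 60, sea_state = 1)
  av2 <- sample_availability(scans2, wedges, env, n_per_scan = 20, seed = 11)
  d2 <- sqrt(av2$x^2 + av2$y^2)
  bins <- cut(d2^2, breaks = seq(0, 2000^2, length.out = 11))
  p <- stats::chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("availability sampling is reproducible and respects the radius rule", {
  env <- toy_env()
  scans <- data.frame(scan_id = 1:20, site = "S",
                      start_time = env$tide$hw_time[4] + (1:20) * 600,
                      sea_state = rep(c(0, 2), 10))
  wedges <- list(S = sector_wedge("S", 0, 0, 0, 120, 2500))
  rfn <- function(site, ss) if (ss == 0) 2500 else 1200
  a1 <- sample_availability(scans, wedges, env, seed = 7, radius_fn = rfn)
  a2 <- sample_availability(scans, wedges, env, seed = 7, radius_fn = rfn)
  expect_identical(a1, a2)
  d <- sqrt(a1$x^2 + a1$y^2)
  expect_true(all(d[a1$sea_state == 2] <= 1200))
  expect_true(any(d[a1$sea_state == 0] > 1200))
})

test_that("collinearity screening drops by priority", {
  set.seed(31)
  n <- 1000
  rec <- data.frame(a = rnorm(n))
  rec$b <- rec$a  # identical copy
  rec$c <- rnorm(n)
  out <- screen_collinearity(rec, c("a", "b", "c"), priority = c("a"))
  expect_equal(sort(out$retained), c("a", "c"))
  expect_equal(out$dropped, "b")
  # when the second member is higher priority, the first drops
  out2 <- screen_collinearity(rec, c("a", "b", "c"), priority = c("b"))
  expect_equal(out2$dropped, "a")
  # independent covariates survive
  ind <- data.frame(u = rnorm(n), v = rnorm(n), w = rnorm(n))
  expect_length(screen_collinearity(ind, c("u", "v", "w"))$dropped, 0)
})

test_that("smooth bases satisfy periodicity and penalty null spaces", {
  tm <- smooth_term("tidal_state", "cyclic_cubic", period = 12.42)
  ends <- build_smooth_basis(
    tm, data.frame(tidal_state = c(0, 12.42, seq(0.5, 11.5, by = 0.5))))
  expect_lt(max(abs(ends$X[1, ] - ends$X[2, ])), 1e-9)
  # constant functions are unpenalized under both bases
  x <- seq(0, 12, length.out = 50)
  b <- build_smooth_basis(tm, data.frame(tidal_state = x))
  const <- rep(1, ncol(b$X))
  # the cyclic basis sums to a constant; project a constant onto it
  cfit <- stats::lm.fit(b$X, rep(1, length(x)))$coefficients
  expect_lt(drop(t(cfit) %*% b$S %*% cfit), 1e-8)
  tp <- smooth_term("depth", "thin_plate", k = 8)
  bt <- build_smooth_basis(tp, data.frame(depth = seq(5, 50, length.out = 60)))
  lin <- stats::lm.fit(bt$X, seq(5, 50, length.out = 60))$coefficients
  expect_lt(drop(t(lin) %*% bt$S %*% lin) /
              drop(crossprod(seq(5, 50, length.out = 60))), 1e-10)
  expect_error(build_smooth_basis(
    smooth_term("depth", "thin_plate", k = 30),
    data.frame(depth = 1:10)), "basis dimension")
})

test_that("a cyclic smooth reproduces a noiseless sine", {
  x <- seq(0, 12.42, length.out = 200)
  y <- sin(2 * pi * x / 12.42)
  fit <- mgcv::gam(y ~ s(x, bs = "cc", k = 10),
                   knots = list(x = seq(0, 12.42, length.out = 10)))
  expect_lt(max(abs(stats::fitted(fit) - y)), 1e-3)
})

test_that("IWLR recovers the closed-form two-stratum coefficient", {
  rec <- two_stratum_records(n1 = 30, n0 = 10, n_avail = 100, W = 1000)
  m <- fit_iwlr(rec, list(smooth_term("xbin", "linear")), W = 1000)
  expect_equal(unname(coef(m)["xbin"]), log(3), tolerance = 0.02)
  expect_true(m$deviance_explained >= 0 && m$deviance_explained <= 100)
})

test_that("IWLR slopes are insensitive to doubling the availability weight", {
  rec <- two_stratum_records(W = 1000)
  m1 <- fit_iwlr(rec, list(smooth_term("xbin", "linear")), W = 1000)
  rec2 <- rec; rec2$case_weight <- ifelse(rec2$response == 1, 1, 2000)
  m2 <- fit_iwlr(rec2, list(smooth_term("xbin", "linear")), W = 2000)
  expect_lt(abs(coef(m1)["xbin"] - coef(m2)["xbin"]), 1e-3)
})

test_that("a constant covariate earns no effect", {
  rec <- two_stratum_records()
  rec$flatvar <- 5
  m <- suppressWarnings(
    fit_iwlr(rec, list(smooth_term("flatvar", "linear"))))
  # the design is unidentifiable up to the intercept: no deviance can be
  # attributed to the covariate and predictions are flat
  expect_equal(m$deviance_explained, 0, tolerance = 1e-8)
  pr <- predict_relative_rate(m, newdata = data.frame(flatvar = c(5, 5)))
  expect_equal(pr$relative_rate[1], pr$relative_rate[2])
})

test_that("the null model explains exactly zero deviance", {
  rec <- two_stratum_records()
  m0 <- fit_iwlr(rec, list())
  expect_equal(m0$deviance_explained, 0, tolerance = 1e-10)
})

test_that("rate ratios exponentiate coefficients", {
  expect_equal(as.numeric(rate_ratio(0)), 1)
  expect_equal(attr(rate_ratio(-0.58, digits = 2), "reported"), 0.56)
  expect_equal(attr(rate_ratio(3.6, digits = 3), "reported"), 36.6)
  expect_error(rate_ratio(Inf))
})

test_that("day-grouped CVLL matches a hand-computed two-day toy", {
  W <- 1000
  rec <- data.frame(response = c(1, 0, 0, 1, 0, 0),
                    day_id = rep(c("d1", "d2"), each = 3))
  rec$case_weight <- ifelse(rec$response == 1, 1, W)
  got <- cvll_grouped(rec, list(), W = W)
  # intercept-only fold fit: weighted MLE p = sum(w y)/sum(w) = 1/2001,
  # identical for both folds by symmetry
  p <- 1 / 2001
  expected <- 2 * (log(p) + 2 * W * log(1 - p))
  expect_equal(as.numeric(got), expected, tolerance = 1e-6)
  expect_equal(attr(got, "n_folds"), 2L)
  # permutation invariance
  perm <- rec[sample(nrow(rec)), ]
  expect_equal(as.numeric(cvll_grouped(perm, list(), W = W)),
               as.numeric(got), tolerance = 1e-9)
})

test_that("CVLL ranking is invariant to day relabeling", {
  rec <- two_stratum_records()
  a <- cvll_grouped(rec, list(smooth_term("xbin", "linear")))
  rec2 <- rec
  rec2$day_id <- ifelse(rec2$day_id == "d1", "zebra", "apple")
  b <- cvll_grouped(rec2, list(smooth_term("xbin", "linear")))
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-9)
})

test_that("forward selection keeps a helpful term and reports bookkeeping", {
  set.seed(55)
  n <- 900
  days <- rep(sprintf("d%02d", 1:9), length.out = n)
  x <- rnorm(n)
  noise <- rnorm(n)
  lp <- -2 + 1.2 * x
  y <- rbinom(n, 1, stats::plogis(lp))
  rec <- data.frame(response = y, x = x, noise = noise, day_id = days)
  rec$case_weight <- ifelse(rec$response == 1, 1, 1000)
  sel <- forward_select(rec,
                        list(x = smooth_term("x", "linear"),
                             noise = smooth_term("noise", "linear")),
                        W = 1000)
  expect_equal(sel$table$term[1], "x")
  expect_true(sel$table$retained[1])
  # bookkeeping identity on every produced table
  expect_lt(selection_delta_consistency(sel$table), 1e-9)
})

test_that("effect predictions follow the fitted linear predictor", {
  rec <- two_stratum_records()
  m0 <- fit_iwlr(rec, list())
  flat <- predict_relative_rate(m0, newdata = data.frame(xbin = c(0, 1)))
  expect_equal(flat$relative_rate[1], flat$relative_rate[2])
  m1 <- fit_iwlr(rec, list(smooth_term("xbin", "linear")))
  curve <- predict_relative_rate(m1, vary = "xbin", n = 5)
  slope <- diff(log(curve$relative_rate)) / diff(curve$xbin)
  expect_equal(mean(slope), unname(coef(m1)["xbin"]), tolerance = 1e-6)
})

test_that("cyclic effect curves match the fitted basis directly", {
  set.seed(77)
  n <- 600
  ts <- runif(n, 0, 12.42)
  lp <- -1 + 0.8 * cos(2 * pi * (ts + 3) / 12.42)
  y <- rbinom(n, 1, stats::plogis(lp))
  rec <- data.frame(response = y, tidal_state = ts,
                    day_id = rep(c("a", "b", "c"), length.out = n))
  rec$case_weight <- ifelse(rec$response == 1, 1, 1000)
  tm <- smooth_term("tidal_state", "cyclic_cubic", period = 12.42)
  m <- fit_iwlr(rec, list(tm))
  curve <- predict_relative_rate(m, vary = "tidal_state", n = 25)
  direct <- exp(as.numeric(mgcv::predict.gam(
    m$fit, newdata = data.frame(tidal_state = curve$tidal_state),
    type = "link")))
  expect_equal(curve$relative_rate, direct, tolerance = 1e-9)
  # endpoints of the cycle agree
  expect_equal(curve$relative_rate[1], curve$relative_rate[25],
               tolerance = 1e-6)
})
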