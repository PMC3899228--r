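# Effort-balanced kernel density surfaces and percent-volume core areas.
# The estimator is the fixed bivariate-normal kernel with a full 2x2
# bandwidth matrix chosen by smoothed cross-validation.

#' Sector wedge geometry
#'
#' The region surveyed from one platform: a circular sector centred on the
#' platform's local position between two true bearings, out to a radius.
#'
#' @param site Sector label.
#' @param x,y Apex (platform) position in the local frame (m).
#' @param start,end Bearings bounding the sector, degrees true (clockwise
#'   from start to end).
#' @param radius Outer radius (m).
#' @return Object of class \code{sector_wedge}.
#' @export
sector_wedge <- function(site, x, y, start, end, radius) {
  stopifnot(radius > 0)
  width <- (end - start) %% 360
  if (width == 0) width <- 360
  structure(list(site = as.character(site), x = x, y = y,
                 start = start, end = end, width = width, radius = radius),
            class = "sector_wedge")
}

#' Point-in-sector test
#' @param wedge A [sector_wedge()].
#' @param px,py Point coordinates (vectorised).
#' @return Logical vector.
#' @export
in_sector <- function(wedge, px, py) {
  dx <- px - wedge$x; dy <- py - wedge$y
  d <- sqrt(dx^2 + dy^2)
  b <- (atan2(dx, dy) * 180 / pi) %% 360
  rel <- (b - wedge$start) %% 360
  d <= wedge$radius & (rel <= wedge$width | d < 1e-9)
}

#' Area of a sector wedge in km^2
#' @param wedge A [sector_wedge()].
#' @export
sector_area_km2 <- function(wedge) {
  (wedge$width / 360) * pi * wedge$radius^2 / 1e6
}

#' Balance survey effort across sectors
#'
#' Restricts the scans to periods with simultaneous coverage from every
#' sector, then randomly selects the same number of scans per sector so that
#' density surfaces are not driven by unequal effort.
#'
#' @param scans Data frame with scan_id, site, start_time.
#' @param sightings Data frame with scan_id (restricted to selected scans).
#' @param n_per_sector Scans retained per sector (default 600).
#' @param seed Integer seed making the subsample reproducible.
#' @param require_simultaneous If TRUE (default) only scan start times at
#'   which every sector was active are eligible.
#' @return List with \code{scans} and \code{sightings} subsampled.
#' @export
balance_effort <- function(scans, sightings, n_per_sector = 600, seed,
                           require_simultaneous = TRUE) {
  sites <- sort(unique(scans$site))
  eligible <- scans
  if (require_simultaneous && length(sites) > 1) {
    tab <- table(scans$start_time, scans$site)
    full <- rownames(tab)[apply(tab > 0, 1, all)]
    eligible <- scans[as.character(scans$start_time) %in% full, , drop = FALSE]
  }
  counts <- table(eligible$site)
  short <- sites[!(sites %in% names(counts)) | counts[sites] < n_per_sector]
  if (length(short) > 0)
    stop(sprintf("sector %s has only %d simultaneous-coverage scans (< %d)",
                 short[1], if (short[1] %in% names(counts)) counts[[short[1]]] else 0L,
                 n_per_sector))
  keep <- .with_seed(seed, unlist(lapply(sites, function(st) {
    ids <- eligible$scan_id[eligible$site == st]
    if (length(ids) == n_per_sector) ids else sample(ids, n_per_sector)
  })))
  list(scans = scans[scans$scan_id %in% keep, , drop = FALSE],
       sightings = sightings[sightings$scan_id %in% keep, , drop = FALSE])
}

# Evaluate an expression under a fixed seed, restoring the caller's RNG
# state afterwards so seeded operations do not perturb each other.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Weight sightings falling in sector overlaps
#'
#' Points inside more than one sector wedge were surveyable from two
#' platforms and receive weight 0.5 to correct for double effort; points in
#' exactly one sector receive weight 1; points in none are flagged.
#'
#' @param points Data frame with x, y.
#' @param wedges List of [sector_wedge()]s.
#' @return Object of class \code{weighted_points}: data frame x, y, weight,
#'   n_sectors.
#' @export
weight_overlap_sightings <- function(points, wedges) {
  counts <- Reduce(`+`, lapply(wedges, function(w)
    as.integer(in_sector(w, points$x, points$y))))
  out <- data.frame(x = points$x, y = points$y,
                    weight = ifelse(counts >= 2, 0.5, 1),
                    n_sectors = counts)
  if (any(counts == 0))
    warning(sum(counts == 0), " point(s) outside all sectors (kept, weight 1)")
  class(out) <- c("weighted_points", "data.frame")
  out
}

# Bivariate normal density with covariance S evaluated at displacement
# matrix D (n x 2).
.dmvnorm2 <- function(D, S) {
  Sinv <- solve(S)
  q <- Sinv[1, 1] * D[, 1]^2 + 2 * Sinv[1, 2] * D[, 1] * D[, 2] +
    Sinv[2, 2] * D[, 2]^2
  exp(-q / 2) / (2 * pi * sqrt(det(S)))
}

#' Smoothed cross-validation criterion for a bandwidth matrix
#'
#' The SCV objective for weighted bivariate data with Gaussian kernels and a
#' pilot bandwidth G:
#' \deqn{SCV(H) = \frac{\sum w_i^2}{(\sum w_i)^2}\frac{|H|^{-1/2}}{4\pi} +
#'   \sum_{i \ne j}\frac{w_i w_j}{(\sum w_i)^2}
#'   (\phi_{2H+2G} - 2\phi_{H+2G} + \phi_{2G})(x_i - x_j)}
#'
#' @param H Candidate 2x2 symmetric positive-definite bandwidth matrix.
#' @param points A \code{weighted_points} data frame (or any x, y, weight).
#' @param G Pilot bandwidth matrix (normal-scale pilot by default).
#' @return The criterion value.
#' @export
scv_criterion <- function(H, points, G = NULL) {
  w <- if (is.null(points$weight)) rep(1, nrow(points)) else points$weight
  X <- cbind(points$x, points$y)
  if (is.null(G)) G <- .pilot_bandwidth(X, w)
  sw <- sum(w)
  ij <- which(upper.tri(matrix(0, nrow(X), nrow(X))), arr.ind = TRUE)
  D <- X[ij[, 1], , drop = FALSE] - X[ij[, 2], , drop = FALSE]
  pw <- 2 * w[ij[, 1]] * w[ij[, 2]] / sw^2
  term1 <- sum(w^2) / sw^2 / (4 * pi * sqrt(det(H)))
  term2 <- sum(pw * (.dmvnorm2(D, 2 * H + 2 * G) -
                       2 * .dmvnorm2(D, H + 2 * G) +
                       .dmvnorm2(D, 2 * G)))
  term1 + term2
}

# Normal-scale pilot: G = n_eff^(-1/3) * S (d = 2 plug-in pilot scaling).
.pilot_bandwidth <- function(X, w) {
  neff <- sum(w)^2 / sum(w^2)
  S <- stats::cov.wt(X, wt = w / sum(w), method = "ML")$cov
  neff^(-1 / 3) * S
}

# Weighted normal-scale bandwidth (the plug-in fallback).
.normal_scale_bandwidth <- function(X, w) {
  neff <- sum(w)^2 / sum(w^2)
  S <- stats::cov.wt(X, wt = w / sum(w), method = "ML")$cov
  neff^(-1 / 3) * S
}

#' Bandwidth matrix by smoothed cross-validation
#'
#' Minimises the [scv_criterion()] over symmetric positive-definite matrices
#' via a log-Cholesky parameterisation, starting from the normal-scale
#' bandwidth.  Deterministic given the inputs.  With fewer points than
#' \code{min_n_scv} the normal-scale plug-in bandwidth is returned instead
#' and flagged in the \code{method} attribute.
#'
#' @param points A \code{weighted_points} data frame (columns x, y and
#'   optionally weight); at least 8 points with positive spread.
#' @param min_n_scv Below this n the plug-in fallback is used (default 25).
#' @return A 2x2 bandwidth matrix (m^2) with attribute \code{method} equal
#'   to \code{"scv"} or \code{"plugin"}.
#' @export
scv_bandwidth <- function(points, min_n_scv = 25) {
  w <- if (is.null(points$weight)) rep(1, nrow(points)) else points$weight
  X <- cbind(points$x, points$y)
  if (nrow(X) < 8) stop("need at least 8 points for bandwidth selection")
  if (any(apply(X, 2, stats::sd) == 0)) stop("degenerate point set (zero variance)")
  H0 <- .normal_scale_bandwidth(X, w)
  if (nrow(X) < min_n_scv)
    return(structure(H0, method = "plugin"))
  G <- .pilot_bandwidth(X, w)
  L0 <- chol(H0)
  par0 <- c(log(L0[1, 1]), L0[1, 2], log(L0[2, 2]))
  make_H <- function(p) {
    L <- matrix(c(exp(p[1]), p[2], 0, exp(p[3])), 2, 2)
    crossprod(L)
  }
  obj <- function(p) scv_criterion(make_H(p), points, G)
  fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  structure(make_H(fit$par), method = "scv")
}

#' Kernel density surface on a metric grid
#'
#' Weighted mixture of bivariate normal kernels with common bandwidth H,
#' evaluated at cell centres and normalised by total weight, so that the
#' surface integrates to one when the grid holds the kernel mass.
#'
#' @param points A \code{weighted_points} data frame.
#' @param H 2x2 bandwidth matrix (m^2).
#' @param cell_size Output cell size (default 50 m).
#' @param grid Optional [raster_grid()] defining the output geometry; by
#'   default a grid covering the points plus a 3-sigma margin.
#' @param mass_warn Warn when less than this fraction of mass falls inside
#'   the grid (default 0.99).
#' @return A [raster_grid()] of density (per m^2) with attribute
#'   \code{total_weight}.
#' @export
kde_surface <- function(points, H, cell_size = 50, grid = NULL,
                        mass_warn = 0.99) {
  ev <- eigen(H, symmetric = TRUE)
  if (any(ev$values <= 0)) stop("bandwidth matrix must be positive definite")
  sig <- sqrt(max(ev$values))
  w <- if (is.null(points$weight)) rep(1, nrow(points)) else points$weight
  if (is.null(grid)) {
    m <- 3 * sig
    xr <- range(points$x) + c(-m, m)
    yr <- range(points$y) + c(-m, m)
    nc <- ceiling(diff(xr) / cell_size); nr <- ceiling(diff(yr) / cell_size)
    grid <- raster_grid(matrix(0, nr, nc), xr[1], yr[1], cell_size)
  }
  xs <- grid_x(grid); ys <- grid_y(grid)
  nr <- length(ys); nc <- length(xs)
  dens <- matrix(0, nr, nc)
  Sinv <- solve(H)
  norm <- 2 * pi * sqrt(det(H))
  cutoff <- 5 * sig
  for (i in seq_len(nrow(points))) {
    jx <- which(abs(xs - points$x[i]) <= cutoff)
    iy <- which(abs(ys - points$y[i]) <= cutoff)
    if (length(jx) == 0 || length(iy) == 0) next
    dx <- xs[jx] - points$x[i]
    dy <- ys[iy] - points$y[i]
    qx <- outer(dy^2 * Sinv[2, 2], dx^2 * Sinv[1, 1], `+`) +
      2 * Sinv[1, 2] * outer(dy, dx)
    dens[iy, jx] <- dens[iy, jx] + w[i] * exp(-qx / 2) / norm
  }
  dens <- dens / sum(w)
  out <- raster_grid(dens, grid$xll, grid$yll, grid$cell_size, grid$nodata)
  mass <- sum(dens) * grid$cell_size^2
  if (mass < mass_warn)
    warning(sprintf("only %.1f%% of kernel mass falls inside the grid", 100 * mass))
  attr(out, "total_weight") <- sum(w)
  out
}

#' Percent-volume contours of a density surface
#'
#' For each level p the cells are ranked by density and the smallest set of
#' cells whose cumulative volume reaches p% forms the contour region; the
#' 50% region is the conventional core area.  Areas are cell-mask areas.
#' Land is not excluded.
#'
#' @param surface A density [raster_grid()] from [kde_surface()].
#' @param levels Percent levels in (0, 100) (default 50, 60, 75, 95).
#' @return A list of \code{volume_contour} objects, each with \code{level},
#'   \code{area_km2}, \code{threshold} (density at the contour),
#'   \code{mask} (logical matrix) and \code{polygons} (rings traced on the
#'   mask, as lists of x/y).
#' @export
volume_contours <- function(surface, levels = c(50, 60, 75, 95)) {
  if (any(levels <= 0 | levels >= 100)) stop("levels must lie in (0, 100)")
  v <- surface$values
  vals <- v[!is.na(v)]
  o <- order(vals, decreasing = TRUE)
  mass <- cumsum(vals[o]) / sum(vals)
  valid_idx <- which(!is.na(v))
  out <- lapply(sort(levels), function(p) {
    k <- which(mass >= p / 100)[1]
    thr <- vals[o][k]
    # exactly the k highest-density cells (cell-count semantics; ties do
    # not inflate the region)
    mask <- matrix(FALSE, nrow(v), ncol(v))
    mask[valid_idx[o[seq_len(k)]]] <- TRUE
    area <- sum(mask) * surface$cell_size^2 / 1e6
    ind <- raster_grid(ifelse(mask, 1, 0), surface$xll, surface$yll,
                       surface$cell_size)
    polys <- grDevices::contourLines(x = grid_x(surface),
                                     y = rev(grid_y(surface)),
                                     z = t(ind$values[nrow(ind$values):1, ,
                                                      drop = FALSE]),
                                     levels = 0.5)
    structure(list(level = p, area_km2 = area, threshold = thr,
                   mask = mask, polygons = polys),
              class = "volume_contour")
  })
  names(out) <- paste0("p", sort(levels))
  out
}

#' @export
print.volume_contour <- function(x, ...) {
  cat(sprintf("<volume_contour> %g%%: %.3f km^2 (%d cells)\n",
              x$level, x$area_km2, sum(x$mask)))
  invisible(x)
}

#' Write volume contours to GeoJSON
#'
#' @param contours List from [volume_contours()].
#' @param path Output path.
#' @param properties Named list of extra properties (e.g. species, month).
#' @export
write_contours_geojson <- function(contours, path, properties = list()) {
  feats <- lapply(contours, function(vc) {
    rings <- lapply(vc$polygons, function(pl) {
      xy <- cbind(pl$x, pl$y)
      if (!all(xy[1, ] == xy[nrow(xy), ])) xy <- rbind(xy, xy[1, ])
      lapply(seq_len(nrow(xy)), function(i) c(xy[i, 1], xy[i, 2]))
    })
    list(type = "Feature",
         properties = c(properties,
                        list(level = vc$level, area_km2 = vc$area_km2)),
         geometry = list(type = "MultiPolygon",
                         coordinates = lapply(rings, list)))
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = unname(feats)),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Core-area percentage of the survey area
#'
#' @param contour_area_km2 Area of a percent-volume contour (km^2).
#' @param survey_area_km2 Total surveyed area (km^2).
#' @return Integer-rounded percentage \code{100 * contour / survey}.
#' @export
core_area_percentage <- function(contour_area_km2, survey_area_km2) {
  stopifnot(all(contour_area_km2 > 0), all(survey_area_km2 > 0))
  round(100 * contour_area_km2 / survey_area_km2)
}

#' Correlation between two density surfaces
#'
#' Pearson correlation across the cells valid in both surfaces; quantifies
#' whether two species use the area in the same way.
#'
#' @param s1,s2 Congruent density [raster_grid()]s.
#' @return Pearson correlation coefficient.
#' @export
surface_correlation <- function(s1, s2) {
  if (!identical(dim(s1$values), dim(s2$values)))
    stop("surfaces are not on congruent grids")
  ok <- !is.na(s1$values) & !is.na(s2$values)
  if (sum(ok) < 3) stop("fewer than 3 shared valid cells")
  stats::cor(s1$values[ok], s2$values[ok])
}
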