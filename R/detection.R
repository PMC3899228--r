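# Distance-dependent detectability: accumulation curves, piecewise-linear
# inflection estimation, curve pooling, and the sighting filter that
# restricts analysis to the uniform-detection region.

#' Distance-accumulation curve
#'
#' The empirical cumulative proportion of sightings up to each observed
#' distance: constant detection with distance appears as a straight rise,
#' and the departure from linearity marks where detectability declines.
#'
#' @param distances Radial distances (m), at least one, non-negative.
#' @param key Optional label (e.g. site/species/sea-state) carried along.
#' @return An object of class \code{accumulation_curve} with the sorted
#'   distances and cumulative proportions.
#' @export
accumulation_curve <- function(distances, key = NULL) {
  distances <- distances[!is.na(distances)]
  if (length(distances) == 0) stop("no distances supplied")
  if (any(distances < 0)) stop("distances must be non-negative")
  d <- sort(distances)
  structure(list(distances = d,
                 cumulative = seq_along(d) / length(d),
                 key = key),
            class = "accumulation_curve")
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat(sprintf("<accumulation_curve%s> n = %d, distances %g-%g m\n",
              if (is.null(x$key)) "" else paste0(" ", x$key),
              length(x$distances), min(x$distances), max(x$distances)))
  invisible(x)
}

#' Estimate the inflection point of an accumulation curve
#'
#' Fits a continuous two-segment ("broken stick") least-squares line to the
#' cumulative curve, searching candidate breakpoints over the quantiles of
#' the observed distances, and returns the breakpoint of the best fit whose
#' second slope does not exceed the first.  When the broken stick improves
#' on a single straight line by less than \code{tol} (relative SSE) the
#' curve is judged to show no decline and the maximum distance is returned
#' with attribute \code{no_decline = TRUE}.
#'
#' @param curve An [accumulation_curve()].
#' @param min_points Minimum number of observations required (default 20).
#' @param n_candidates Size of the breakpoint candidate grid (default 50
#'   quantiles of the observed distances between the 5th and 95th
#'   percentile).
#' @param tol Relative SSE improvement below which no breakpoint is declared
#'   (default 0.01).
#' @param domain Axis on which the two segments are fitted:
#'   \code{"distance"} (default) suits curves that rise linearly with
#'   distance; \code{"area"} fits against squared distance, appropriate when
#'   sightings are uniform per unit area over a sector so the cumulative
#'   proportion is linear in the area surveyed.  The returned breakpoint is
#'   always a distance.
#' @return Breakpoint distance (m) with attributes \code{no_decline},
#'   \code{candidates} (the grid searched, on the distance axis) and
#'   \code{slopes}.
#' @export
estimate_inflection <- function(curve, min_points = 20, n_candidates = 50,
                                tol = 0.01,
                                domain = c("distance", "area")) {
  domain <- match.arg(domain)
  x <- curve$distances; y <- curve$cumulative
  if (domain == "area") x <- x^2
  if (length(x) < min_points)
    stop(sprintf("need at least %d observations (have %d)", min_points, length(x)))
  cand <- unique(stats::quantile(x, probs = seq(0.05, 0.95,
                                                length.out = n_candidates),
                                 names = FALSE, type = 1))
  sse1 <- sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
  best <- list(sse = Inf, bp = NA, slopes = c(NA, NA))
  for (c0 in cand) {
    X <- cbind(1, x, pmax(x - c0, 0))
    fit <- stats::lm.fit(X, y)
    b <- fit$coefficients
    if (is.na(b[3]) || b[3] > 0) next  # second slope must not exceed first
    sse <- sum(fit$residuals^2)
    if (sse < best$sse)
      best <- list(sse = sse, bp = c0, slopes = c(b[2], b[2] + b[3]))
  }
  no_decline <- !is.finite(best$sse) || (sse1 - best$sse) < tol * sse1
  out <- if (no_decline) max(x) else best$bp
  if (domain == "area") {
    out <- sqrt(out)
    cand <- sqrt(cand)
  }
  structure(out, no_decline = no_decline, candidates = cand,
            slopes = best$slopes)
}

# Two-sample Kolmogorov-Smirnov statistic (max vertical deviation between
# the empirical cdfs, evaluated on the pooled support; ties handled exactly).
.ks_statistic <- function(d1, d2) {
  grid <- sort(unique(c(d1, d2)))
  F1 <- stats::ecdf(d1)(grid)
  F2 <- stats::ecdf(d2)(grid)
  max(abs(F1 - F2))
}

#' Group accumulation curves that can be pooled
#'
#' Curves whose pairwise maximum vertical deviation (the two-sample
#' Kolmogorov-Smirnov statistic) is at most \code{threshold} are linked, and
#' the connected components of that graph form the pooled groups.  The rule
#' is deterministic given the inputs.
#'
#' @param curves List of [accumulation_curve()]s (>= 2).
#' @param threshold Maximum deviation tolerated within a group (default 0.1).
#' @return List with \code{groups} (list of integer index vectors),
#'   \code{statistic} (the pairwise deviation matrix) and the threshold.
#' @export
poolable_curves <- function(curves, threshold = 0.1) {
  stopifnot(length(curves) >= 2)
  n <- length(curves)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- .ks_statistic(curves[[i]]$distances,
                                        curves[[j]]$distances)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] <= threshold) parent[find(j)] <- find(i)
  comp <- vapply(seq_len(n), find, 0L)
  keys <- vapply(curves, function(cv)
    if (is.null(cv$key)) NA_character_ else as.character(cv$key), "")
  dimnames(D) <- list(keys, keys)
  list(groups = unname(split(seq_len(n), comp)), statistic = D,
       threshold = threshold)
}

#' Detection limits table
#'
#' One inflection radius per (site, species, sea state); sightings beyond
#' this radius are treated as detection artefacts, not habitat signal.
#'
#' @param site,species,sea_state,radius_m Equal-length vectors.
#' @return Data frame of class \code{detection_limits}.
#' @export
detection_limits <- function(site, species, sea_state, radius_m) {
  stopifnot(all(radius_m > 0))
  df <- data.frame(site = as.character(site), species = as.character(species),
                   sea_state = as.integer(sea_state), radius_m = radius_m,
                   stringsAsFactors = FALSE)
  # soft check: radius should not grow with sea state for a fixed site/species
  for (grp in split(df, paste(df$site, df$species))) {
    grp <- grp[order(grp$sea_state), ]
    if (is.unsorted(-grp$radius_m))
      warning(sprintf("inflection radius increases with sea state for %s/%s",
                      grp$site[1], grp$species[1]))
  }
  class(df) <- c("detection_limits", "data.frame")
  df
}

#' @rdname detection_limits
#' @param path CSV path with columns site, species, sea_state, radius_m.
#' @export
read_detection_limits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  detection_limits(df$site, df$species, df$sea_state, df$radius_m)
}

#' @rdname detection_limits
#' @param limits A \code{detection_limits} table.
#' @export
write_detection_limits <- function(limits, path) {
  utils::write.csv(as.data.frame(limits), path, row.names = FALSE)
}

#' Default per-species sea-state caps
#'
#' Dolphin sightings are usable through sea state 2; porpoise sightings
#' through sea state 1, with sea state 2 admitted only inside its own
#' (smaller) inflection radius, which the limits table expresses.
#' @return Named integer vector of maximum usable sea states.
#' @export
default_species_caps <- function() c(porpoise = 2L, rissos = 2L)

#' Filter sightings to the uniform-detection region
#'
#' Applies, in order: removal of repeat sightings of the same animal within
#' one scan (identical scan/species/bearing/reticle records), the
#' per-species sea-state cap, and the per-(site, species, sea-state)
#' inflection-radius cut.  The filter is idempotent.
#'
#' @param sightings Data frame with columns scan_id, species, distance_m and
#'   (for the de-duplication) bearing, reticles.
#' @param scans Data frame with columns scan_id, site, sea_state.
#' @param limits A [detection_limits()] table covering every (site, species,
#'   sea state) combination present after the cap; a missing entry is a
#'   configuration error.
#' @param species_caps Named vector of maximum sea states per species.
#' @return The retained rows of \code{sightings}, joined with site and
#'   sea_state.
#' @export
apply_detection_filter <- function(sightings, scans, limits,
                                   species_caps = default_species_caps()) {
  stopifnot(all(sightings$scan_id %in% scans$scan_id))
  m <- match(sightings$scan_id, scans$scan_id)
  s <- sightings
  s$site <- scans$site[m]
  s$sea_state <- scans$sea_state[m]
  # re-sightings within one scan
  if (all(c("bearing", "reticles") %in% names(s))) {
    dup <- duplicated(s[c("scan_id", "species", "bearing", "reticles")])
    s <- s[!dup, , drop = FALSE]
  }
  caps <- species_caps[s$species]
  if (any(is.na(caps)))
    stop("no sea-state cap for species: ",
         paste(unique(s$species[is.na(caps)]), collapse = ", "))
  s <- s[s$sea_state <= caps, , drop = FALSE]
  if (nrow(s) == 0) return(s)
  key <- paste(s$site, s$species, s$sea_state, sep = "/")
  lkey <- paste(limits$site, limits$species, limits$sea_state, sep = "/")
  mi <- match(key, lkey)
  if (any(is.na(mi)))
    stop("no detection limit for: ",
         paste(unique(key[is.na(mi)]), collapse = ", "))
  s[s$distance_m <= limits$radius_m[mi], , drop = FALSE]
}
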