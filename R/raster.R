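# Regular raster grids in the local metric frame, plus the small amount of
# grid I/O and algebra the covariate engineering needs.  Values are stored as
# a matrix whose first row is the NORTHERNMOST row (the ESRI ASCII layout);
# missing cells are NA internally and the nodata sentinel only on disk.

#' Create a raster grid
#'
#' @param values Numeric matrix; row 1 is the northernmost row.
#' @param xll,yll Coordinates of the lower-left corner of the grid (m).
#' @param cell_size Cell size in metres (default 50).
#' @param nodata Sentinel written to disk for missing cells (default -9999).
#' @return An object of class \code{raster_grid}.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cell_size = 50,
                        nodata = -9999) {
  stopifnot(is.matrix(values), cell_size > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cell_size = cell_size, nodata = nodata),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells of %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$xll, x$yll))
  cat(sprintf("  values: [%g, %g], %d missing\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

# Cell-centre coordinate vectors (x by column, y by row; y decreasing).
grid_x <- function(g) g$xll + (seq_len(ncol(g$values)) - 0.5) * g$cell_size
grid_y <- function(g) g$yll + (nrow(g$values) - seq_len(nrow(g$values)) + 0.5) * g$cell_size

#' Read an ESRI ASCII grid
#'
#' Supports the standard 6-line header (\code{ncols nrows
#' xllcorner yllcorner cellsize NODATA_value}); \code{xllcenter/yllcenter}
#' headers are converted to corner registration.
#'
#' @param path Path to an .asc file.
#' @return A [raster_grid()].
#' @export
read_ascii_grid <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, 1)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) == 2 && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    } else {
      seek(con, pos)
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ESRI ASCII header in ", path)
  vals <- scan(con, quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("grid body does not match header dimensions")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  raster_grid(m, xll, yll, hdr$cellsize, nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param grid A [raster_grid()].
#' @param path Output path.
#' @param digits Significant digits written (default 7).
#' @export
write_ascii_grid <- function(grid, path, digits = 7) {
  v <- grid$values
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", grid$xll),
           sprintf("yllcorner %.10g", grid$yll),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %.10g", grid$nodata))
  body <- apply(v, 1, function(row) {
    row[is.na(row)] <- grid$nodata
    paste(signif(row, digits), collapse = " ")
  })
  writeLines(c(hdr, body), path)
}

#' Bilinear sampling of a raster grid
#'
#' Samples values at arbitrary points by bilinear interpolation between the
#' four surrounding cell centres; points between the outermost cell centres
#' and the grid edge are clamped to the centre lattice.  Any contributing
#' missing cell makes the result NA; points outside the grid extent are NA.
#'
#' @param grid A [raster_grid()].
#' @param x,y Point coordinates (m), vectorised.
#' @return Numeric vector of sampled values.
#' @export
sample_raster <- function(grid, x, y) {
  v <- grid$values
  cs <- grid$cell_size
  nr <- nrow(v); nc <- ncol(v)
  out <- rep(NA_real_, length(x))
  inside <- x >= grid$xll & x <= grid$xll + nc * cs &
            y >= grid$yll & y <= grid$yll + nr * cs
  if (!any(inside)) return(out)
  # continuous column/row index on the cell-centre lattice
  fx <- (x[inside] - grid$xll) / cs - 0.5
  fy <- (grid$yll + nr * cs - y[inside]) / cs - 0.5  # row index from north
  fx <- pmin(pmax(fx, 0), nc - 1)
  fy <- pmin(pmax(fy, 0), nr - 1)
  j0 <- pmin(floor(fx), nc - 2); i0 <- pmin(floor(fy), nr - 2)
  if (nc == 1) j0 <- rep(0, length(fx))
  if (nr == 1) i0 <- rep(0, length(fy))
  tx <- fx - j0; ty <- fy - i0
  idx <- function(i, j) v[cbind(i + 1, j + 1)]
  j1 <- pmin(j0 + 1, nc - 1); i1 <- pmin(i0 + 1, nr - 1)
  val <- (1 - tx) * (1 - ty) * idx(i0, j0) +
         tx * (1 - ty) * idx(i0, j1) +
         (1 - tx) * ty * idx(i1, j0) +
         tx * ty * idx(i1, j1)
  out[inside] <- val
  out
}

#' Resample a raster onto the geometry of another
#'
#' Bilinear resampling of \code{grid} at the cell centres of \code{target}.
#'
#' @param grid Source [raster_grid()].
#' @param target Raster whose geometry defines the output.
#' @return A [raster_grid()] with the geometry of \code{target}.
#' @export
resample_to <- function(grid, target) {
  xs <- grid_x(target); ys <- grid_y(target)
  pts <- expand.grid(row = seq_along(ys), col = seq_along(xs))
  vals <- sample_raster(grid, xs[pts$col], ys[pts$row])
  m <- matrix(NA_real_, length(ys), length(xs))
  m[cbind(pts$row, pts$col)] <- vals
  raster_grid(m, target$xll, target$yll, target$cell_size, target$nodata)
}

# Shift a matrix by (di, dj) padding with NA; di > 0 moves values south.
.shift_matrix <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  ri <- seq_len(nr) - di; cj <- seq_len(nc) - dj
  ok_i <- ri >= 1 & ri <= nr; ok_j <- cj >= 1 & cj <= nc
  out[ok_i, ok_j] <- m[ri[ok_i], cj[ok_j]]
  out
}

# Horn 3x3 gradient of the SEABED ELEVATION (-depth) in x (east) and
# y (north); returns list(dzdx, dzdy) with NA borders.
.horn_gradient <- function(depth) {
  e <- -depth$values
  cs <- depth$cell_size
  s <- function(di, dj) .shift_matrix(e, di, dj)
  # neighbours named by compass direction of the neighbour relative to cell
  nw <- s(1, 1);  n_ <- s(1, 0);  ne <- s(1, -1)
  w_ <- s(0, 1);                  e_ <- s(0, -1)
  sw <- s(-1, 1); s_ <- s(-1, 0); se <- s(-1, -1)
  dzdx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * cs)
  dzdy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * cs)
  list(dzdx = dzdx, dzdy = dzdy)
}

#' Seabed slope from a depth grid
#'
#' Horn's 3x3 finite-difference gradient of the seabed surface, in degrees
#' (0 = flat, 90 = vertical).  Border cells and cells with any missing
#' neighbour are NA.
#'
#' @param depth Depth [raster_grid()] (metres, positive down).
#' @return A [raster_grid()] of slope in degrees.
#' @export
terrain_slope <- function(depth) {
  if (sum(!is.na(depth$values)) < 9)
    stop("need at least a 3x3 block of valid depth cells")
  g <- .horn_gradient(depth)
  slope <- atan(sqrt(g$dzdx^2 + g$dzdy^2)) * 180 / pi
  raster_grid(slope, depth$xll, depth$yll, depth$cell_size, depth$nodata)
}

#' Seabed aspect from a depth grid
#'
#' Azimuth of the downslope direction of the seabed surface, degrees
#' clockwise from north in [0, 360).  Flat cells carry NaN (distinct from the
#' NA used for missing data).
#'
#' @inheritParams terrain_slope
#' @return A [raster_grid()] of aspect in degrees.
#' @export
terrain_aspect <- function(depth) {
  if (sum(!is.na(depth$values)) < 9)
    stop("need at least a 3x3 block of valid depth cells")
  g <- .horn_gradient(depth)
  asp <- (atan2(-g$dzdx, -g$dzdy) * 180 / pi) %% 360
  flat <- !is.na(g$dzdx) & g$dzdx == 0 & g$dzdy == 0
  asp[flat] <- NaN
  raster_grid(asp, depth$xll, depth$yll, depth$cell_size, depth$nodata)
}

# Neighbour offsets in the deterministic order rook-first N, E, S, W then
# diagonals NE, SE, SW, NW; (di, dj) with di = +1 meaning the neighbour lies
# one row NORTH of the cell.
.neighbor_order <- rbind(c(1, 0), c(0, -1), c(-1, 0), c(0, 1),
                         c(1, -1), c(-1, -1), c(-1, 1), c(1, 1))

#' Neighbourhood standard deviation
#'
#' Standard deviation of each cell together with its \code{k} nearest
#' neighbouring cells, used as the spatial-variation measure for slope and
#' for the current components.  Neighbours are taken in the fixed order N, E,
#' S, W, NE, SE, SW, NW; cells whose selected neighbourhood leaves the grid
#' or touches missing data are NA.
#'
#' @param grid A [raster_grid()].
#' @param k_neighbors Number of neighbouring cells included (default 5:
#'   the four rook neighbours plus NE; 8 gives the full Moore neighbourhood).
#' @return A [raster_grid()] of standard deviations.
#' @export
neighborhood_sd <- function(grid, k_neighbors = 5) {
  stopifnot(k_neighbors >= 1, k_neighbors <= 8)
  v <- grid$values
  layers <- c(list(v), lapply(seq_len(k_neighbors), function(i)
    .shift_matrix(v, .neighbor_order[i, 1], .neighbor_order[i, 2])))
  n <- k_neighbors + 1
  mean_ <- Reduce(`+`, layers) / n
  ssq <- Reduce(`+`, lapply(layers, function(m) (m - mean_)^2))
  raster_grid(sqrt(ssq / (n - 1)), grid$xll, grid$yll, grid$cell_size,
              grid$nodata)
}
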