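#' Grid geometry for north-up regular rasters
#'
#' A `grid_spec` fixes the geometry every raster operation in the package
#' relies on: a planar metric CRS, north-up rows (row 1 at the top), and
#' half-open cells. Cell (r, c) spans
#' `[origin_x + (c-1)*res, origin_x + c*res)` in x and
#' `(origin_y - r*res, origin_y - (r-1)*res]` in y, so a point on an interior
#' vertical edge belongs to the right-hand cell and a point on an interior
#' horizontal edge to the lower cell.
#'
#' @param origin_x,origin_y Coordinates (m) of the outer top-left corner of
#'   cell (1, 1).
#' @param res_m Cell size in metres; must be positive.
#' @param nrows,ncols Grid dimensions; at least 1 each.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(0, 1000, res_m = 5, nrows = 200, ncols = 200)
#' @export
grid_spec <- function(origin_x, origin_y, res_m, nrows, ncols) {
  stopifnot(is.numeric(origin_x), is.numeric(origin_y), is.numeric(res_m))
  if (res_m <= 0) stop("`res_m` must be positive, got ", res_m, call. = FALSE)
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  if (nrows < 1L || ncols < 1L) {
    stop("grid must have at least one row and one column", call. = FALSE)
  }
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         res_m = as.numeric(res_m), nrows = nrows, ncols = ncols),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells @ %g m, origin (%g, %g)\n",
              x$nrows, x$ncols, x$res_m, x$origin_x, x$origin_y))
  invisible(x)
}

grid_extent <- function(g) {
  c(xmin = g$origin_x, xmax = g$origin_x + g$ncols * g$res_m,
    ymin = g$origin_y - g$nrows * g$res_m, ymax = g$origin_y)
}

grid_equal <- function(a, b, tol = 1e-9) {
  abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol &&
    abs(a$res_m - b$res_m) < tol && a$nrows == b$nrows && a$ncols == b$ncols
}

#' Cell-centre coordinates of a grid
#'
#' @param g A [grid_spec()].
#' @return A list with numeric vectors `x` (length `ncols`, west to east) and
#'   `y` (length `nrows`, north to south).
#' @keywords internal
grid_centres <- function(g) {
  list(x = g$origin_x + (seq_len(g$ncols) - 0.5) * g$res_m,
       y = g$origin_y - (seq_len(g$nrows) - 0.5) * g$res_m)
}

#' Single-band raster on a regular grid
#'
#' The package's raster container: a numeric or integer matrix laid out
#' north-up on a [grid_spec()]. Land cover uses an integer matrix of class
#' codes (see [lc_codes()]); concentrations use a numeric matrix in ug/m3.
#'
#' @param values Matrix with `grid$nrows` rows and `grid$ncols` columns.
#'   Row 1 is the northernmost row.
#' @param grid A [grid_spec()].
#' @param role One of `"landcover"`, `"concentration"`, `"delta"`,
#'   `"fraction"`. Baseline concentrations must be finite and non-negative;
#'   delta rasters may be negative.
#' @return An object of class `eq_raster`.
#' @export
eq_raster <- function(values, grid, role = c("concentration", "landcover",
                                             "delta", "fraction")) {
  role <- match.arg(role)
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (nrow(values) != grid$nrows || ncol(values) != grid$ncols) {
    stop(sprintf("values matrix is %d x %d but grid is %d x %d",
                 nrow(values), ncol(values), grid$nrows, grid$ncols),
         call. = FALSE)
  }
  if (role == "landcover") {
    known <- unname(lc_codes())
    bad <- setdiff(unique(as.vector(values)), known)
    if (length(bad)) {
      stop("unknown land-cover codes: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    storage.mode(values) <- "integer"
  } else {
    if (any(!is.finite(values))) stop("raster values must be finite", call. = FALSE)
    if (role == "concentration" && any(values < 0)) {
      stop("concentration raster has negative values", call. = FALSE)
    }
    storage.mode(values) <- "double"
  }
  structure(list(values = values, grid = grid, role = role),
            class = "eq_raster")
}

#' @export
print.eq_raster <- function(x, ...) {
  rng <- range(x$values)
  cat(sprintf("<eq_raster:%s> %d x %d @ %g m, range [%g, %g]\n",
              x$role, x$grid$nrows, x$grid$ncols, x$grid$res_m, rng[1], rng[2]))
  invisible(x)
}

#' @export
as_tibble.eq_raster <- function(x, ...) {
  ctr <- grid_centres(x$grid)
  xs <- rep(ctr$x, each = x$grid$nrows)
  ys <- rep(ctr$y, times = x$grid$ncols)
  vals <- as.vector(x$values)
  tibble::tibble(x = xs, y = ys, value = vals)
}

#' Land-cover class codes
#'
#' The categorical band of a land-cover raster uses these integer codes.
#'
#' @return Named integer vector: TREE = 1, GRASS = 2, WATER = 3,
#'   BUILDING = 4, MINERAL = 5, BARE = 6.
#' @examples
#' lc_codes()[["TREE"]]
#' @export
lc_codes <- function() {
  c(TREE = 1L, GRASS = 2L, WATER = 3L, BUILDING = 4L, MINERAL = 5L, BARE = 6L)
}

# row/col of the cell containing each point, per the half-open convention;
# returns NA for points outside the extent
point_cell <- function(g, x, y) {
  col <- floor((x - g$origin_x) / g$res_m) + 1
  row <- floor((g$origin_y - y) / g$res_m) + 1
  outside <- col < 1 | col > g$ncols | row < 1 | row > g$nrows
  col[outside] <- NA
  row[outside] <- NA
  list(row = row, col = col)
}

#' Fraction of fine land-cover cells in given classes, per coarse cell
#'
#' Computes, for every cell of a coarser target grid, the proportion of the
#' land-cover cells it contains whose class is in `codes` — e.g. the woodland
#' fraction per 3 km grid cell that drives the PM2.5 meta-models.
#'
#' @param lc Land-cover [eq_raster()].
#' @param target A [grid_spec()] whose cells exactly tile groups of `lc`
#'   cells: same origin and extent, cell size an integer multiple of the
#'   land-cover cell size.
#' @param codes Integer vector of class codes counted in the numerator.
#' @return An `eq_raster` with role `"fraction"` on `target`, values in
#'   \[0, 1\].
#' @export
class_fraction <- function(lc, target, codes) {
  stopifnot(inherits(lc, "eq_raster"), inherits(target, "grid_spec"))
  g <- lc$grid
  k <- target$res_m / g$res_m
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf("grids do not nest: target res %g m is not a multiple of land-cover res %g m",
                 target$res_m, g$res_m), call. = FALSE)
  }
  k <- as.integer(round(k))
  same_origin <- abs(target$origin_x - g$origin_x) < 1e-9 &&
    abs(target$origin_y - g$origin_y) < 1e-9
  if (!same_origin || target$nrows * k != g$nrows || target$ncols * k != g$ncols) {
    stop("grids do not nest: target grid does not tile the land-cover grid ",
         "(origins or extents differ)", call. = FALSE)
  }
  m <- matrix(as.numeric(lc$values %in% codes), g$nrows, g$ncols)
  s <- rowsum(m, rep(seq_len(target$nrows), each = k))
  s <- t(rowsum(t(s), rep(seq_len(target$ncols), each = k)))
  dimnames(s) <- NULL
  eq_raster(s / (k * k), target, role = "fraction")
}

#' Count raster cells of given classes within a radius of a point
#'
#' A cell is counted when its centre lies within Euclidean distance
#' `radius_m` of the point (boundary inclusive). Cells outside the raster
#' extent contribute nothing; a point outside the extent simply returns 0.
#' This is the primitive behind "viewable trees within 30 m" and "tree cover
#' within 300 m of a building".
#'
#' @param lc Land-cover [eq_raster()].
#' @param x,y Point coordinates (m), length 1.
#' @param radius_m Search radius in metres, positive.
#' @param codes Integer class codes to count.
#' @return A list with `count` (integer) and `area_m2` (count times cell
#'   area).
#' @export
cells_within <- function(lc, x, y, radius_m, codes) {
  stopifnot(inherits(lc, "eq_raster"), length(x) == 1L, length(y) == 1L)
  if (radius_m <= 0) stop("`radius_m` must be positive", call. = FALSE)
  g <- lc$grid
  ctr <- grid_centres(g)
  cmin <- max(1L, floor((x - radius_m - g$origin_x) / g$res_m) + 1L)
  cmax <- min(g$ncols, ceiling((x + radius_m - g$origin_x) / g$res_m))
  rmin <- max(1L, floor((g$origin_y - (y + radius_m)) / g$res_m) + 1L)
  rmax <- min(g$nrows, ceiling((g$origin_y - (y - radius_m)) / g$res_m))
  if (cmin > cmax || rmin > rmax) {
    return(list(count = 0L, area_m2 = 0))
  }
  dx2 <- (ctr$x[cmin:cmax] - x)^2
  dy2 <- (ctr$y[rmin:rmax] - y)^2
  within <- outer(dy2, dx2, `+`) <= radius_m^2
  sub <- lc$values[rmin:rmax, cmin:cmax, drop = FALSE]
  n <- sum(within & matrix(sub %in% codes, nrow(sub), ncol(sub)))
  list(count = as.integer(n), area_m2 = n * g$res_m^2)
}

#' Area (m2) of given land-cover classes within a radius of many points
#'
#' Vectorised convenience over [cells_within()] for per-building tree-cover
#' extraction.
#'
#' @inheritParams cells_within
#' @param x,y Equal-length coordinate vectors.
#' @return Numeric vector of areas in m2.
#' @export
area_within <- function(lc, x, y, radius_m, codes) {
  stopifnot(length(x) == length(y))
  vapply(seq_along(x), function(i) {
    cells_within(lc, x[i], y[i], radius_m, codes)$area_m2
  }, numeric(1))
}

#' Sample a raster at points
#'
#' Returns the value of the cell containing each point — nearest-cell
#' ("point sampling") extraction with no interpolation, following the
#' half-open cell convention (a point on an interior edge takes the value of
#' the right/lower neighbour).
#'
#' @param r An [eq_raster()].
#' @param x,y Equal-length coordinate vectors; every point must lie inside
#'   the raster extent.
#' @return Numeric vector of sampled values.
#' @export
sample_at <- function(r, x, y) {
  stopifnot(inherits(r, "eq_raster"), length(x) == length(y))
  idx <- point_cell(r$grid, x, y)
  bad <- which(is.na(idx$row) | is.na(idx$col))
  if (length(bad)) {
    stop(sprintf("point (%g, %g) lies outside the raster extent",
                 x[bad[1]], y[bad[1]]), call. = FALSE)
  }
  r$values[cbind(idx$row, idx$col)]
}

#' Bilinearly resample a raster onto a new grid
#'
#' Each target cell centre receives the bilinear interpolation of the four
#' surrounding source cell-centre values. Outside the source centre lattice
#' (within half a source cell of the extent edge) values are clamped to the
#' nearest edge/corner centre value, so constant fields are preserved exactly
#' and the output never overshoots the local neighbourhood.
#'
#' @param src Source [eq_raster()] (typically a coarse delta field).
#' @param target A [grid_spec()] whose extent lies within the source extent.
#' @return An `eq_raster` on `target` with the same role as `src`.
#' @export
bilinear_resample <- function(src, target) {
  stopifnot(inherits(src, "eq_raster"), inherits(target, "grid_spec"))
  es <- grid_extent(src$grid); et <- grid_extent(target)
  tol <- 1e-9
  if (et["xmin"] < es["xmin"] - tol || et["xmax"] > es["xmax"] + tol ||
      et["ymin"] < es["ymin"] - tol || et["ymax"] > es["ymax"] + tol) {
    stop("target extent is not contained in the source extent", call. = FALSE)
  }
  g <- src$grid
  tc <- grid_centres(target)
  # fractional position on the source centre lattice (0-based), clamped
  fx <- pmin(pmax((tc$x - g$origin_x) / g$res_m - 0.5, 0), g$ncols - 1)
  fy <- pmin(pmax((g$origin_y - tc$y) / g$res_m - 0.5, 0), g$nrows - 1)
  c0 <- pmin(floor(fx), g$ncols - 2 + (g$ncols == 1)); c0 <- pmax(c0, 0)
  r0 <- pmin(floor(fy), g$nrows - 2 + (g$nrows == 1)); r0 <- pmax(r0, 0)
  wx <- fx - c0
  wy <- fy - r0
  v <- src$values
  out <- matrix(0, target$nrows, target$ncols)
  c1 <- pmin(c0 + 1, g$ncols - 1)
  r1 <- pmin(r0 + 1, g$nrows - 1)
  for (j in seq_len(target$ncols)) {
    a <- v[cbind(r0 + 1, c0[j] + 1)]
    b <- v[cbind(r0 + 1, c1[j] + 1)]
    d <- v[cbind(r1 + 1, c0[j] + 1)]
    e <- v[cbind(r1 + 1, c1[j] + 1)]
    top <- a * (1 - wx[j]) + b * wx[j]
    bot <- d * (1 - wx[j]) + e * wx[j]
    out[, j] <- top * (1 - wy) + bot * wy
  }
  eq_raster(out, target, role = src$role)
}
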