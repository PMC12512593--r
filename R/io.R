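#' Write a raster as an ESRI ASCII grid
#'
#' Rasters are stored in the ESRI ASCII grid format (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by the value matrix, north row first — a
#' plain-text format read by every desktop GIS, whose row order matches the
#' package's north-up convention directly.
#'
#' @param r An [eq_raster()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  stopifnot(inherits(r, "eq_raster"))
  g <- r$grid
  header <- c(
    sprintf("ncols %d", g$ncols),
    sprintf("nrows %d", g$nrows),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y - g$nrows * g$res_m),
    sprintf("cellsize %.10g", g$res_m),
    "NODATA_value -9999"
  )
  body <- apply(r$values, 1L, function(row) {
    paste(formatC(row, format = "g", digits = 17), collapse = " ")
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file written by [write_ascii_grid()] or any
#'   GIS. Nodata cells are rejected: the analysis footprint must be complete.
#' @param role Raster role passed to [eq_raster()]; `"landcover"` coerces the
#'   band to integer class codes.
#' @return An [eq_raster()].
#' @export
read_ascii_grid <- function(path, role = "concentration") {
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- stats::setNames(
    vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
    tolower(vapply(kv, `[[`, character(1), 1))
  )
  ncols <- as.integer(hdr[["ncols"]]); nrows <- as.integer(hdr[["nrows"]])
  res <- hdr[["cellsize"]]
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != nrows * ncols) {
    stop("ASCII grid body has ", length(vals), " values, expected ",
         nrows * ncols, call. = FALSE)
  }
  nodata <- hdr[["nodata_value"]]
  if (any(vals == nodata)) {
    stop("ASCII grid contains nodata cells inside the analysis footprint",
         call. = FALSE)
  }
  m <- matrix(vals, nrows, ncols, byrow = TRUE)
  g <- grid_spec(origin_x = hdr[["xllcorner"]],
                 origin_y = hdr[["yllcorner"]] + nrows * res,
                 res_m = res, nrows = nrows, ncols = ncols)
  eq_raster(m, g, role = role)
}

#' Write buildings as GeoJSON points
#'
#' @param buildings Tibble with columns `id`, `x`, `y`, `population`,
#'   `zone_id`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_buildings_geojson <- function(buildings, path) {
  features <- purrr::pmap(buildings, function(id, x, y, population, zone_id, ...) {
    list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(x, y)),
      properties = list(id = id, population = population, zone_id = zone_id)
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read buildings from GeoJSON
#'
#' @param path Path to a GeoJSON FeatureCollection of points with properties
#'   `id`, `population`, `zone_id`.
#' @return Tibble with columns `id`, `x`, `y`, `population`, `zone_id`.
#' @export
read_buildings_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (length(fc$features) == 0L) {
    return(tibble::tibble(id = integer(), x = numeric(), y = numeric(),
                          population = numeric(), zone_id = integer()))
  }
  purrr::map_dfr(fc$features, function(f) {
    tibble::tibble(
      id = as.integer(f$properties$id),
      x = as.numeric(f$geometry$coordinates[[1]]),
      y = as.numeric(f$geometry$coordinates[[2]]),
      population = as.numeric(f$properties$population),
      zone_id = as.integer(f$properties$zone_id)
    )
  })
}

#' Write statistical zones as GeoJSON rectangles
#'
#' @param zones Tibble with columns `zone_id`, `xmin`, `xmax`, `ymin`,
#'   `ymax` (axis-aligned rectangular zones).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_zones_geojson <- function(zones, path) {
  features <- purrr::pmap(zones, function(zone_id, xmin, xmax, ymin, ymax, ...) {
    ring <- list(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax),
                 c(xmin, ymax), c(xmin, ymin))
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = list(zone_id = zone_id)
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read statistical zones from GeoJSON
#'
#' @param path Path to a GeoJSON FeatureCollection of axis-aligned polygon
#'   rectangles with property `zone_id`.
#' @return Tibble with columns `zone_id`, `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
read_zones_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  purrr::map_dfr(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    tibble::tibble(zone_id = as.integer(f$properties$zone_id),
                   xmin = min(xs), xmax = max(xs),
                   ymin = min(ys), ymax = max(ys))
  })
}

#' Write a synthetic city to a directory
#'
#' Emits the land cover and both PM2.5 grids as ESRI ASCII grids, buildings
#' and zones as GeoJSON, and the socio-demographic tables as CSV
#' (`zone_table.csv` with columns `zone_id`, `category`, `subcategory`,
#' `count`; `zone_income.csv` with `zone_id`, `median_income`). The file set
#' round-trips losslessly through [read_city()].
#'
#' @param city A [generate_city()] result.
#' @param dir Output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_city <- function(city, dir) {
  stopifnot(inherits(city, "synthetic_city"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ascii_grid(city$landcover, file.path(dir, "landcover.asc"))
  write_ascii_grid(city$coarse_pm25, file.path(dir, "pm25_coarse.asc"))
  write_ascii_grid(city$fine_pm25, file.path(dir, "pm25_fine.asc"))
  write_buildings_geojson(city$buildings, file.path(dir, "buildings.geojson"))
  write_zones_geojson(city$zones, file.path(dir, "zones.geojson"))
  readr::write_csv(city$zone_table, file.path(dir, "zone_table.csv"))
  readr::write_csv(city$zone_income, file.path(dir, "zone_income.csv"))
  jsonlite::write_json(city$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic city from a directory
#'
#' @param dir Directory written by [write_city()].
#' @return A `synthetic_city` object (see [generate_city()]).
#' @export
read_city <- function(dir) {
  city <- list(
    landcover = read_ascii_grid(file.path(dir, "landcover.asc"),
                                role = "landcover"),
    coarse_pm25 = read_ascii_grid(file.path(dir, "pm25_coarse.asc")),
    fine_pm25 = read_ascii_grid(file.path(dir, "pm25_fine.asc")),
    buildings = read_buildings_geojson(file.path(dir, "buildings.geojson")),
    zones = read_zones_geojson(file.path(dir, "zones.geojson")),
    zone_table = readr::read_csv(file.path(dir, "zone_table.csv"),
                                 col_types = readr::cols(
                                   zone_id = readr::col_integer(),
                                   category = readr::col_character(),
                                   subcategory = readr::col_character(),
                                   count = readr::col_double())),
    zone_income = readr::read_csv(file.path(dir, "zone_income.csv"),
                                  col_types = readr::cols(
                                    zone_id = readr::col_integer(),
                                    median_income = readr::col_double())),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE)
  )
  class(city) <- "synthetic_city"
  city
}
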