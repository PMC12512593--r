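#' Configure a synthetic city
#'
#' Defines the study conditions for [generate_city()]: a square domain on a
#' planar metric CRS with a 5 m categorical land-cover grid, a 1 km fine and
#' a 3 km coarse PM2.5 grid, rectangular statistical zones, and radial
#' spatial gradients (centre value + slope per metre of distance from the
#' domain centre + Gaussian noise) in baseline PM2.5, tree-cover probability
#' and zone median income. Subgroup composition per zone follows a softmax
#' link on standardised zone income, so the sign of each `loading` plants a
#' monotone income-composition relationship the pipeline should recover.
#'
#' @param extent_m Side of the square domain (m); must be divisible by
#'   `coarse_res_m`.
#' @param landcover_res_m,fine_res_m,coarse_res_m Cell sizes (m); each
#'   coarser grid must be an integer multiple of the next finer one.
#' @param n_zones Number of statistical zones (>= 3), tessellated as a
#'   near-square grid of rectangles.
#' @param n_buildings Number of residential buildings, placed uniformly.
#' @param seed Integer root seed; each random field draws from its own child
#'   stream so changing one gradient leaves the others untouched.
#' @param baseline_pm25,tree_fraction,income Radial gradient specs: lists
#'   with `centre` (value at the domain centre), `slope` (change per metre
#'   of radial distance) and `noise_sd`. Units: ug/m3 for PM2.5, probability
#'   for tree fraction, currency units for income.
#' @param subgroups Per-category composition spec: for each of `age`,
#'   `citizenship`, `employment`, `education`, a list with `subcats`
#'   (labels), `base` (city-wide shares summing to 1), `loading`
#'   (per-subcategory coefficients on standardised zone income) and
#'   `noise_sd` (log-scale compositional noise).
#' @param building_pop Log-normal parameters (`meanlog`, `sdlog`) for
#'   persons per building.
#' @param class_mix Shares of GRASS, MINERAL, WATER, BARE among cells that
#'   are neither tree nor building; must sum to 1.
#' @return An object of class `city_config`.
#' @export
city_config <- function(extent_m = 6000,
                        landcover_res_m = 5,
                        fine_res_m = 1000,
                        coarse_res_m = 3000,
                        n_zones = 25,
                        n_buildings = 2000,
                        seed = 1L,
                        baseline_pm25 = list(centre = 12, slope = -4e-4, noise_sd = 0.1),
                        tree_fraction = list(centre = 0.10, slope = 2e-5, noise_sd = 0.02),
                        income = list(centre = 30000, slope = 1.5, noise_sd = 1000),
                        subgroups = default_subgroups(),
                        building_pop = list(meanlog = log(20), sdlog = 0.8),
                        class_mix = c(GRASS = 0.45, MINERAL = 0.35,
                                      WATER = 0.05, BARE = 0.15)) {
  check_nesting <- function(coarse, fine, what) {
    if (fine <= 0 || coarse <= 0) {
      stop("resolutions must be positive (", what, ")", call. = FALSE)
    }
    if (abs(coarse / fine - round(coarse / fine)) > 1e-9) {
      stop(sprintf("resolution nesting violated: %s (%g m is not a multiple of %g m)",
                   what, coarse, fine), call. = FALSE)
    }
  }
  check_nesting(extent_m, coarse_res_m, "extent_m / coarse_res_m")
  check_nesting(coarse_res_m, fine_res_m, "coarse_res_m / fine_res_m")
  check_nesting(fine_res_m, landcover_res_m, "fine_res_m / landcover_res_m")
  if (n_zones < 3) stop("`n_zones` must be at least 3", call. = FALSE)
  stopifnot(abs(sum(class_mix) - 1) < 1e-9)
  structure(
    list(extent_m = extent_m, landcover_res_m = landcover_res_m,
         fine_res_m = fine_res_m, coarse_res_m = coarse_res_m,
         n_zones = as.integer(n_zones), n_buildings = as.integer(n_buildings),
         seed = as.integer(seed),
         baseline_pm25 = baseline_pm25, tree_fraction = tree_fraction,
         income = income, subgroups = subgroups,
         building_pop = building_pop, class_mix = class_mix),
    class = "city_config"
  )
}

#' Default subgroup composition specification
#'
#' City-wide base shares loosely follow a European city age/education
#' structure; loadings encode the usual socio-economic correlations
#' (higher-income zones hold more citizens, employed and
#' tertiary-educated residents, slightly more over-65s and fewer children).
#'
#' @return Named list of per-category composition specs (see
#'   [city_config()]).
#' @export
default_subgroups <- function() {
  list(
    age = list(subcats = c("<18", "18-64", ">=65"),
               base = c(0.20, 0.64, 0.16),
               loading = c(-0.15, 0.05, 0.15), noise_sd = 0.05),
    citizenship = list(subcats = c("citizen", "non_citizen"),
                       base = c(0.88, 0.12),
                       loading = c(0.4, -0.4), noise_sd = 0.05),
    employment = list(subcats = c("employed", "unemployed"),
                      base = c(0.92, 0.08),
                      loading = c(0.3, -0.3), noise_sd = 0.05),
    education = list(subcats = c("primary", "secondary", "tertiary"),
                     base = c(0.25, 0.40, 0.35),
                     loading = c(-0.4, 0.0, 0.4), noise_sd = 0.05)
  )
}

#' Paris-like and Aarhus-like study configurations
#'
#' Two preset spatial patterns for planted-gradient recovery. In the
#' Paris-like city, income rises with distance from the centre while PM2.5
#' falls with distance, co-locating low income with poor air (bottom income
#' quintile more exposed). The Aarhus-like city inverts the income gradient:
#' the affluent live in the dense, polluted centre (top quintile more
#' exposed).
#'
#' @param seed Integer root seed.
#' @param noise_sd Common noise level applied to the income and PM2.5
#'   gradients; 0 gives noiseless planted gradients.
#' @param ... Further arguments passed to [city_config()].
#' @return A `city_config`.
#' @export
city_config_paris_like <- function(seed = 1L, noise_sd = 0, ...) {
  city_config(seed = seed,
              baseline_pm25 = list(centre = 15.5, slope = -4e-4, noise_sd = noise_sd),
              income = list(centre = 22000, slope = 2.5, noise_sd = noise_sd * 5000),
              ...)
}

#' @rdname city_config_paris_like
#' @export
city_config_aarhus_like <- function(seed = 1L, noise_sd = 0, ...) {
  city_config(seed = seed,
              baseline_pm25 = list(centre = 10.8, slope = -2e-4, noise_sd = noise_sd),
              income = list(centre = 34000, slope = -2.5, noise_sd = noise_sd * 5000),
              ...)
}

# deterministic child seed per random field, so streams are independent
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + k * 7L
}

# radial gradient field evaluated at coordinates, without noise
radial_field <- function(spec, x, y, cx, cy) {
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  spec$centre + spec$slope * d
}

#' Generate a synthetic city
#'
#' Builds the complete input set for the exposure-equity pipeline: a 5 m
#' land-cover raster, residential building points with populations, a
#' rectangular zone tessellation with fractional subgroup counts and median
#' income per zone, and coarse (3 km) and fine (1 km) baseline PM2.5
#' rasters. Deterministic for a fixed config and seed. The returned `truth`
#' element records the planted gradient slopes for recovery tests.
#'
#' @param config A [city_config()].
#' @return An object of class `synthetic_city`: a list with elements
#'   `landcover`, `buildings`, `zones`, `zone_table`, `zone_income`,
#'   `coarse_pm25`, `fine_pm25`, `truth`.
#' @examples
#' city <- generate_city(city_config(n_buildings = 50, n_zones = 4, seed = 7))
#' city$buildings
#' @export
generate_city <- function(config) {
  stopifnot(inherits(config, "city_config"))
  ext <- config$extent_m
  cx <- cy <- ext / 2
  codes <- lc_codes()

  lg <- grid_spec(0, ext, config$landcover_res_m,
                  ext / config$landcover_res_m, ext / config$landcover_res_m)
  fg <- grid_spec(0, ext, config$fine_res_m,
                  ext / config$fine_res_m, ext / config$fine_res_m)
  cg <- grid_spec(0, ext, config$coarse_res_m,
                  ext / config$coarse_res_m, ext / config$coarse_res_m)

  # --- land cover: tree probability gradient, remainder from class_mix ----
  ctr <- grid_centres(lg)
  xs <- rep(ctr$x, each = lg$nrows)
  ys <- rep(ctr$y, times = lg$ncols)
  p_tree <- radial_field(config$tree_fraction, xs, ys, cx, cy)
  set.seed(child_seed(config$seed, 1L))
  if (config$tree_fraction$noise_sd > 0) {
    p_tree <- p_tree + stats::rnorm(length(p_tree), 0, config$tree_fraction$noise_sd)
  }
  p_tree <- pmin(pmax(p_tree, 0), 1)
  set.seed(child_seed(config$seed, 2L))
  is_tree <- stats::runif(length(p_tree)) < p_tree
  other <- sample(codes[names(config$class_mix)], length(p_tree),
                  replace = TRUE, prob = config$class_mix)
  lc_vals <- ifelse(is_tree, codes[["TREE"]], other)
  lc <- matrix(as.integer(lc_vals), lg$nrows, lg$ncols)

  # --- zones: near-square rectangular tessellation ------------------------
  zr <- floor(sqrt(config$n_zones))
  while (config$n_zones %% zr != 0L) zr <- zr - 1L
  zc <- config$n_zones %/% zr
  zw <- ext / zc; zh <- ext / zr
  zones <- tidyr::expand_grid(zrow = seq_len(zr), zcol = seq_len(zc)) |>
    dplyr::mutate(
      zone_id = dplyr::row_number(),
      xmin = (.data$zcol - 1) * zw, xmax = .data$zcol * zw,
      ymin = (.data$zrow - 1) * zh, ymax = .data$zrow * zh
    ) |>
    dplyr::select("zone_id", "xmin", "xmax", "ymin", "ymax")

  # --- buildings: uniform placement, log-normal population ----------------
  set.seed(child_seed(config$seed, 3L))
  nb <- config$n_buildings
  bx <- stats::runif(nb, 0, ext)
  by <- stats::runif(nb, 0, ext)
  bpop <- stats::rlnorm(nb, config$building_pop$meanlog, config$building_pop$sdlog)
  # zone_id numbering matches the row-major tessellation above
  bz <- as.integer(pmin(floor(by / zh), zr - 1) * zc + pmin(floor(bx / zw), zc - 1) + 1)
  buildings <- tibble::tibble(id = seq_len(nb), x = bx, y = by,
                              population = bpop, zone_id = bz)
  if (nb > 0) {
    cell <- point_cell(lg, bx, by)
    lc[cbind(cell$row, cell$col)] <- codes[["BUILDING"]]
  }
  landcover <- eq_raster(lc, lg, role = "landcover")

  # --- zone income gradient ----------------------------------------------
  zcx <- (zones$xmin + zones$xmax) / 2
  zcy <- (zones$ymin + zones$ymax) / 2
  set.seed(child_seed(config$seed, 4L))
  med_inc <- radial_field(config$income, zcx, zcy, cx, cy)
  if (config$income$noise_sd > 0) {
    med_inc <- med_inc + stats::rnorm(length(med_inc), 0, config$income$noise_sd)
  }
  zone_income <- tibble::tibble(zone_id = zones$zone_id,
                                median_income = med_inc)

  # --- subgroup counts: softmax link on standardised income ---------------
  zone_pop <- buildings |>
    dplyr::group_by(.data$zone_id) |>
    dplyr::summarise(population = sum(.data$population)) |>
    dplyr::right_join(tibble::tibble(zone_id = zones$zone_id), by = "zone_id") |>
    dplyr::mutate(population = tidyr::replace_na(.data$population, 0)) |>
    dplyr::arrange(.data$zone_id)
  z_std <- if (stats::sd(med_inc) > 0) {
    (med_inc - mean(med_inc)) / stats::sd(med_inc)
  } else rep(0, length(med_inc))

  set.seed(child_seed(config$seed, 5L))
  zone_table <- purrr::imap_dfr(config$subgroups, function(sg, cat) {
    purrr::map_dfr(seq_along(zones$zone_id), function(i) {
      eps <- if (sg$noise_sd > 0) {
        stats::rnorm(length(sg$subcats), 0, sg$noise_sd)
      } else rep(0, length(sg$subcats))
      w <- sg$base * exp(sg$loading * z_std[i] + eps)
      p <- w / sum(w)
      tibble::tibble(zone_id = zones$zone_id[i], category = cat,
                     subcategory = sg$subcats,
                     count = p * zone_pop$population[i])
    })
  })
  zone_table <- dplyr::bind_rows(
    tibble::tibble(zone_id = zone_pop$zone_id, category = "population",
                   subcategory = "all", count = zone_pop$population),
    zone_table
  ) |> dplyr::arrange(.data$zone_id, .data$category, .data$subcategory)

  # --- PM2.5 gradients: fine (1 km) and coarse (3 km) baselines -----------
  make_pm <- function(g, stream) {
    gc <- grid_centres(g)
    px <- rep(gc$x, each = g$nrows)
    py <- rep(gc$y, times = g$ncols)
    v <- radial_field(config$baseline_pm25, px, py, cx, cy)
    set.seed(child_seed(config$seed, stream))
    if (config$baseline_pm25$noise_sd > 0) {
      v <- v + stats::rnorm(length(v), 0, config$baseline_pm25$noise_sd)
    }
    eq_raster(matrix(pmax(v, 0.1), g$nrows, g$ncols), g, role = "concentration")
  }
  fine_pm25 <- make_pm(fg, 6L)
  coarse_pm25 <- make_pm(cg, 7L)

  city <- list(
    landcover = landcover, buildings = buildings, zones = zones,
    zone_table = zone_table, zone_income = zone_income,
    coarse_pm25 = coarse_pm25, fine_pm25 = fine_pm25,
    truth = list(seed = config$seed,
                 pm25_slope = config$baseline_pm25$slope,
                 income_slope = config$income$slope,
                 tree_slope = config$tree_fraction$slope)
  )
  class(city) <- "synthetic_city"
  city
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat(sprintf("<synthetic_city> %d x %d land-cover cells @ %g m, %d zones, %d buildings\n",
              x$landcover$grid$nrows, x$landcover$grid$ncols,
              x$landcover$grid$res_m, nrow(x$zones), nrow(x$buildings)))
  invisible(x)
}
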