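#' Disaggregate zone subgroup counts to buildings
#'
#' Dasymetric disaggregation: for a building `u` in zone `z` and subgroup
#' `a`, the building-level subgroup population is
#' `count[a, z] / population[z] * population[u]` — the zone subgroup
#' proportion scaled by the building's total residents. Weights stay
#' fractional throughout; rounding to whole persons would break mass
#' conservation.
#'
#' @param zone_table Tidy zone table with columns `zone_id`, `category`,
#'   `subcategory`, `count`, including a `population`/`all` row per zone
#'   holding the zone population total.
#' @param buildings Tibble with `id`, `population`, `zone_id`.
#' @return Long tibble with columns `id`, `zone_id`, `category`,
#'   `subcategory`, `population` (the building-level subgroup population).
#' @export
disaggregate <- function(zone_table, buildings) {
  zone_pop <- zone_table |>
    dplyr::filter(.data$category == "population") |>
    dplyr::select("zone_id", zone_pop = "count")
  counts <- zone_table |>
    dplyr::filter(.data$category != "population")
  missing_pop <- setdiff(unique(buildings$zone_id), zone_pop$zone_id)
  if (length(missing_pop)) {
    stop("zones with buildings but no recorded population: ",
         paste(missing_pop, collapse = ", "), call. = FALSE)
  }
  occupied <- buildings |>
    dplyr::distinct(.data$zone_id) |>
    dplyr::left_join(zone_pop, by = "zone_id")
  if (any(occupied$zone_pop <= 0)) {
    stop("zone(s) contain buildings but have zero recorded population: ",
         paste(occupied$zone_id[occupied$zone_pop <= 0], collapse = ", "),
         call. = FALSE)
  }
  buildings |>
    dplyr::select("id", "zone_id", building_pop = "population") |>
    dplyr::inner_join(counts, by = "zone_id",
                      relationship = "many-to-many") |>
    dplyr::inner_join(zone_pop, by = "zone_id") |>
    dplyr::mutate(population = .data$count / .data$zone_pop * .data$building_pop) |>
    dplyr::select("id", "zone_id", "category", "subcategory", "population")
}

#' Population-weighted mean
#'
#' The exposure statistic: each building's value weighted by its (subgroup)
#' population, `sum(w * v) / sum(w)`.
#'
#' @param values Finite numeric vector (e.g. sampled PM2.5 per building).
#' @param weights Non-negative weights of the same length with a positive
#'   sum.
#' @return Scalar weighted mean.
#' @export
pop_weighted_mean <- function(values, weights) {
  stopifnot(length(values) == length(weights))
  if (any(!is.finite(values)) || any(!is.finite(weights))) {
    stop("values and weights must be finite", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  sw <- sum(weights)
  if (sw == 0) {
    stop("subgroup absent: total weight is zero, exposure undefined",
         call. = FALSE)
  }
  sum(weights * values) / sw
}

#' Classify zones into income quintile classes
#'
#' Zones are ranked by median income (ties broken by ascending zone id) and
#' the cumulative building population is partitioned into fifths; a zone
#' belongs to the quintile containing the midpoint of its population mass,
#' so each quintile holds as close as possible to 20% of the total
#' population. Classes: bottom quintile, middle quintiles (2-4), top
#' quintile. All buildings inherit their zone's class.
#'
#' @param zone_income Tibble with `zone_id`, `median_income`.
#' @param buildings Tibble with `population`, `zone_id`.
#' @return Tibble with `zone_id`, `median_income`, `zone_pop`, `quintile`,
#'   `income_class` (`bottom_quintile`, `middle_quintiles`,
#'   `top_quintile`).
#' @export
income_classes <- function(zone_income, buildings) {
  if (length(unique(zone_income$median_income)) < 2L) {
    stop("all zone median incomes are identical: quintiles undefined",
         call. = FALSE)
  }
  pops <- buildings |>
    dplyr::group_by(.data$zone_id) |>
    dplyr::summarise(zone_pop = sum(.data$population))
  z <- zone_income |>
    dplyr::left_join(pops, by = "zone_id") |>
    dplyr::mutate(zone_pop = dplyr::coalesce(.data$zone_pop, 0)) |>
    dplyr::arrange(.data$median_income, .data$zone_id)
  total <- sum(z$zone_pop)
  if (total <= 0) stop("no building population to classify", call. = FALSE)
  mid <- cumsum(z$zone_pop) - z$zone_pop / 2
  q <- pmin(pmax(ceiling(mid / (total / 5)), 1L), 5L)
  z |>
    dplyr::mutate(
      quintile = as.integer(q),
      income_class = dplyr::case_when(
        quintile == 1L ~ "bottom_quintile",
        quintile == 5L ~ "top_quintile",
        TRUE ~ "middle_quintiles"
      )
    ) |>
    dplyr::arrange(.data$zone_id)
}

income_subcats <- c("bottom_quintile", "middle_quintiles", "top_quintile")

#' Population-weighted exposure and tree cover per subgroup
#'
#' Builds the central result table: for every socio-demographic subgroup,
#' the population-weighted mean PM2.5 concentration (baseline and greening
#' scenario, sampled at each building from the fine surfaces) and the
#' population-weighted tree cover within `tree_radius_m` of each building
#' (in hectares), with the scenario-minus-baseline change for both. Income
#' rows weight by total building population within each income class (zone
#' income is a single median, so no per-person income counts exist); a
#' `total` row weights by total building population.
#'
#' @param buildings Tibble with `id`, `x`, `y`, `population`, `zone_id`.
#' @param subgroup_pops Building-level subgroup populations from
#'   [disaggregate()].
#' @param surfaces A [scenario_surfaces()] result.
#' @param lc_current,lc_scenario Land-cover rasters for the two scenarios.
#' @param zone_income Tibble with `zone_id`, `median_income` for income
#'   classification; omit (`NULL`) to skip income rows.
#' @param tree_radius_m Tree-cover search radius around each building (m).
#' @return A tibble of class `exposure_table` with columns `category`,
#'   `subcategory`, `population`, `pm25_baseline`, `pm25_scenario`,
#'   `pm25_delta`, `tree_ha_baseline`, `tree_ha_scenario`, `tree_ha_delta`.
#' @export
exposure_table <- function(buildings, subgroup_pops, surfaces,
                           lc_current, lc_scenario,
                           zone_income = NULL, tree_radius_m = 300) {
  tree <- lc_codes()[["TREE"]]
  per_building <- buildings |>
    dplyr::mutate(
      pm25_baseline = sample_at(surfaces$pm25_current_fine, .data$x, .data$y),
      pm25_scenario = sample_at(surfaces$pm25_scenario_fine, .data$x, .data$y),
      tree_ha_baseline = area_within(lc_current, .data$x, .data$y,
                                     tree_radius_m, tree) / 1e4,
      tree_ha_scenario = area_within(lc_scenario, .data$x, .data$y,
                                     tree_radius_m, tree) / 1e4
    )

  row_for <- function(category, subcategory, weights) {
    tibble::tibble(
      category = category, subcategory = subcategory,
      population = sum(weights),
      pm25_baseline = pop_weighted_mean(per_building$pm25_baseline, weights),
      pm25_scenario = pop_weighted_mean(per_building$pm25_scenario, weights),
      tree_ha_baseline = pop_weighted_mean(per_building$tree_ha_baseline, weights),
      tree_ha_scenario = pop_weighted_mean(per_building$tree_ha_scenario, weights)
    )
  }

  sub_rows <- subgroup_pops |>
    dplyr::distinct(.data$category, .data$subcategory) |>
    purrr::pmap_dfr(function(category, subcategory) {
      sp <- subgroup_pops |>
        dplyr::filter(.data$category == !!category,
                      .data$subcategory == !!subcategory)
      m <- match(per_building$id, sp$id)
      w <- ifelse(is.na(m), 0, sp$population[m])
      row_for(category, subcategory, w)
    })

  income_rows <- NULL
  if (!is.null(zone_income)) {
    classes <- income_classes(zone_income, buildings)
    joined <- per_building |>
      dplyr::left_join(dplyr::select(classes, "zone_id", "income_class"),
                       by = "zone_id")
    income_rows <- purrr::map_dfr(income_subcats, function(s) {
      w <- ifelse(joined$income_class == s, joined$population, 0)
      row_for("income", s, w)
    })
  }

  total_row <- row_for("total", "total", per_building$population)

  out <- dplyr::bind_rows(sub_rows, income_rows, total_row) |>
    dplyr::mutate(
      pm25_delta = .data$pm25_scenario - .data$pm25_baseline,
      tree_ha_delta = .data$tree_ha_scenario - .data$tree_ha_baseline
    ) |>
    dplyr::select("category", "subcategory", "population",
                  "pm25_baseline", "pm25_scenario", "pm25_delta",
                  "tree_ha_baseline", "tree_ha_scenario", "tree_ha_delta")
  class(out) <- c("exposure_table", class(out))
  out
}

#' Format an exposure table for display
#'
#' Rounds concentrations and tree cover to 2 decimals and changes to 3
#' decimals, the conventional table precision; the unrounded table remains
#' the machine-readable output.
#'
#' @param t An [exposure_table()].
#' @return A tibble with display-rounded columns.
#' @export
format_exposure_table <- function(t) {
  t |>
    dplyr::mutate(
      dplyr::across(c("pm25_baseline", "pm25_scenario",
                      "tree_ha_baseline", "tree_ha_scenario"),
                    ~ round(.x, 2)),
      dplyr::across(c("pm25_delta", "tree_ha_delta"), ~ round(.x, 3))
    )
}
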