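make_zone_table <- function(zone_id, pop, counts) {
  dplyr::bind_rows(
    tibble::tibble(zone_id = zone_id, category = "population",
                   subcategory = "all", count = pop),
    counts
  )
}

test_that("disaggregation scales zone proportions by building population", {
  zt <- make_zone_table(1L, 100,
                        tibble::tibble(zone_id = 1L, category = "employment",
                                       subcategory = c("employed", "unemployed"),
                                       count = c(40, 60)))
  b <- tibble::tibble(id = 1L, population = 10, zone_id = 1L)
  d <- disaggregate(zt, b)
  expect_equal(d$population[d$subcategory == "employed"], 4.0)
  expect_equal(d$population[d$subcategory == "unemployed"], 6.0)

  # one building holding the whole zone population inherits the counts
  b2 <- tibble::tibble(id = 1L, population = 100, zone_id = 1L)
  d2 <- disaggregate(zt, b2)
  expect_equal(d2$population[d2$subcategory == "employed"], 40)
})

test_that("disaggregation conserves zone subgroup totals", {
  city <- generate_city(city_config(n_zones = 20, n_buildings = 300, seed = 9,
                                    extent_m = 6000))
  d <- disaggregate(city$zone_table, city$buildings)
  sums <- d |>
    dplyr::group_by(zone_id, category, subcategory) |>
    dplyr::summarise(s = sum(population), .groups = "drop")
  zt <- city$zone_table |>
    dplyr::filter(category != "population") |>
    dplyr::inner_join(sums, by = c("zone_id", "category", "subcategory"))
  # building populations define the zone populations, so totals match exactly
  expect_equal(zt$s, zt$count, tolerance = 1e-9)
})

test_that("disaggregation rejects buildings in zones without population", {
  zt <- make_zone_table(1L, 0,
                        tibble::tibble(zone_id = 1L, category = "employment",
                                       subcategory = c("employed", "unemployed"),
                                       count = c(0, 0)))
  b <- tibble::tibble(id = 1L, population = 5, zone_id = 1L)
  expect_error(disaggregate(zt, b), "zero recorded population")
  expect_error(disaggregate(zt, tibble::tibble(id = 1L, population = 5,
                                               zone_id = 2L)),
               "no recorded population")
})

test_that("pop_weighted_mean implements sum(w v)/sum(w) with guards", {
  expect_equal(pop_weighted_mean(15.30, 7), 15.30)
  expect_equal(pop_weighted_mean(c(10, 20), c(1, 3)), 17.5)
  expect_equal(pop_weighted_mean(rep(4.2, 5), runif(5, 0.1, 2)), 4.2)
  expect_error(pop_weighted_mean(c(1, 2), c(0, 0)), "subgroup absent")
  expect_error(pop_weighted_mean(c(1, NA), c(1, 1)), "finite")
  expect_error(pop_weighted_mean(c(1, 2), c(-1, 2)), "non-negative")
})

test_that("income quintiles partition cumulative building population", {
  # five equal-population zones with distinct incomes: one zone per quintile
  zi <- tibble::tibble(zone_id = 1:5, median_income = c(30, 10, 50, 20, 40))
  b <- tibble::tibble(id = 1:5, population = rep(100, 5), zone_id = 1:5)
  cl <- income_classes(zi, b)
  expect_identical(cl$quintile[order(cl$median_income)], 1:5)
  expect_identical(cl$income_class[cl$median_income == 10], "bottom_quintile")
  expect_identical(cl$income_class[cl$median_income == 50], "top_quintile")
  expect_identical(sum(cl$income_class == "middle_quintiles"), 3L)

  # tied incomes order by ascending zone id
  zi2 <- tibble::tibble(zone_id = c(2L, 1L), median_income = c(10, 10))
  b2 <- tibble::tibble(id = 1:2, population = c(1, 1), zone_id = c(1L, 2L))
  expect_error(income_classes(zi2, b2), "identical")
  zi3 <- tibble::tibble(zone_id = 1:3, median_income = c(10, 10, 99))
  b3 <- tibble::tibble(id = 1:3, population = c(2, 2, 2), zone_id = 1:3)
  cl3 <- income_classes(zi3, b3)
  expect_lt(cl3$quintile[cl3$zone_id == 1], cl3$quintile[cl3$zone_id == 2])
})

test_that("quintile class populations approximate a 20/60/20 split", {
  city <- generate_city(city_config(n_zones = 25, n_buildings = 1000, seed = 14))
  cl <- income_classes(city$zone_income, city$buildings)
  shares <- cl |>
    dplyr::group_by(income_class) |>
    dplyr::summarise(p = sum(zone_pop)) |>
    dplyr::mutate(p = p / sum(p))
  max_zone <- max(cl$zone_pop) / sum(cl$zone_pop)
  expect_lt(abs(shares$p[shares$income_class == "bottom_quintile"] - 0.20), max_zone)
  expect_lt(abs(shares$p[shares$income_class == "top_quintile"] - 0.20), max_zone)
  expect_lt(abs(shares$p[shares$income_class == "middle_quintiles"] - 0.60),
            2 * max_zone)
})

test_that("exposure_table matches the brute-force double loop on a small city", {
  city <- generate_city(small_city_config(seed = 19))
  grn <- apply_330(city$landcover, city$buildings, city$zones)
  surf <- scenario_surfaces(meta_model_aarhus(), city$landcover,
                            grn$landcover_scenario, city$coarse_pm25$grid,
                            city$coarse_pm25, city$fine_pm25)
  sub <- disaggregate(city$zone_table, city$buildings)
  got <- exposure_table(city$buildings, sub, surf, city$landcover,
                        grn$landcover_scenario, zone_income = city$zone_income,
                        tree_radius_m = 150)
  want <- bf_exposure_table(city, surf, city$landcover,
                            grn$landcover_scenario, tree_radius_m = 150)
  key <- paste(want$category, want$subcategory)
  got <- got[match(key, paste(got$category, got$subcategory)), ]
  for (col in c("population", "pm25_baseline", "pm25_scenario", "pm25_delta",
                "tree_ha_baseline", "tree_ha_scenario", "tree_ha_delta")) {
    expect_equal(got[[col]], want[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("subgroups partition the population: totals and scale invariance", {
  city <- generate_city(small_city_config(seed = 23))
  surf <- scenario_surfaces(meta_model_aarhus(), city$landcover, city$landcover,
                            city$coarse_pm25$grid, city$coarse_pm25,
                            city$fine_pm25)
  sub <- disaggregate(city$zone_table, city$buildings)
  t1 <- exposure_table(city$buildings, sub, surf, city$landcover,
                       city$landcover, zone_income = city$zone_income,
                       tree_radius_m = 100)
  tot <- t1[t1$category == "total", ]
  for (cat in c("age", "citizenship", "employment", "education", "income")) {
    rows <- t1[t1$category == cat, ]
    expect_equal(sum(rows$population), tot$population, tolerance = 1e-9)
    expect_equal(sum(rows$population * rows$pm25_baseline),
                 tot$population * tot$pm25_baseline, tolerance = 1e-9)
    expect_equal(sum(rows$population * rows$tree_ha_scenario),
                 tot$population * tot$tree_ha_scenario, tolerance = 1e-9)
  }

  # scaling every building population leaves weighted means unchanged
  b2 <- dplyr::mutate(city$buildings, population = population * 7)
  zt2 <- dplyr::mutate(city$zone_table, count = count * 7)
  sub2 <- disaggregate(zt2, b2)
  t2 <- exposure_table(b2, sub2, surf, city$landcover, city$landcover,
                       zone_income = city$zone_income, tree_radius_m = 100)
  expect_equal(t2$pm25_baseline, t1$pm25_baseline, tolerance = 1e-9)
  expect_equal(t2$tree_ha_baseline, t1$tree_ha_baseline, tolerance = 1e-9)
})

test_that("uniform surfaces give every subgroup the same exposure", {
  city <- generate_city(small_city_config(
    seed = 31, baseline_pm25 = list(centre = 9, slope = 0, noise_sd = 0)))
  surf <- scenario_surfaces(meta_model_aarhus(), city$landcover, city$landcover,
                            city$coarse_pm25$grid, city$coarse_pm25,
                            city$fine_pm25)
  sub <- disaggregate(city$zone_table, city$buildings)
  t1 <- exposure_table(city$buildings, sub, surf, city$landcover,
                       city$landcover, zone_income = city$zone_income,
                       tree_radius_m = 100)
  expect_equal(diff(range(t1$pm25_baseline)), 0, tolerance = 1e-12)
  expect_equal(diff(range(t1$pm25_delta)), 0, tolerance = 1e-12)
})

test_that("display formatting rounds to table precision", {
  t <- tibble::tibble(category = "total", subcategory = "total",
                      population = 1, pm25_baseline = 10.6449,
                      pm25_scenario = 10.6101, pm25_delta = -0.03478,
                      tree_ha_baseline = 3.0712, tree_ha_scenario = 3.5049,
                      tree_ha_delta = 0.43371)
  f <- format_exposure_table(t)
  expect_equal(f$pm25_baseline, 10.64)
  expect_equal(f$pm25_delta, -0.035)
  expect_equal(f$tree_ha_delta, 0.434)
})
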