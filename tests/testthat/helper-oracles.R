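# Independent brute-force oracles and small fixture builders. These are kept
# deliberately naive (plain loops, direct index arithmetic) so they share no
# code path with the implementations they check.

# uniform land-cover raster of one class
const_lc <- function(code, nrows = 40, ncols = 40, res = 5, origin_y = NULL) {
  if (is.null(origin_y)) origin_y <- nrows * res
  eq_raster(matrix(as.integer(code), nrows, ncols),
            grid_spec(0, origin_y, res, nrows, ncols), role = "landcover")
}

const_conc <- function(value, nrows = 4, ncols = 4, res = 1000, origin_y = NULL) {
  if (is.null(origin_y)) origin_y <- nrows * res
  eq_raster(matrix(value, nrows, ncols),
            grid_spec(0, origin_y, res, nrows, ncols))
}

# random land cover with a given tree probability
random_lc <- function(nrows, ncols, res = 5, p_tree = 0.3, seed = 1) {
  set.seed(seed)
  codes <- lc_codes()
  v <- matrix(sample(codes, nrows * ncols, replace = TRUE,
                     prob = c(p_tree, rep((1 - p_tree) / 5, 5))),
              nrows, ncols)
  eq_raster(v, grid_spec(0, nrows * res, res, nrows, ncols), role = "landcover")
}

# brute force: count cells of given codes whose centre is within radius,
# scanning every cell of the raster
bf_cells_within <- function(lc, x, y, radius, codes) {
  g <- lc$grid
  n <- 0L
  for (r in seq_len(g$nrows)) {
    cy <- g$origin_y - (r - 0.5) * g$res_m
    for (c in seq_len(g$ncols)) {
      cx <- g$origin_x + (c - 0.5) * g$res_m
      if ((cx - x)^2 + (cy - y)^2 <= radius^2 && lc$values[r, c] %in% codes) {
        n <- n + 1L
      }
    }
  }
  list(count = n, area_m2 = n * g$res_m^2)
}

# brute force point sampling by direct index arithmetic
bf_sample_at <- function(r, x, y) {
  g <- r$grid
  col <- floor((x - g$origin_x) / g$res_m) + 1
  row <- floor((g$origin_y - y) / g$res_m) + 1
  r$values[cbind(row, col)]
}

# brute-force class fraction: loop over target cells and count member cells
bf_class_fraction <- function(lc, target, codes) {
  k <- as.integer(round(target$res_m / lc$grid$res_m))
  out <- matrix(NA_real_, target$nrows, target$ncols)
  for (R in seq_len(target$nrows)) {
    for (C in seq_len(target$ncols)) {
      block <- lc$values[((R - 1) * k + 1):(R * k), ((C - 1) * k + 1):(C * k)]
      out[R, C] <- sum(block %in% codes) / (k * k)
    }
  }
  out
}

# brute-force exposure table: double loop over subgroups x buildings, with
# subgroup weights recomputed from the raw zone table and values sampled and
# tree areas enumerated by direct index arithmetic
bf_exposure_table <- function(city, surfaces, lc_current, lc_scenario,
                              tree_radius_m = 300) {
  b <- city$buildings
  zt <- city$zone_table
  zpop <- zt[zt$category == "population", ]
  zone_pop <- stats::setNames(zpop$count, zpop$zone_id)

  bf_tree_area <- function(lc, x, y) {
    g <- lc$grid
    cmin <- max(1L, floor((x - tree_radius_m - g$origin_x) / g$res_m) + 1L)
    cmax <- min(g$ncols, ceiling((x + tree_radius_m - g$origin_x) / g$res_m))
    rmin <- max(1L, floor((g$origin_y - y - tree_radius_m) / g$res_m) + 1L)
    rmax <- min(g$nrows, ceiling((g$origin_y - y + tree_radius_m) / g$res_m))
    n <- 0L
    for (r in rmin:rmax) {
      cy <- g$origin_y - (r - 0.5) * g$res_m
      cx <- g$origin_x + (cmin:cmax - 0.5) * g$res_m
      hit <- (cx - x)^2 + (cy - y)^2 <= tree_radius_m^2 &
        lc$values[r, cmin:cmax] == lc_codes()[["TREE"]]
      n <- n + sum(hit)
    }
    n * g$res_m^2
  }

  pm_b <- bf_sample_at(surfaces$pm25_current_fine, b$x, b$y)
  pm_s <- bf_sample_at(surfaces$pm25_scenario_fine, b$x, b$y)
  tr_b <- vapply(seq_len(nrow(b)),
                 function(i) bf_tree_area(lc_current, b$x[i], b$y[i]),
                 numeric(1)) / 1e4
  tr_s <- vapply(seq_len(nrow(b)),
                 function(i) bf_tree_area(lc_scenario, b$x[i], b$y[i]),
                 numeric(1)) / 1e4

  wmean <- function(v, w) sum(w * v) / sum(w)
  rows <- list()
  subs <- unique(zt[zt$category != "population", c("category", "subcategory")])
  for (i in seq_len(nrow(subs))) {
    cat_i <- subs$category[i]; sub_i <- subs$subcategory[i]
    w <- numeric(nrow(b))
    for (u in seq_len(nrow(b))) {
      cnt <- zt$count[zt$zone_id == b$zone_id[u] & zt$category == cat_i &
                        zt$subcategory == sub_i]
      w[u] <- cnt / zone_pop[[as.character(b$zone_id[u])]] * b$population[u]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      category = cat_i, subcategory = sub_i, population = sum(w),
      pm25_baseline = wmean(pm_b, w), pm25_scenario = wmean(pm_s, w),
      tree_ha_baseline = wmean(tr_b, w), tree_ha_scenario = wmean(tr_s, w))
  }
  cls <- income_classes(city$zone_income, b)
  bcls <- cls$income_class[match(b$zone_id, cls$zone_id)]
  for (s in c("bottom_quintile", "middle_quintiles", "top_quintile")) {
    w <- ifelse(bcls == s, b$population, 0)
    rows[[length(rows) + 1L]] <- data.frame(
      category = "income", subcategory = s, population = sum(w),
      pm25_baseline = wmean(pm_b, w), pm25_scenario = wmean(pm_s, w),
      tree_ha_baseline = wmean(tr_b, w), tree_ha_scenario = wmean(tr_s, w))
  }
  rows[[length(rows) + 1L]] <- data.frame(
    category = "total", subcategory = "total", population = sum(b$population),
    pm25_baseline = wmean(pm_b, b$population),
    pm25_scenario = wmean(pm_s, b$population),
    tree_ha_baseline = wmean(tr_b, b$population),
    tree_ha_scenario = wmean(tr_s, b$population))
  out <- do.call(rbind, rows)
  out$pm25_delta <- out$pm25_scenario - out$pm25_baseline
  out$tree_ha_delta <- out$tree_ha_scenario - out$tree_ha_baseline
  out
}

# a small city that exercises every stage quickly
small_city_config <- function(seed = 1, n_buildings = 80, ...) {
  city_config(extent_m = 3000, n_zones = 9, n_buildings = n_buildings,
              seed = seed, ...)
}
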