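#' Parameters for the '3' and '30' greening targets
#'
#' Controls the two components of the 3-30-300 urban greening rule that the
#' package models: every residential building should have at least three
#' viewable trees — operationalised on a 5 m land-cover grid as
#' `min_viewable_tree_cells` (default 2) tree cells within
#' `viewable_radius_m` (default 30 m) — and every neighbourhood (statistical
#' zone) should reach `neighbourhood_target` (default 30%) green and blue
#' space cover.
#'
#' @param viewable_radius_m Radius (m) of the viewable-tree search around a
#'   building.
#' @param min_viewable_tree_cells Tree cells required within that radius.
#' @param neighbourhood_target Required fraction of zone cells in
#'   `green_blue_codes`, in (0, 1].
#' @param green_blue_codes Classes counted toward the neighbourhood target.
#'   Default tree canopy and water; grass is excluded by default but can be
#'   added.
#' @param eligible_codes Classes convertible to tree canopy. Buildings and
#'   water are never convertible; sealed (mineral) surfaces are eligible, as
#'   dense city centres can only be regreened by depaving.
#' @param seed Accepted for interface compatibility; the placement algorithm
#'   is fully deterministic and does not consume it.
#' @return An object of class `greening_params`.
#' @export
greening_params <- function(viewable_radius_m = 30,
                            min_viewable_tree_cells = 2L,
                            neighbourhood_target = 0.30,
                            green_blue_codes = lc_codes()[c("TREE", "WATER")],
                            eligible_codes = lc_codes()[c("GRASS", "BARE", "MINERAL")],
                            seed = NULL) {
  if (neighbourhood_target <= 0 || neighbourhood_target > 1) {
    stop("`neighbourhood_target` must lie in (0, 1]", call. = FALSE)
  }
  if (min_viewable_tree_cells < 1L) {
    stop("`min_viewable_tree_cells` must be at least 1", call. = FALSE)
  }
  forbidden <- intersect(unname(eligible_codes),
                         unname(lc_codes()[c("BUILDING", "WATER")]))
  if (length(forbidden)) {
    stop("buildings and water are never eligible for conversion", call. = FALSE)
  }
  structure(list(viewable_radius_m = viewable_radius_m,
                 min_viewable_tree_cells = as.integer(min_viewable_tree_cells),
                 neighbourhood_target = neighbourhood_target,
                 green_blue_codes = as.integer(unname(green_blue_codes)),
                 eligible_codes = as.integer(unname(eligible_codes)),
                 seed = seed),
            class = "greening_params")
}

#' Viewable-tree deficit of a building
#'
#' Number of additional tree cells a building needs within the viewable
#' radius to satisfy the '3' target.
#'
#' @param lc Land-cover [eq_raster()].
#' @param x,y Building coordinates (length 1).
#' @param params A [greening_params()].
#' @return Non-negative integer deficit.
#' @export
viewable_deficit <- function(lc, x, y, params = greening_params()) {
  n <- cells_within(lc, x, y, params$viewable_radius_m, lc_codes()[["TREE"]])$count
  max(0L, params$min_viewable_tree_cells - n)
}

# cell centres inside an axis-aligned zone rectangle (half-open membership)
zone_cells <- function(g, zone) {
  ctr <- grid_centres(g)
  cols <- which(ctr$x >= zone$xmin & ctr$x < zone$xmax)
  rows <- which(ctr$y >= zone$ymin & ctr$y < zone$ymax)
  list(rows = rows, cols = cols)
}

#' Green and blue space fraction of a zone
#'
#' Fraction of a zone's interior land-cover cells (cell centre inside the
#' zone rectangle) whose class counts toward the neighbourhood target.
#'
#' @param lc Land-cover [eq_raster()].
#' @param zone One-row tibble or list with `xmin`, `xmax`, `ymin`, `ymax`.
#' @param params A [greening_params()].
#' @return Fraction in \[0, 1\].
#' @export
neighbourhood_fraction <- function(lc, zone, params = greening_params()) {
  zc <- zone_cells(lc$grid, zone)
  if (!length(zc$rows) || !length(zc$cols)) {
    stop("zone contains no land-cover cell centres", call. = FALSE)
  }
  sub <- lc$values[zc$rows, zc$cols, drop = FALSE]
  mean(sub %in% params$green_blue_codes)
}

#' Apply the '3' and '30' greening targets to a land cover
#'
#' Deterministic land-cover editing: first, buildings are processed in
#' ascending id and each viewable-tree deficit is met by converting the
#' nearest eligible cells within the viewable radius (ties broken by row
#' then column); then each zone short of the neighbourhood target has
#' eligible cells converted — preferring cells adjacent to existing tree
#' canopy, then scan order — until the target fraction is reached. Tree
#' cells are only ever added. Units whose target cannot be met with the
#' eligible cells available are reported in `infeasible`, never raised as
#' errors.
#'
#' @param lc Baseline land-cover [eq_raster()].
#' @param buildings Tibble with `id`, `x`, `y` (and any other columns).
#' @param zones Tibble of zone rectangles (`zone_id`, `xmin`, `xmax`,
#'   `ymin`, `ymax`).
#' @param params A [greening_params()].
#' @return An object of class `greening_result`: list with
#'   `landcover_scenario` (edited raster), `placements` (tibble of converted
#'   cells: `row`, `col`, `prior_class`, `reason`, `unit_id`) and
#'   `infeasible` (tibble `unit`, `id`, `shortfall`).
#' @export
apply_330 <- function(lc, buildings, zones, params = greening_params()) {
  stopifnot(inherits(lc, "eq_raster"), lc$role == "landcover")
  g <- lc$grid
  vals <- lc$values
  tree <- lc_codes()[["TREE"]]
  placements <- list()
  infeasible <- list()
  ctr <- grid_centres(g)
  log_batch <- function(rr, cc, reason, unit_id) {
    tibble::tibble(row = as.integer(rr), col = as.integer(cc),
                   prior_class = vals[cbind(rr, cc)],
                   reason = reason, unit_id = as.integer(unit_id))
  }

  # --- '3': viewable trees per building, ascending id ---------------------
  b <- dplyr::arrange(buildings, .data$id)
  r2 <- params$viewable_radius_m^2
  for (i in seq_len(nrow(b))) {
    cmin <- max(1L, floor((b$x[i] - params$viewable_radius_m) / g$res_m -
                            (g$origin_x / g$res_m)) + 1L)
    cmax <- min(g$ncols, ceiling((b$x[i] + params$viewable_radius_m - g$origin_x) / g$res_m))
    rmin <- max(1L, floor((g$origin_y - (b$y[i] + params$viewable_radius_m)) / g$res_m) + 1L)
    rmax <- min(g$nrows, ceiling((g$origin_y - (b$y[i] - params$viewable_radius_m)) / g$res_m))
    if (cmin > cmax || rmin > rmax) next
    rows <- rmin:rmax; cols <- cmin:cmax
    d2 <- outer((ctr$y[rows] - b$y[i])^2, (ctr$x[cols] - b$x[i])^2, `+`)
    inrad <- d2 <= r2
    sub <- vals[rows, cols, drop = FALSE]
    have <- sum(inrad & sub == tree)
    deficit <- params$min_viewable_tree_cells - have
    if (deficit <= 0) next
    elig <- which(inrad & matrix(sub %in% params$eligible_codes,
                                 nrow(sub), ncol(sub)), arr.ind = TRUE)
    if (nrow(elig)) {
      rr <- rows[elig[, 1]]; cc <- cols[elig[, 2]]
      ord <- order(d2[elig], rr, cc)
      take <- utils::head(ord, deficit)
      placements[[length(placements) + 1L]] <-
        log_batch(rr[take], cc[take], "viewable", b$id[i])
      vals[cbind(rr[take], cc[take])] <- tree
      deficit <- deficit - length(take)
    }
    if (deficit > 0) {
      infeasible[[length(infeasible) + 1L]] <- list(
        unit = "building", id = b$id[i], shortfall = deficit)
    }
  }

  # --- '30': neighbourhood green/blue target per zone ---------------------
  zs <- dplyr::arrange(zones, .data$zone_id)
  for (i in seq_len(nrow(zs))) {
    zc <- zone_cells(g, zs[i, ])
    if (!length(zc$rows) || !length(zc$cols)) next
    sub <- vals[zc$rows, zc$cols, drop = FALSE]
    n_cells <- length(sub)
    n_green <- sum(sub %in% params$green_blue_codes)
    needed <- ceiling(params$neighbourhood_target * n_cells - n_green - 1e-9)
    if (needed <= 0) next
    elig <- which(matrix(sub %in% params$eligible_codes, nrow(sub), ncol(sub)),
                  arr.ind = TRUE)
    if (nrow(elig)) {
      rr <- zc$rows[elig[, 1]]; cc <- zc$cols[elig[, 2]]
      # adjacency to existing trees via 8-neighbour dilation on the zone
      # sub-rectangle (padded one cell so cross-zone trees count)
      rpad <- max(1L, min(zc$rows) - 1L):min(g$nrows, max(zc$rows) + 1L)
      cpad <- max(1L, min(zc$cols) - 1L):min(g$ncols, max(zc$cols) + 1L)
      tr <- vals[rpad, cpad, drop = FALSE] == tree
      dil <- tr
      nr <- nrow(tr); ncp <- ncol(tr)
      shift <- function(m, dr, dc) {
        out <- matrix(FALSE, nr, ncp)
        rs <- max(1, 1 + dr):min(nr, nr + dr)
        cs <- max(1, 1 + dc):min(ncp, ncp + dc)
        out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
        out
      }
      for (dr in -1:1) for (dc in -1:1) {
        if (dr || dc) dil <- dil | shift(tr, dr, dc)
      }
      adj <- dil[cbind(rr - rpad[1] + 1L, cc - cpad[1] + 1L)]
      ord <- order(-adj, rr, cc)
      take <- utils::head(ord, needed)
      placements[[length(placements) + 1L]] <-
        log_batch(rr[take], cc[take], "neighbourhood", zs$zone_id[i])
      vals[cbind(rr[take], cc[take])] <- tree
      needed <- needed - length(take)
    }
    if (needed > 0) {
      infeasible[[length(infeasible) + 1L]] <- list(
        unit = "zone", id = zs$zone_id[i], shortfall = needed)
    }
  }

  empty_placements <- tibble::tibble(row = integer(), col = integer(),
                                     prior_class = integer(),
                                     reason = character(), unit_id = integer())
  empty_infeasible <- tibble::tibble(unit = character(), id = integer(),
                                     shortfall = integer())
  structure(
    list(
      landcover_scenario = eq_raster(vals, g, role = "landcover"),
      placements = if (length(placements)) {
        dplyr::bind_rows(placements)
      } else empty_placements,
      infeasible = if (length(infeasible)) {
        dplyr::bind_rows(lapply(infeasible, tibble::as_tibble))
      } else empty_infeasible
    ),
    class = "greening_result"
  )
}

#' @export
print.greening_result <- function(x, ...) {
  cat(sprintf("<greening_result> %d cells converted (%d viewable, %d neighbourhood), %d infeasible units\n",
              nrow(x$placements), sum(x$placements$reason == "viewable"),
              sum(x$placements$reason == "neighbourhood"), nrow(x$infeasible)))
  invisible(x)
}
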