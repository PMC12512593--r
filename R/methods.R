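#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a meta-model
#'
#' @param x A [meta_model()].
#' @param ... Unused.
#' @return Tibble with one row per polynomial term (`term`, `estimate`).
#' @export
tidy.meta_model <- function(x, ...) {
  tibble::tibble(term = c("woodfrac^2", "woodfrac", "(Intercept)"),
                 estimate = c(x$c2, x$c1, x$c0))
}

#' One-row summary of a meta-model
#'
#' Reports the intercept (percentage PM2.5 change with no woodland), the
#' woodland fraction of strongest removal on \[0, 1\] and the change there.
#'
#' @param x A [meta_model()].
#' @param ... Unused.
#' @return One-row tibble: `name`, `intercept`, `argmin_woodfrac`,
#'   `min_pcpm`.
#' @export
glance.meta_model <- function(x, ...) {
  w <- if (x$c2 > 0) min(1, max(0, -x$c1 / (2 * x$c2))) else 1
  cand <- unique(c(0, w, 1))
  p <- pcpm(x, cand)
  i <- which.min(p)
  tibble::tibble(name = x$name, intercept = x$c0,
                 argmin_woodfrac = cand[i], min_pcpm = p[i])
}

#' One-row summary of a greening result
#'
#' @param x An [apply_330()] result.
#' @param ... Unused.
#' @return One-row tibble with conversion and infeasibility counts.
#' @export
glance.greening_result <- function(x, ...) {
  tibble::tibble(
    cells_converted = nrow(x$placements),
    viewable_conversions = sum(x$placements$reason == "viewable"),
    neighbourhood_conversions = sum(x$placements$reason == "neighbourhood"),
    infeasible_buildings = sum(x$infeasible$unit == "building"),
    infeasible_zones = sum(x$infeasible$unit == "zone")
  )
}

#' Tidy a gap report
#'
#' @param x A [gaps()] result.
#' @param ... Unused.
#' @return The underlying tibble, one row per category.
#' @export
tidy.gap_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gap_report")
  out
}

#' @export
#' @importFrom tibble as_tibble
tibble::as_tibble

#' Plot a raster
#'
#' Land-cover rasters draw as a categorical map with the class palette;
#' continuous rasters as a filled gradient.
#'
#' @param object An [eq_raster()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eq_raster <- function(object, ...) {
  df <- as_tibble(object)
  if (object$role == "landcover") {
    codes <- lc_codes()
    df$class <- factor(names(codes)[match(df$value, codes)], levels = names(codes))
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$class)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_manual(values = c(
        TREE = "#1b7837", GRASS = "#a6dba0", WATER = "#4393c3",
        BUILDING = "#762a83", MINERAL = "#bababa", BARE = "#dfc27d"
      ), drop = FALSE) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (m)", y = "y (m)", fill = "class")
  } else {
    lab <- switch(object$role,
                  concentration = "PM2.5 (ug/m3)",
                  delta = "delta PM2.5 (ug/m3)",
                  fraction = "fraction")
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (m)", y = "y (m)", fill = lab)
  }
}

#' Plot subgroup exposure, baseline vs scenario
#'
#' Dumbbell-style plot of population-weighted PM2.5 per subgroup: baseline
#' and scenario values joined by a segment, faceted by category.
#'
#' @param object An [exposure_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.exposure_table <- function(object, ...) {
  df <- dplyr::filter(object, .data$category != "total")
  ggplot2::ggplot(df, ggplot2::aes(y = .data$subcategory)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$pm25_baseline,
                                       xend = .data$pm25_scenario,
                                       yend = .data$subcategory),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$pm25_baseline,
                                     colour = "baseline")) +
    ggplot2::geom_point(ggplot2::aes(x = .data$pm25_scenario,
                                     colour = "scenario")) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$category),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "population-weighted PM2.5 (ug/m3)", y = NULL,
                  colour = NULL)
}

#' Plot exposure gaps per category
#'
#' @param report A [gaps()] result.
#' @return A ggplot comparing baseline and scenario gaps per category.
#' @export
plot_gaps <- function(report) {
  df <- tidy(report) |>
    tidyr::pivot_longer(c("gap_baseline", "gap_scenario"),
                        names_to = "scenario", values_to = "gap") |>
    dplyr::mutate(scenario = sub("gap_", "", .data$scenario))
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$gap,
                                   fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "exposure gap (ug/m3)", fill = NULL)
}
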