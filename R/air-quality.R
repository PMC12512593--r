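#' City meta-model: woodland fraction to percentage PM2.5 change
#'
#' A quadratic (or linear) reduced-form emulator of a full atmospheric
#' chemistry transport model: `pcpm(w) = c2 * w^2 + c1 * w + c0`, where `w`
#' is the proportion of woodland (tree canopy) in a grid cell and the result
#' is the percentage change in PM2.5 concentration attributable to that
#' woodland (negative: trees remove particulates by leaf deposition). At
#' construction the model is validated to predict a non-positive change over
#' the whole woodland-fraction domain, checked on a 0.001-step grid.
#'
#' @param c2,c1,c0 Polynomial coefficients (quadratic, linear, intercept).
#' @param name Model label.
#' @param validate Check non-positivity of the prediction on \[0, 1\].
#' @return An object of class `meta_model`.
#' @seealso [meta_model_aarhus()], [meta_model_paris()]
#' @export
meta_model <- function(c2, c1, c0, name = "custom", validate = TRUE) {
  m <- structure(list(c2 = as.numeric(c2), c1 = as.numeric(c1),
                      c0 = as.numeric(c0), name = name),
                 class = "meta_model")
  if (validate) {
    w <- seq(0, 1, by = 1e-3)
    p <- m$c2 * w^2 + m$c1 * w + m$c0
    if (any(p > 0)) {
      stop(sprintf("meta-model '%s' predicts a positive PM2.5 change at woodfrac %.3f",
                   name, w[which(p > 0)[1]]), call. = FALSE)
    }
  }
  m
}

#' Shipped city meta-models
#'
#' The fitted reduced-form models for the two study cities. Aarhus is
#' linear, `pcpm(w) = -3.9134 w - 0.1636`; Paris is quadratic,
#' `pcpm(w) = 6.0425 w^2 - 8.9865 w - 0.8939`, with its minimum (strongest
#' removal) at w = 8.9865 / (2 * 6.0425), about 0.7436 — beyond that
#' woodland fraction the fitted curve turns back up, a documented
#' non-monotonicity of the quadratic fit.
#'
#' @return A `meta_model`.
#' @examples
#' pcpm(meta_model_aarhus(), 0)    # -0.1636
#' pcpm(meta_model_paris(), 0)     # -0.8939
#' @export
meta_model_aarhus <- function() meta_model(0, -3.9134, -0.1636, name = "aarhus")

#' @rdname meta_model_aarhus
#' @export
meta_model_paris <- function() meta_model(6.0425, -8.9865, -0.8939, name = "paris")

#' Percentage PM2.5 change for a woodland fraction
#'
#' @param model A [meta_model()].
#' @param woodfrac Woodland fraction(s) in \[0, 1\].
#' @return Percentage change(s) in PM2.5 concentration (% of the background
#'   concentration; negative values are reductions).
#' @export
pcpm <- function(model, woodfrac) {
  stopifnot(inherits(model, "meta_model"))
  if (any(woodfrac < 0 | woodfrac > 1)) {
    stop("`woodfrac` must lie in [0, 1]", call. = FALSE)
  }
  model$c2 * woodfrac^2 + model$c1 * woodfrac + model$c0
}

#' Absolute PM2.5 delta field from woodland fractions
#'
#' Converts per-cell percentage changes into absolute concentration changes
#' against the coarse background ("EMEP baseline") field:
#' `delta = pcpm(w) / 100 * baseline`, in ug/m3. All values are
#' non-positive: woodland only removes particulates.
#'
#' @param model A [meta_model()].
#' @param woodfrac_raster Fraction [eq_raster()] of woodland per coarse
#'   cell (from [class_fraction()]).
#' @param emep_baseline Coarse background concentration [eq_raster()] on
#'   the same grid.
#' @return A delta [eq_raster()] (role `"delta"`, values <= 0).
#' @export
delta_field <- function(model, woodfrac_raster, emep_baseline) {
  if (!grid_equal(woodfrac_raster$grid, emep_baseline$grid)) {
    stop("woodland-fraction and baseline grids are not aligned", call. = FALSE)
  }
  d <- pcpm(model, woodfrac_raster$values) / 100 * emep_baseline$values
  eq_raster(d, emep_baseline$grid, role = "delta")
}

#' Fine-resolution PM2.5 surfaces for baseline and greening scenario
#'
#' The full air-quality chain: woodland fraction per coarse cell for each
#' land cover, percentage change via the meta-model, absolute delta against
#' the coarse background field, bilinear resampling of the delta to the fine
#' grid, and addition to the fine (satellite-style) baseline surface. The
#' same coarse background multiplies both scenarios, so the scenario-minus-
#' current difference isolates the effect of the added trees.
#'
#' @param model A [meta_model()].
#' @param lc_current,lc_scenario Land-cover rasters on one identical grid.
#' @param coarse_grid The coarse [grid_spec()] (must tile the land cover).
#' @param emep_baseline_coarse Coarse background concentration raster.
#' @param fine_baseline Fine baseline concentration raster whose extent lies
#'   within the coarse extent.
#' @return An object of class `scenario_surfaces`: list with
#'   `pm25_current_fine`, `pm25_scenario_fine` (concentration rasters),
#'   `delta_current_coarse`, `delta_scenario_coarse` (delta rasters).
#' @export
scenario_surfaces <- function(model, lc_current, lc_scenario, coarse_grid,
                              emep_baseline_coarse, fine_baseline) {
  if (!grid_equal(lc_current$grid, lc_scenario$grid)) {
    stop("current and scenario land-cover grids differ", call. = FALSE)
  }
  tree <- lc_codes()[["TREE"]]
  w_cur <- class_fraction(lc_current, coarse_grid, tree)
  w_scn <- class_fraction(lc_scenario, coarse_grid, tree)
  d_cur <- delta_field(model, w_cur, emep_baseline_coarse)
  d_scn <- delta_field(model, w_scn, emep_baseline_coarse)
  d_cur_fine <- bilinear_resample(d_cur, fine_baseline$grid)
  d_scn_fine <- bilinear_resample(d_scn, fine_baseline$grid)
  cur <- fine_baseline$values + d_cur_fine$values
  scn <- fine_baseline$values + d_scn_fine$values
  if (any(cur <= 0) || any(scn <= 0)) {
    stop("delta drives a fine-grid concentration to zero or below; ",
         "the fine baseline is too small for the modelled change",
         call. = FALSE)
  }
  structure(
    list(pm25_current_fine = eq_raster(cur, fine_baseline$grid),
         pm25_scenario_fine = eq_raster(scn, fine_baseline$grid),
         delta_current_coarse = d_cur,
         delta_scenario_coarse = d_scn),
    class = "scenario_surfaces"
  )
}

#' @export
print.scenario_surfaces <- function(x, ...) {
  cat(sprintf("<scenario_surfaces> fine %d x %d @ %g m; mean current %.3f, scenario %.3f ug/m3\n",
              x$pm25_current_fine$grid$nrows, x$pm25_current_fine$grid$ncols,
              x$pm25_current_fine$grid$res_m,
              mean(x$pm25_current_fine$values),
              mean(x$pm25_scenario_fine$values)))
  invisible(x)
}
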