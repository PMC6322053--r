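#' Parameters of the synthetic true concentration surface
#'
#' The true field is a deterministic trend (level + linear gradient + Gaussian
#' hotspots) plus a stationary correlated residual simulated from an
#' exponential-correlation Gaussian random field, clipped at zero.
#'
#' @param level base concentration in ug/m3.
#' @param gradient numeric length 2, ug/m3 per km along x and y.
#' @param hotspots data.frame with columns `x`, `y`, `amp` (ug/m3) and
#'   `radius_km`, each adding `amp * exp(-d^2 / (2 radius^2))`; NULL for none.
#' @param sill variance of the spatial residual (ug/m3)^2; 0 gives a
#'   deterministic field.
#' @param range_km correlation range of the residual; must be > 0 when
#'   `sill > 0`.
#' @return list of class `field_params`.
#' @export
field_params <- function(level = 15, gradient = c(0.15, -0.05),
                         hotspots = NULL, sill = 4, range_km = 20) {
  if (sill < 0) stop("sill must be >= 0")
  if (sill > 0 && range_km <= 0) stop("range_km must be > 0 when sill > 0")
  if (!is.null(hotspots))
    stopifnot(all(c("x", "y", "amp", "radius_km") %in% names(hotspots)))
  structure(list(level = level, gradient = as.numeric(gradient),
                 hotspots = hotspots, sill = sill, range_km = range_km),
            class = "field_params")
}

trend_surface <- function(grid, params) {
  cc <- cell_centers(grid)
  mu <- params$level + params$gradient[1] * (cc$x - mean(cc$x)) +
    params$gradient[2] * (cc$y - mean(cc$y))
  if (!is.null(params$hotspots)) {
    for (k in seq_len(nrow(params$hotspots))) {
      h <- params$hotspots[k, ]
      d2 <- (cc$x - h$x)^2 + (cc$y - h$y)^2
      mu <- mu + h$amp * exp(-d2 / (2 * h$radius_km^2))
    }
  }
  mu
}

#' Simulate the true annual-mean field
#'
#' @param grid a [grid_spec()].
#' @param year calendar year.
#' @param pollutant `"PM25"` or `"NO2"`.
#' @param params a [field_params()].
#' @param seed integer seed; identical seeds give identical fields.
#' @return a [conc_field()] (values clipped at 0).
#' @export
make_true_field <- function(grid, year, pollutant, params, seed) {
  stopifnot(inherits(params, "field_params"))
  set.seed(seed)
  mu <- trend_surface(grid, params)
  w <- if (params$sill > 0) {
    cc <- cell_centers(grid)
    sim_grf(as.matrix(cc[, c("x", "y")]), params$sill, params$range_km)
  } else 0
  conc_field(grid, pollutant, year, pmax(mu + w, 0))
}

#' Model-bias description for the dispersion-model surrogate
#'
#' @param mult multiplicative factor applied to the true field.
#' @param add additive offset in ug/m3.
#' @param error_sill variance of a smooth spatially correlated model-error
#'   field; 0 for none.
#' @param error_range_km correlation range of the model error.
#' @return list of class `model_bias`.
#' @export
model_bias <- function(mult = 1, add = 0, error_sill = 0, error_range_km = 30) {
  if (error_sill < 0) stop("error_sill must be >= 0")
  if (error_sill > 0 && error_range_km <= 0)
    stop("error_range_km must be > 0 when error_sill > 0")
  structure(list(mult = mult, add = add, error_sill = error_sill,
                 error_range_km = error_range_km),
            class = "model_bias")
}

#' Distort the true field into a dispersion-model surrogate
#'
#' `model = mult * true + add + smooth_error`, clipped at 0. With the identity
#' bias (`mult = 1, add = 0, error_sill = 0`) the output equals the input,
#' which makes data fusion a no-op check.
#'
#' @param true a [conc_field()] holding the true surface.
#' @param bias a [model_bias()].
#' @param seed integer seed for the smooth error field.
#' @return a [conc_field()] on the same grid.
#' @export
make_model_field <- function(true, bias, seed) {
  stopifnot(inherits(true, "conc_field"), inherits(bias, "model_bias"))
  set.seed(seed)
  e <- if (bias$error_sill > 0) {
    cc <- cell_centers(true$grid)
    sim_grf(as.matrix(cc[, c("x", "y")]), bias$error_sill,
            bias$error_range_km)
  } else 0
  conc_field(true$grid, true$pollutant, true$year,
             pmax(bias$mult * true$values + bias$add + e, 0))
}
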