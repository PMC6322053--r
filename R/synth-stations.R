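#' Place monitoring stations and simulate their daily series
#'
#' Stations occupy distinct grid cells (at most one per cell) at the cell
#' centre, carry a siting-type label, and record a daily series per pollutant
#' and year: the true cell annual mean plus iid Gaussian measurement noise,
#' with days removed at random according to each station's missing-data
#' fraction. The valid-day mean is therefore unbiased for the true annual
#' mean, with standard error `noise_sd / sqrt(n_valid_days)`.
#'
#' @param grid a [grid_spec()].
#' @param n_stations number of stations (0 allowed; at most `n_cells(grid)`).
#' @param background_fraction fraction labelled `"background"`; the rest split
#'   evenly between `"traffic"` and `"industrial"`.
#' @param missing_profile per-station missing-day fraction in `[0, 1]`;
#'   scalar or vector of length `n_stations`.
#' @param true_fields list of [conc_field()]s (the true surfaces) for which
#'   series are generated.
#' @param noise_sd daily measurement noise sd in ug/m3.
#' @param seed integer seed.
#' @return list of class `station_set` with elements `meta` (station_id,
#'   cell_i, cell_j, x, y, station_type) and `daily` (station_id, pollutant,
#'   year, date, value; missing days have `NA` value).
#' @export
place_stations <- function(grid, n_stations, background_fraction = 0.7,
                           missing_profile = 0.05, true_fields,
                           noise_sd = 2, seed = 1) {
  if (n_stations > n_cells(grid))
    stop("n_stations exceeds the number of grid cells (one station per cell maximum)")
  if (any(missing_profile < 0 | missing_profile > 1))
    stop("missing_profile fractions must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (inherits(true_fields, "conc_field")) true_fields <- list(true_fields)
  set.seed(seed)
  miss <- rep_len(missing_profile, n_stations)
  cc <- cell_centers(grid)
  cells <- if (n_stations > 0) sample.int(n_cells(grid), n_stations) else integer(0)
  n_bg <- round(background_fraction * n_stations)
  type <- rep(c("traffic", "industrial"), length.out = max(n_stations - n_bg, 0))
  type <- sample(c(rep("background", n_bg), type))
  meta <- data.frame(station_id = sprintf("S%03d", seq_len(n_stations)),
                     cell_i = cc$cell_i[cells], cell_j = cc$cell_j[cells],
                     x = cc$x[cells], y = cc$y[cells],
                     station_type = type,
                     missing_fraction = miss,
                     stringsAsFactors = FALSE)
  daily <- vector("list", length(true_fields))
  for (f in seq_along(true_fields)) {
    fld <- true_fields[[f]]
    if (!same_grid(fld$grid, grid)) stop("true field grid does not match")
    days <- seq(as.Date(sprintf("%d-01-01", fld$year)),
                as.Date(sprintf("%d-12-31", fld$year)), by = "day")
    nd <- length(days)
    truth <- fld$values[cells]
    val <- rep(truth, each = nd) + stats::rnorm(nd * n_stations, 0, noise_sd)
    gone <- stats::runif(nd * n_stations) < rep(miss, each = nd)
    val[gone] <- NA_real_
    daily[[f]] <- data.frame(
      station_id = rep(meta$station_id, each = nd),
      pollutant = fld$pollutant, year = fld$year,
      date = rep(days, times = n_stations), value = val,
      stringsAsFactors = FALSE)
  }
  structure(list(meta = meta, daily = do.call(rbind, daily)),
            class = "station_set")
}

#' @export
print.station_set <- function(x, ...) {
  cat(sprintf("station_set: %d stations (%d background), %d daily records\n",
              nrow(x$meta), sum(x$meta$station_type == "background"),
              nrow(x$daily)))
  invisible(x)
}
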