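#' Default configuration of the synthetic study world
#'
#' Desk-scale stand-in for a national study region: a 25 x 20 grid of 4-km
#' cells, two pollutants with model years 1999/2003/2005/2007, 40 monitoring
#' stations (70% background), 60 municipalities, a two-stage sample of 30
#' municipalities x 60 households, and the ground-truth parameters of
#' [world_truth()].
#'
#' @param ... named elements overriding the defaults (nested lists are
#'   replaced wholesale).
#' @return configuration list.
#' @export
default_world_config <- function(...) {
  cfg <- list(
    grid = list(nx = 25, ny = 20, cell_km = 4, origin = c(0, 0)),
    years = model_years,
    pollutants = list(
      PM25 = field_params(level = 18, gradient = c(0.15, -0.05),
                          hotspots = data.frame(x = c(30, 70), y = c(55, 25),
                                                amp = c(8, 6),
                                                radius_km = c(12, 10)),
                          sill = 4, range_km = 20),
      NO2 = field_params(level = 22, gradient = c(-0.10, 0.08),
                         hotspots = data.frame(x = 55, y = 40, amp = 10,
                                               radius_km = 9),
                         sill = 6, range_km = 16)),
    n_stations = 40, background_fraction = 0.7, missing_profile = 0.05,
    n_munis = 60, n_munis_sampled = 30, households_per_muni = 60,
    truth = world_truth(),
    admission_params = default_admission_params(),
    window = as.Date(c("1999-01-01", "2008-12-31")))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Generate a complete synthetic study world
#'
#' Runs the whole generator: true and model concentration fields for every
#' pollutant and model year, monitoring stations with daily series,
#' municipalities with built-up areas, the two-stage cohort, and death /
#' admission records driven by the ground-truth hazard. Deterministic given
#' `seed`.
#'
#' @param config see [default_world_config()].
#' @param seed integer master seed; stage seeds are derived from it.
#' @return list of class `synth_world`: `grid`, `true_fields`,
#'   `model_fields` (lists named `<pollutant>_<year>`), `stations`, `munis`,
#'   `subjects`, `events`, `true_exposure` (municipality annual table from
#'   the true fields), `truth`, `config`, `seed`.
#' @export
make_world <- function(config = default_world_config(), seed = 1) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 8)
  grid <- do.call(grid_spec, config$grid)
  truth <- config$truth
  true_fields <- list()
  model_fields <- list()
  k <- 0
  for (pol in names(config$pollutants)) {
    for (yr in config$years) {
      k <- k + 1
      nm <- sprintf("%s_%d", pol, yr)
      tf <- make_true_field(grid, yr, pol, config$pollutants[[pol]],
                            seed = sub[1] + k)
      true_fields[[nm]] <- tf
      model_fields[[nm]] <- make_model_field(tf, truth$bias,
                                             seed = sub[2] + k)
    }
  }
  stations <- place_stations(grid, config$n_stations,
                             config$background_fraction,
                             config$missing_profile, true_fields,
                             noise_sd = truth$station_noise_sd,
                             seed = sub[3])
  munis <- make_municipalities(grid, config$n_munis, seed = sub[4])
  subjects <- sample_cohort(munis, config$n_munis_sampled,
                            config$households_per_muni,
                            covariates = covariate_model(),
                            seed = sub[5])
  true_exposure <- exposure_table(true_fields, munis$cells)
  events <- simulate_events(subjects, true_exposure, truth,
                            window = config$window,
                            admission_params = config$admission_params,
                            seed = sub[6])
  structure(list(grid = grid, true_fields = true_fields,
                 model_fields = model_fields, stations = stations,
                 munis = munis, subjects = subjects, events = events,
                 true_exposure = true_exposure, truth = truth,
                 config = config, seed = seed),
            class = "synth_world")
}

#' @export
print.synth_world <- function(x, ...) {
  cat(sprintf(
    "synth_world: %dx%d grid, %d fields, %d stations, %d municipalities, %d subjects, %d events\n",
    x$grid$nx, x$grid$ny, length(x$true_fields), nrow(x$stations$meta),
    nrow(x$munis$munis), nrow(x$subjects), nrow(x$events)))
  invisible(x)
}
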