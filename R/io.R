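#' Write a synthetic world to plain-text files
#'
#' Emits the CSV/GeoJSON drop-in schema also accepted in real-data mode:
#' `subjects.csv`, `events.csv`, `stations.csv` (long format), one
#' `field_<pollutant>_<year>.csv` per model field, `muni_cells.csv`, and
#' `municipalities.geojson` (MultiPolygon per municipality at cell
#' resolution).
#'
#' @param world a `synth_world` from [make_world()].
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wcsv <- function(d, name) {
    f <- file.path(dir, name)
    utils::write.csv(d, f, row.names = FALSE)
    files <<- c(files, f)
  }
  wcsv(world$subjects, "subjects.csv")
  wcsv(world$events, "events.csv")
  st <- merge(world$stations$daily,
              world$stations$meta[, c("station_id", "x", "y",
                                      "station_type")],
              by = "station_id")
  st$flag <- ifelse(is.na(st$value), "missing", "valid")
  wcsv(st[order(st$station_id, st$pollutant, st$date), ], "stations.csv")
  for (nm in names(world$model_fields)) {
    d <- field_df(world$model_fields[[nm]])
    wcsv(d[, c("cell_i", "cell_j", "value")], sprintf("field_%s.csv", nm))
  }
  mc <- merge(world$munis$cells,
              world$munis$munis[, c("municipality_id", "population")],
              by = "municipality_id")
  wcsv(mc[order(mc$municipality_id, mc$cell_j, mc$cell_i), ],
       "muni_cells.csv")
  f <- file.path(dir, "municipalities.geojson")
  writeLines(muni_geojson(world$munis, world$grid), f)
  files <- c(files, f)
  invisible(files)
}

# GeoJSON FeatureCollection: one MultiPolygon per municipality made of its
# member-cell squares (cell-resolution geometry, not a dissolved outline)
muni_geojson <- function(munis, grid) {
  cells <- munis$cells
  sq <- function(i, j) {
    x0 <- grid$origin[1] + i * grid$cell_km
    y0 <- grid$origin[2] + j * grid$cell_km
    k <- grid$cell_km
    list(list(list(x0, y0), list(x0 + k, y0), list(x0 + k, y0 + k),
              list(x0, y0 + k), list(x0, y0)))
  }
  feats <- lapply(split(cells, cells$municipality_id), function(mc) {
    pop <- munis$munis$population[
      munis$munis$municipality_id == mc$municipality_id[1]]
    list(type = "Feature",
         properties = list(municipality_id = mc$municipality_id[1],
                           population = pop,
                           size_class = classify_municipality(pop)),
         geometry = list(type = "MultiPolygon",
                         coordinates = mapply(sq, mc$cell_i, mc$cell_j,
                                              SIMPLIFY = FALSE)))
  })
  jsonlite::toJSON(list(type = "FeatureCollection", features = unname(feats)),
                   auto_unbox = TRUE, digits = NA)
}

#' Read a long-format station file
#'
#' Accepts the `stations.csv` schema written by [write_world()] (station_id,
#' pollutant, year, date, value, x, y, station_type) and rebuilds a
#' `station_set`.
#'
#' @param path CSV file.
#' @return a `station_set` (see [place_stations()]).
#' @export
read_stations_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "pollutant", "year", "date", "value", "x", "y",
            "station_type")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("stations file lacks columns: ",
                         paste(miss, collapse = ", "))
  d$date <- as.Date(d$date)
  meta <- unique(d[, c("station_id", "x", "y", "station_type")])
  structure(list(meta = meta,
                 daily = d[, c("station_id", "pollutant", "year", "date",
                               "value")]),
            class = "station_set")
}

#' Read a gridded concentration field from CSV
#'
#' @param path CSV with columns cell_i, cell_j, value.
#' @param grid the [grid_spec()] the cells refer to.
#' @param pollutant,year labels of the field.
#' @return a [conc_field()].
#' @export
read_field_csv <- function(path, grid, pollutant, year) {
  d <- utils::read.csv(path)
  vals <- rep(NA_real_, n_cells(grid))
  vals[cell_index(grid, d$cell_i, d$cell_j)] <- d$value
  if (anyNA(vals)) stop("field file does not cover every grid cell")
  conc_field(grid, pollutant, year, vals)
}

#' Read a reference rate table from CSV
#'
#' @param path CSV with columns year, sex, age_class, rate (events per
#'   person-year).
#' @return data.frame suitable for [expected_events()] and [oe_report()].
#' @export
read_rates_csv <- function(path) {
  # sex codes "F"/"T" would otherwise be guessed as logicals
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(sex = "character"))
  need <- c("year", "sex", "age_class", "rate")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("rates file lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(d$rate < 0)) stop("rates must be >= 0")
  d[, need]
}

#' Read municipality cell membership from CSV
#'
#' @param path CSV with municipality_id, cell_i, cell_j, builtup_area_km2 and
#'   optionally population.
#' @return list with `cells` and (when population is present) `munis`.
#' @export
read_muni_cells_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("municipality_id", "cell_i", "cell_j", "builtup_area_km2")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("muni_cells file lacks columns: ",
                         paste(miss, collapse = ", "))
  out <- list(cells = d[, need])
  if ("population" %in% names(d)) {
    mm <- unique(d[, c("municipality_id", "population")])
    mm$size_class <- classify_municipality(mm$population)
    out$munis <- mm
  }
  out
}
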