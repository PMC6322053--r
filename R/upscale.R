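#' Built-up-area-weighted block average to municipality level
#'
#' Change of support from grid cells to municipalities:
#' `C_i = sum_p (A_ip / A_i) * y_p`, where `y_p` is the concentration of
#' member cell p and `A_ip` its within-municipality built-up area. Weights
#' are non-negative and sum to 1, so every municipal mean lies inside the
#' range of its member-cell values. Municipalities with zero total built-up
#' area fall back to the unweighted mean of their member cells, with a
#' warning.
#'
#' @param field a [conc_field()] (typically a fused field).
#' @param muni_cells data.frame (municipality_id, cell_i, cell_j,
#'   builtup_area_km2); a cell split across municipalities may appear in
#'   several with its within-municipality built-up area.
#' @return data.frame (municipality_id, value).
#' @export
block_average <- function(field, muni_cells) {
  stopifnot(inherits(field, "conc_field"),
            all(c("municipality_id", "cell_i", "cell_j",
                  "builtup_area_km2") %in% names(muni_cells)))
  g <- field$grid
  bad <- muni_cells$cell_i < 0 | muni_cells$cell_i >= g$nx |
    muni_cells$cell_j < 0 | muni_cells$cell_j >= g$ny
  if (any(bad))
    stop("member cell missing from field: (",
         muni_cells$cell_i[bad][1], ", ", muni_cells$cell_j[bad][1], ")")
  if (any(muni_cells$builtup_area_km2 < 0))
    stop("built-up areas must be >= 0")
  y <- field$values[cell_index(g, muni_cells$cell_i, muni_cells$cell_j)]
  id <- factor(muni_cells$municipality_id,
               levels = unique(muni_cells$municipality_id))
  a_i <- as.numeric(tapply(muni_cells$builtup_area_km2, id, sum))
  zero <- a_i == 0
  if (any(zero)) {
    warning("zero built-up area in ",
            paste(levels(id)[zero], collapse = ", "),
            "; falling back to unweighted cell mean")
  }
  num <- as.numeric(tapply(muni_cells$builtup_area_km2 * y, id, sum))
  val <- ifelse(zero, as.numeric(tapply(y, id, mean)), num / a_i)
  data.frame(municipality_id = levels(id), value = val,
             stringsAsFactors = FALSE)
}

#' Municipality annual exposure table from fused fields
#'
#' Applies [block_average()] to each fused field and stacks the results into
#' the long annual exposure table consumed by the risk-set builder.
#'
#' @param fields list of [conc_field()]s (any mix of pollutants and years).
#' @param muni_cells see [block_average()].
#' @return data.frame (municipality_id, pollutant, year, value).
#' @export
exposure_table <- function(fields, muni_cells) {
  out <- lapply(fields, function(f) {
    b <- block_average(f, muni_cells)
    b$pollutant <- f$pollutant
    b$year <- f$year
    b
  })
  out <- do.call(rbind, out)
  out[, c("municipality_id", "pollutant", "year", "value")]
}

#' Cumulative-mean risk-set exposures
#'
#' Builds the four risk-set exposures per municipality and pollutant from the
#' model-year annual values: each risk set carries the mean of all model
#' years available up to its start (see [risk_set_intervals()]). All four
#' model years must be present; missing years are an error, never imputed.
#'
#' @param annual data.frame (municipality_id, pollutant, year, value)
#'   restricted to (or at least containing) years 1999, 2003, 2005, 2007.
#' @return data.frame (municipality_id, pollutant, interval, interval_start,
#'   interval_end, exposure).
#' @export
build_risk_set_exposure <- function(annual) {
  stopifnot(all(c("municipality_id", "pollutant", "year", "value") %in%
                  names(annual)))
  annual <- annual[annual$year %in% model_years, ]
  rs <- risk_set_intervals()
  combo <- unique(annual[, c("municipality_id", "pollutant")])
  key <- paste(annual$municipality_id, annual$pollutant, annual$year)
  out <- vector("list", nrow(rs))
  for (k in seq_len(nrow(rs))) {
    yrs <- rs$years[[k]]
    vals <- matrix(NA_real_, nrow(combo), length(yrs))
    for (j in seq_along(yrs)) {
      m <- match(paste(combo$municipality_id, combo$pollutant, yrs[j]), key)
      vals[, j] <- annual$value[m]
    }
    if (anyNA(vals)) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop("missing annual exposure for ", combo$municipality_id[bad[1]],
           " ", combo$pollutant[bad[1]], " year ", yrs[bad[2]])
    }
    out[[k]] <- data.frame(municipality_id = combo$municipality_id,
                           pollutant = combo$pollutant,
                           interval = rs$interval[k],
                           interval_start = rs$start[k],
                           interval_end = rs$end[k],
                           exposure = rowMeans(vals),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$municipality_id, out$pollutant, out$interval), ]
  rownames(out) <- NULL
  out
}

#' Single-year sensitivity exposure
#'
#' Assigns one model year's annual value (default 2005) to the whole
#' follow-up: the returned table has the same shape as
#' [build_risk_set_exposure()] with the constant value in all four intervals,
#' so it drops into the counting-process builder unchanged.
#'
#' @param annual data.frame (municipality_id, pollutant, year, value).
#' @param year the single exposure year, default 2005.
#' @return data.frame (municipality_id, pollutant, interval, interval_start,
#'   interval_end, exposure).
#' @export
single_year_exposure <- function(annual, year = 2005) {
  sel <- annual[annual$year == year, ]
  if (nrow(sel) == 0) stop("year ", year, " absent from the annual table")
  rs <- risk_set_intervals()
  out <- merge(sel[, c("municipality_id", "pollutant", "value")],
               rs[, c("interval", "start", "end")])
  out <- data.frame(municipality_id = out$municipality_id,
                    pollutant = out$pollutant,
                    interval = out$interval,
                    interval_start = out$start,
                    interval_end = out$end,
                    exposure = out$value,
                    stringsAsFactors = FALSE)
  out <- out[order(out$municipality_id, out$pollutant, out$interval), ]
  rownames(out) <- NULL
  out
}
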