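#' Quality control of one station-year series
#'
#' Completeness is the fraction of valid (non-missing) daily values out of the
#' days of the calendar year. Series meeting the completeness threshold are
#' averaged to an annual observed value; the rest are rejected with a reason.
#'
#' @param series data.frame with `date` (Date) and `value` (NA = missing).
#' @param year calendar year to evaluate.
#' @param min_completeness acceptance threshold, default 0.80.
#' @return list: `annual_mean` (NA when rejected), `completeness`, `accepted`,
#'   `reason`.
#' @export
qc_station_year <- function(series, year, min_completeness = 0.80) {
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  expected <- length(days)
  if (expected == 0) stop("malformed series: zero expected observations")
  in_year <- series[!is.na(series$date) &
                      format(series$date, "%Y") == as.character(year), ]
  valid <- in_year$value[!is.na(in_year$value)]
  completeness <- length(valid) / expected
  if (completeness >= min_completeness) {
    list(annual_mean = mean(valid), completeness = completeness,
         accepted = TRUE, reason = "ok")
  } else {
    list(annual_mean = NA_real_, completeness = completeness,
         accepted = FALSE,
         reason = sprintf("completeness %.3f below %.2f", completeness,
                          min_completeness))
  }
}

#' Annual station values with QC for a station set
#'
#' Applies [qc_station_year()] to every station of a `station_set` for one
#' pollutant and year.
#'
#' @param stations a `station_set` from [place_stations()], or any list with
#'   `meta` and `daily` in the same long format.
#' @param pollutant,year which series to evaluate.
#' @param min_completeness see [qc_station_year()].
#' @return data.frame of annual station values: station metadata plus
#'   `annual_mean`, `completeness`, `accepted`, `reason`.
#' @export
annual_station_values <- function(stations, pollutant, year,
                                  min_completeness = 0.80) {
  d <- stations$daily
  d <- d[d$pollutant == pollutant & d$year == year, ]
  meta <- stations$meta
  out <- lapply(seq_len(nrow(meta)), function(k) {
    qc_station_year(d[d$station_id == meta$station_id[k], c("date", "value")],
                    year, min_completeness)
  })
  res <- meta[, intersect(c("station_id", "cell_i", "cell_j", "x", "y",
                            "station_type"), names(meta))]
  res$pollutant <- pollutant
  res$year <- as.integer(year)
  res$annual_mean <- vapply(out, `[[`, numeric(1), "annual_mean")
  res$completeness <- vapply(out, `[[`, numeric(1), "completeness")
  res$accepted <- vapply(out, `[[`, logical(1), "accepted")
  res$reason <- vapply(out, `[[`, character(1), "reason")
  rownames(res) <- NULL
  res
}

#' Select the stations entering the assimilation
#'
#' Keeps only background-type stations whose annual value passed QC, in
#' stable input order. Background monitors are the only ones whose spatial
#' representativeness matches the model's urban-background support.
#'
#' @param values data.frame of annual station values
#'   (see [annual_station_values()]).
#' @return the retained subset; a warning (not an error) if empty.
#' @export
select_assimilation_stations <- function(values) {
  out <- values[values$station_type == "background" & values$accepted, ]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning("no background station passed QC; assimilation set is empty")
  out
}

#' Fit the residual variogram against the model drift
#'
#' Residuals are observation minus the drift-field value of the observation's
#' containing cell. Their empirical semivariogram is fitted by weighted least
#' squares (weights = pairs per lag) to the chosen model form.
#'
#' @param obs data.frame of selected annual station values (needs `x`, `y`,
#'   `annual_mean`).
#' @param drift a [conc_field()] used as external drift.
#' @param model_form variogram form, default exponential.
#' @param n_lags bins of the empirical variogram.
#' @param fallback [variogram_model()] returned (with a warning) when fewer
#'   than 5 observations are available.
#' @return a fitted [variogram_model()].
#' @export
fit_residual_variogram <- function(obs, drift,
                                   model_form = "exponential", n_lags = 12,
                                   fallback = variogram_model(
                                     "exponential", nugget = 0.5, psill = 2,
                                     range_km = 20)) {
  if (nrow(obs) < 5) {
    warning("fewer than 5 observations; returning fallback variogram")
    return(fallback)
  }
  ci <- cell_of_xy(drift$grid, obs$x, obs$y)
  resid <- obs$annual_mean -
    drift$values[cell_index(drift$grid, ci$cell_i, ci$cell_j)]
  if (stats::sd(resid) < 1e-12) {
    return(variogram_model(model_form, nugget = 0, psill = 0, range_km = 1))
  }
  ev <- empirical_variogram(cbind(obs$x, obs$y), resid, n_lags = n_lags)
  cutoff <- max(ev$lag)
  obj <- function(p) {
    # clamp: the finite-difference gradient probes just outside the bounds
    m <- variogram_model(model_form, max(p[1], 0), max(p[2], 0),
                         max(p[3], 1e-9))
    sum(ev$n_pairs * (vgm_gamma(m, ev$lag) - ev$gamma)^2)
  }
  v0 <- stats::var(resid)
  init <- c(nugget = max(ev$gamma[1] / 2, 1e-6),
            psill = max(v0 - ev$gamma[1] / 2, 1e-6),
            range = cutoff / 3)
  # bounded search: the exponential sill/range pair is weakly identified on a
  # single realization and can escape jointly without these limits
  fit <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(0, 0, cutoff / 100),
                      upper = c(10 * v0, 10 * v0, 2 * cutoff))
  variogram_model(model_form, max(fit$par[1], 0), max(fit$par[2], 0),
                  max(fit$par[3], cutoff / 100))
}

# average observations sharing a location (prevents singular systems)
average_duplicates <- function(x, y, z) {
  key <- paste(signif(x, 12), signif(y, 12))
  if (!anyDuplicated(key)) return(list(x = x, y = y, z = z))
  g <- factor(key, levels = unique(key))
  list(x = as.numeric(tapply(x, g, mean)),
       y = as.numeric(tapply(y, g, mean)),
       z = as.numeric(tapply(z, g, mean)))
}

#' Fuse the model field with observations by kriging with external drift
#'
#' Observations are modelled as Y(s) = mu(s) + w(s) + eps(s), where the drift
#' mu(s) is a linear function of the model-field value at s (drift functions
#' {1, model(s)}), w(s) a stationary residual with the supplied variogram and
#' eps(s) the nugget/measurement error. The KED system is solved globally
#' (all observations for every prediction cell). With a zero nugget the
#' predictor is exact at observation locations. The nugget is treated as
#' measurement error: predictions target the smooth annual-mean signal.
#' Negative predictions are clipped at 0 and counted in `n_clipped`.
#'
#' @param obs data.frame with `x`, `y` and `annual_mean` (or `value`).
#' @param drift a [conc_field()] (the model surrogate).
#' @param vgm a [variogram_model()] for the residual w + eps.
#' @param cells optional integer vector of cell indices to predict (default
#'   all cells).
#' @param return_weights if TRUE, attach the kriging weight matrix and
#'   Lagrange multipliers as attributes `lambda` and `nu`.
#' @return a `fused_field` (a [conc_field()] with per-cell
#'   `variance`, plus `n_clipped`, `n_obs`, `vgm`, `fallback`). With zero
#'   observations the drift is returned unchanged, variance infinite, with a
#'   warning.
#' @export
ked_fuse <- function(obs, drift, vgm, cells = NULL, return_weights = FALSE) {
  stopifnot(inherits(drift, "conc_field"), inherits(vgm, "variogram_model"))
  grid <- drift$grid
  cc <- cell_centers(grid)
  if (is.null(cells)) cells <- seq_len(n_cells(grid))
  z_col <- if ("annual_mean" %in% names(obs)) "annual_mean" else "value"
  if (nrow(obs) == 0) {
    warning("no observations: returning the drift field unchanged (fallback)")
    out <- conc_field(grid, drift$pollutant, drift$year, drift$values)
    out$variance <- rep(Inf, n_cells(grid))
    out$n_clipped <- 0L; out$n_obs <- 0L; out$vgm <- vgm; out$fallback <- TRUE
    class(out) <- c("fused_field", class(out))
    return(out)
  }
  if (any(obs$x < grid$origin[1] | obs$x > grid$origin[1] + grid$nx * grid$cell_km |
          obs$y < grid$origin[2] | obs$y > grid$origin[2] + grid$ny * grid$cell_km))
    stop("observation locations outside the grid")
  dd <- average_duplicates(obs$x, obs$y, obs[[z_col]])
  x <- dd$x; y <- dd$y; z <- dd$z
  n <- length(z)
  ci <- cell_of_xy(grid, x, y)
  mu_obs <- drift$values[cell_index(grid, ci$cell_i, ci$cell_j)]
  mu0 <- drift$values[cells]
  pc <- cbind(cc$x[cells], cc$y[cells])
  oc <- cbind(x, y)
  use_drift <- n >= 2 && stats::sd(mu_obs) > 1e-10
  total_sill <- vgm$nugget + vgm$psill
  if (total_sill <= 0) {
    # degenerate noiseless residual: generalised-least-squares drift fit
    X <- if (use_drift) cbind(1, mu_obs) else matrix(1, n, 1)
    beta <- qr.coef(qr(X), z)
    X0 <- if (use_drift) cbind(1, mu0) else matrix(1, length(cells), 1)
    pred <- drop(X0 %*% beta)
    krig_var <- rep(0, length(cells))
    lambda <- NULL; nu <- NULL
  } else {
    C <- vgm_cov(vgm, dist_mat(oc, oc))
    Fm <- if (use_drift) cbind(1, mu_obs) else matrix(1, n, 1)
    p <- ncol(Fm)
    A <- rbind(cbind(C, Fm), cbind(t(Fm), matrix(0, p, p)))
    # residual covariance obs -> prediction points, excluding the nugget
    h0 <- dist_mat(oc, pc)
    c0 <- vgm$psill * vgm_corr(vgm$form, h0, vgm$range_km)
    f0 <- if (use_drift) rbind(1, mu0) else matrix(1, 1, length(cells))
    rhs <- rbind(c0, f0)
    sol <- tryCatch(solve(A, rhs), error = function(e) qr.solve(A, rhs))
    lambda <- sol[seq_len(n), , drop = FALSE]
    nu <- sol[n + seq_len(p), , drop = FALSE]
    pred <- drop(crossprod(lambda, z))
    krig_var <- pmax(vgm$psill - colSums(lambda * c0) - colSums(nu * f0), 0)
  }
  n_clipped <- sum(pred < 0)
  if (n_clipped > 0)
    message(sprintf("ked_fuse: %d negative prediction(s) clipped at 0",
                    n_clipped))
  vals <- rep(NA_real_, n_cells(grid))
  vv <- rep(NA_real_, n_cells(grid))
  vals[cells] <- pmax(pred, 0)
  vv[cells] <- krig_var
  if (length(cells) < n_cells(grid)) {
    # partial prediction: fill unpredicted cells with the drift for validity
    vals[-cells] <- drift$values[-cells]
    vv[-cells] <- NA_real_
  }
  out <- conc_field(grid, drift$pollutant, drift$year, vals)
  out$variance <- vv
  out$n_clipped <- as.integer(n_clipped)
  out$n_obs <- n
  out$vgm <- vgm
  out$fallback <- FALSE
  class(out) <- c("fused_field", class(out))
  if (return_weights) {
    attr(out, "lambda") <- lambda
    attr(out, "nu") <- nu
    attr(out, "mu_obs") <- mu_obs
  }
  out
}

#' @export
print.fused_field <- function(x, ...) {
  cat(sprintf(
    "fused_field: %s %d, %d obs, mean %.2f ug/m3, mean kriging sd %.2f%s\n",
    x$pollutant, x$year, x$n_obs, mean(x$values),
    sqrt(mean(x$variance[is.finite(x$variance)])),
    if (isTRUE(x$fallback)) " [drift fallback]" else ""))
  invisible(x)
}
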