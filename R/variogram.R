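#' Variogram model for the spatial residual
#'
#' Parametric semivariogram of the stationary Gaussian residual process in the
#' fusion model Y(s) = mu(s) + w(s) + eps(s): `nugget` is the micro-scale /
#' measurement variance, `psill` the partial sill (variance of w) and
#' `range_km` the correlation-decay distance.
#'
#' @param form one of `"exponential"`, `"spherical"`, `"gaussian"`.
#' @param nugget non-negative nugget variance.
#' @param psill non-negative partial sill.
#' @param range_km positive range parameter in km (effective range for the
#'   exponential/gaussian forms is about 3x / 1.7x this value).
#' @return An object of class `variogram_model`.
#' @export
variogram_model <- function(form = c("exponential", "spherical", "gaussian"),
                            nugget, psill, range_km) {
  form <- match.arg(form)
  if (nugget < 0 || psill < 0) stop("nugget and psill must be >= 0")
  if (range_km <= 0) stop("range_km must be > 0")
  structure(list(form = form, nugget = nugget, psill = psill,
                 range_km = range_km),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s, nugget %.3g, psill %.3g, range %.3g km\n",
              x$form, x$nugget, x$psill, x$range_km))
  invisible(x)
}

# correlation of w(s) at separation h (no nugget)
vgm_corr <- function(form, h, range_km) {
  switch(form,
    exponential = exp(-h / range_km),
    gaussian    = exp(-(h / range_km)^2),
    spherical   = ifelse(h >= range_km, 0,
                         1 - (1.5 * h / range_km - 0.5 * (h / range_km)^3)),
    stop("unknown variogram form: ", form))
}

#' Semivariance of a variogram model
#'
#' @param model a [variogram_model()].
#' @param h numeric vector of separation distances in km.
#' @return gamma(h); `nugget + psill * (1 - corr(h))` for h > 0, 0 at h = 0.
#' @export
vgm_gamma <- function(model, h) {
  g <- model$nugget + model$psill * (1 - vgm_corr(model$form, h, model$range_km))
  g[h == 0] <- 0
  g
}

# covariance C(h) = sill - gamma(h); at h = 0 includes the nugget
vgm_cov <- function(model, h) {
  cv <- model$psill * vgm_corr(model$form, h, model$range_km)
  cv[h == 0] <- cv[h == 0] + model$nugget
  cv
}

# dense distance matrix between two coordinate sets (n x 2, m x 2)
dist_mat <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

# simulate a zero-mean Gaussian random field at coords with the given
# correlation form, partial sill and range, via dense Cholesky
sim_grf <- function(coords, sill, range_km, form = "exponential") {
  n <- nrow(coords)
  if (sill == 0) return(numeric(n))
  C <- sill * vgm_corr(form, dist_mat(coords, coords), range_km)
  # tiny jitter keeps the Cholesky stable for smooth forms
  L <- chol(C + diag(1e-10 * sill, n))
  drop(crossprod(L, stats::rnorm(n)))
}

#' Empirical semivariogram
#'
#' Classical (Matheron) binned estimator: half the average squared difference
#' of all point pairs falling in each distance bin.
#'
#' @param coords matrix/data.frame with two columns (km).
#' @param z numeric values at `coords`.
#' @param n_lags number of distance bins.
#' @param cutoff maximum pair distance considered; default half the maximum
#'   distance between points.
#' @return data.frame with `lag` (bin midpoint, km), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(coords, z, n_lags = 12, cutoff = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 points")
  d <- dist_mat(coords, coords)
  iu <- upper.tri(d)
  dd <- d[iu]
  sq <- (outer(z, z, "-")^2)[iu] / 2
  if (is.null(cutoff)) cutoff <- max(dd) / 2
  keep <- dd > 0 & dd <= cutoff
  dd <- dd[keep]; sq <- sq[keep]
  br <- seq(0, cutoff, length.out = n_lags + 1)
  bin <- cut(dd, br, include.lowest = TRUE, labels = FALSE)
  g <- tapply(sq, bin, mean)
  np <- tapply(sq, bin, length)
  mid <- (br[-1] + br[-length(br)]) / 2
  idx <- as.integer(names(g))
  data.frame(lag = mid[idx], gamma = as.numeric(g),
             n_pairs = as.integer(np))
}
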