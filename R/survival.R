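#' Cox model with time-varying exposure and age class
#'
#' Fits the hazard model on counting-process rows: exposure (per chosen
#' increment, default 10 ug/m3) and age class enter as time-varying terms
#' through the (start, stop] interval structure; baseline covariates are
#' adjusted for; the variance is a cluster-robust sandwich aggregated at the
#' first-stage sampling unit (municipality) to respect the two-stage survey
#' design. Ties use the Efron approximation (tied event days are inevitable
#' at day granularity).
#'
#' @param intervals counting-process rows from [build_counting_process()].
#' @param covariates baseline covariate columns to adjust for (those present
#'   are used).
#' @param cluster column defining the robust-variance clusters; default
#'   `"municipality_id"`, the primary sampling unit. `NULL` for naive
#'   variance.
#' @param increment exposure increment for the reported hazard ratio, ug/m3.
#' @param age how the time-varying age class enters: `"strata"` (default; the
#'   baseline hazard is stratified by age class, robust to sparse classes) or
#'   `"covariate"` (age class as a time-varying factor).
#' @param strata_covs covariates moved into `strata()` (the proportional-
#'   hazards fallback); they then have no reported coefficient.
#' @param cause_name,pollutant labels carried into the result.
#' @return object of class `hazard_fit`: the `coxph` fit plus
#'   `hr_per_increment`, `robust_se` (of the log-HR), `ci95`, `n_subjects`,
#'   `n_events`, `coef_table`, `strata`.
#' @export
fit_cox <- function(intervals,
                    covariates = c("sex", "education", "marital",
                                   "occupation", "smoking",
                                   "physical_activity", "bmi"),
                    cluster = "municipality_id", increment = 10,
                    age = c("strata", "covariate"), strata_covs = NULL,
                    cause_name = NULL, pollutant = NULL) {
  age <- match.arg(age)
  if (sum(intervals$event) < 1) stop("zero events: nothing to fit")
  d <- intervals
  d$expo <- d$exposure / increment
  d$age_class <- factor(d$age_class)
  if ("education" %in% names(d)) d$education <- factor(d$education,
                                                       ordered = FALSE)
  if ("physical_activity" %in% names(d))
    d$physical_activity <- factor(d$physical_activity, ordered = FALSE)
  covariates <- setdiff(intersect(covariates, names(d)), strata_covs)
  terms <- c("expo",
             if (age == "covariate") "age_class" else "strata(age_class)",
             covariates,
             if (length(strata_covs))
               sprintf("strata(%s)", paste(strata_covs, collapse = ", ")))
  fml <- stats::as.formula(paste("survival::Surv(tstart, tstop, event) ~",
                                 paste(terms, collapse = " + ")))
  cl_vec <- if (!is.null(cluster)) d[[cluster]]
  not_converged <- NULL
  fit <- withCallingHandlers({
    if (is.null(cluster))
      survival::coxph(fml, data = d, ties = "efron", model = TRUE)
    else
      survival::coxph(fml, data = d, ties = "efron", model = TRUE,
                      cluster = cl_vec, robust = TRUE)
  }, warning = function(w) {
    if (grepl("did not converge", conditionMessage(w))) {
      not_converged <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    }
  })
  if (!is.null(not_converged))
    stop("Cox fit did not converge after ", fit$iter, " iterations: ",
         not_converged)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("collinear covariates (NA coefficients): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  se <- sqrt(diag(fit$var))[which(names(cf) == "expo")]
  b <- cf[["expo"]]
  structure(list(fit = fit,
                 cause_name = cause_name, pollutant = pollutant,
                 increment = increment,
                 hr_per_increment = exp(b),
                 log_hr = b, robust_se = se,
                 ci95 = exp(b + c(-1, 1) * stats::qnorm(0.975) * se),
                 n_subjects = length(unique(intervals$subject_id)),
                 n_events = sum(intervals$event),
                 coef_table = summary(fit)$coefficients,
                 strata = strata_covs, age = age),
            class = "hazard_fit")
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat(sprintf("hazard_fit%s%s: HR %.3f (95%% CI %.3f-%.3f) per %g ug/m3; %d events / %d subjects\n",
              if (!is.null(x$cause_name)) paste0(" ", x$cause_name) else "",
              if (!is.null(x$pollutant)) paste0(" vs ", x$pollutant) else "",
              x$hr_per_increment, x$ci95[1], x$ci95[2], x$increment,
              x$n_events, x$n_subjects))
  if (length(x$strata))
    cat("  stratified by:", paste(x$strata, collapse = ", "), "\n")
  invisible(x)
}

#' Proportional-hazards diagnostics for the fixed predictors
#'
#' Scaled-Schoenfeld-residual test per fixed baseline covariate (the
#' time-varying exposure and age class are excluded by construction). A
#' covariate is marked for stratification when its p-value falls below
#' `alpha`.
#'
#' @param hf a `hazard_fit`.
#' @param alpha decision threshold, default 0.05.
#' @param transform time transform passed to [survival::cox.zph()].
#' @return data.frame (covariate, chisq, df, p, decision).
#' @export
test_ph <- function(hf, alpha = 0.05, transform = "km") {
  stopifnot(inherits(hf, "hazard_fit"))
  zp <- survival::cox.zph(hf$fit, transform = transform, terms = TRUE)
  tab <- as.data.frame(zp$table)
  tab$covariate <- rownames(tab)
  drop <- c("GLOBAL", "expo", "age_class")
  tab <- tab[!tab$covariate %in% drop, , drop = FALSE]
  data.frame(covariate = tab$covariate, chisq = tab$chisq, df = tab$df,
             p = tab$p,
             decision = ifelse(tab$p < alpha, "stratify", "keep"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Effect-modification likelihood-ratio test
#'
#' Compares the hazard model with and without exposure-by-modifier
#' interaction terms; the two fits differ only in those terms, so twice the
#' partial-log-likelihood difference is chi-square with one degree of
#' freedom per added term.
#'
#' @param intervals counting-process rows.
#' @param modifier one of the fitted covariates.
#' @param covariates,increment,age as in [fit_cox()].
#' @param alpha significance threshold recorded with the decision.
#' @return object of class `interaction_test`: modifier, log-likelihoods,
#'   LRT statistic, df, p-value.
#' @export
fit_with_interaction <- function(intervals, modifier,
                                 covariates = c("sex", "education", "marital",
                                                "occupation", "smoking",
                                                "physical_activity", "bmi"),
                                 increment = 10, age = "strata",
                                 alpha = 0.05) {
  covariates <- intersect(covariates, names(intervals))
  if (!modifier %in% covariates)
    stop("modifier must be one of the fitted covariates")
  red <- fit_cox(intervals, covariates, cluster = NULL,
                 increment = increment, age = age)
  d <- intervals
  d$expo <- d$exposure / increment
  d$age_class <- factor(d$age_class)
  if ("education" %in% names(d)) d$education <- factor(d$education,
                                                       ordered = FALSE)
  if ("physical_activity" %in% names(d))
    d$physical_activity <- factor(d$physical_activity, ordered = FALSE)
  terms <- c("expo", if (age == "covariate") "age_class" else
    "strata(age_class)", covariates, sprintf("expo:%s", modifier))
  fml <- stats::as.formula(paste("survival::Surv(tstart, tstop, event) ~",
                                 paste(terms, collapse = " + ")))
  full <- survival::coxph(fml, data = d, ties = "efron")
  ll_full <- full$loglik[2]
  ll_red <- red$fit$loglik[2]
  df <- length(stats::coef(full)) - length(stats::coef(red$fit))
  lrt <- max(2 * (ll_full - ll_red), 0)
  structure(list(modifier = modifier, ll_full = ll_full, ll_reduced = ll_red,
                 lrt = lrt, df = df,
                 p = stats::pchisq(lrt, df, lower.tail = FALSE),
                 alpha = alpha, fit_full = full, fit_reduced = red$fit),
            class = "interaction_test")
}

#' @export
print.interaction_test <- function(x, ...) {
  cat(sprintf("interaction_test: exposure x %s, LRT %.2f on %d df, p = %.4g\n",
              x$modifier, x$lrt, x$df, x$p))
  invisible(x)
}
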