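#' Stratified person-years from counting-process rows
#'
#' Sums follow-up time by calendar year, sex and age class, splitting rows at
#' calendar-year boundaries internally. Person-years are day counts divided
#' by 365.25, so the stratified table decomposes the total additively.
#'
#' @param intervals counting-process rows (needs `tstart`, `tstop` numeric
#'   days, plus any `by` columns; `year` is derived internally).
#' @param by stratification columns, any subset of
#'   `c("year", "sex", "age_class")`.
#' @return data.frame with the `by` columns and `person_years`.
#' @export
person_years <- function(intervals, by = c("year", "sex", "age_class")) {
  if (any(intervals$tstop <= intervals$tstart))
    stop("interval spanning no valid calendar day")
  t0 <- intervals$tstart; t1 <- intervals$tstop
  y0 <- as.integer(format(as.Date(floor(t0), origin = "1970-01-01"), "%Y"))
  # last instant covered is t1 - eps: its day is ceiling(t1) - 1
  y1 <- as.integer(format(as.Date(ceiling(t1) - 1, origin = "1970-01-01"),
                          "%Y"))
  ny <- y1 - y0 + 1L
  idx <- rep(seq_along(t0), ny)
  yr <- sequence(ny) - 1L + y0[idx]
  jan1 <- function(y) as.numeric(as.Date(sprintf("%d-01-01", y)))
  a <- pmax(t0[idx], jan1(yr))
  b <- pmin(t1[idx], jan1(yr + 1L))
  py <- (b - a) / DAYS_PER_YEAR
  key <- data.frame(row = idx, year = yr)
  for (cl in setdiff(by, "year")) key[[cl]] <- intervals[[cl]][idx]
  g <- interaction(key[, by, drop = FALSE], drop = TRUE, lex.order = TRUE)
  agg <- tapply(py, g, sum)
  out <- data.frame(do.call(rbind, strsplit(names(agg), ".", fixed = TRUE)),
                    stringsAsFactors = FALSE)
  names(out) <- by
  if ("year" %in% by) out$year <- as.integer(out$year)
  out$person_years <- as.numeric(agg)
  rownames(out) <- NULL
  out
}

#' Expected events from a rate table
#'
#' Multiplies stratum-specific event rates (per person-year) with the
#' cohort's person-years. Every stratum holding person-time must be covered
#' by the rate table.
#'
#' @param py person-years table from [person_years()].
#' @param rates data.frame with the same stratification columns plus `rate`.
#' @return `py` with columns `rate` and `expected` appended.
#' @export
expected_events <- function(py, rates) {
  by <- setdiff(names(py), "person_years")
  if (!all(by %in% names(rates)))
    stop("rate table lacks stratification columns: ",
         paste(setdiff(by, names(rates)), collapse = ", "))
  if (any(rates$rate < 0)) stop("rates must be >= 0")
  keyfun <- function(d) do.call(paste, d[by])
  m <- match(keyfun(py), keyfun(rates))
  miss <- is.na(m) & py$person_years > 0
  if (any(miss))
    stop("rate table does not cover strata: ",
         paste(utils::head(keyfun(py)[miss], 5), collapse = "; "))
  py$rate <- rates$rate[m]
  py$expected <- py$rate * py$person_years
  py
}

#' Observed/expected completeness report
#'
#' Linkage-completeness check: the number of events observed in the cohort is
#' compared with the number expected from reference rates applied to the
#' cohort's person-years. Reported per stratum and in total, with an exact
#' Poisson 95% interval for the O/E ratio; a stratum is flagged when that
#' interval excludes 1.
#'
#' @param intervals counting-process rows with an `event` column.
#' @param rates rate table, see [expected_events()].
#' @param by stratification columns.
#' @return data.frame (strata, observed, expected, oe, ci_lo, ci_hi,
#'   flagged), with a `"TOTAL"` row appended.
#' @export
oe_report <- function(intervals, rates, by = c("year", "sex", "age_class")) {
  py <- person_years(intervals, by = by)
  exp_tab <- expected_events(py, rates)
  ev <- intervals[intervals$event == 1, , drop = FALSE]
  if (nrow(ev) > 0) {
    ev_year <- as.integer(format(as.Date(ev$tstop - 1, origin = "1970-01-01"),
                                 "%Y"))
    kd <- list(year = ev_year)
    for (cl in setdiff(by, "year")) kd[[cl]] <- ev[[cl]]
    ev_key <- do.call(paste, kd[by])
    obs <- table(ev_key)
    key <- do.call(paste, exp_tab[by])
    exp_tab$observed <- as.integer(obs[key])
    exp_tab$observed[is.na(exp_tab$observed)] <- 0L
  } else exp_tab$observed <- 0L
  tot <- data.frame(matrix("TOTAL", 1, length(by)), stringsAsFactors = FALSE)
  names(tot) <- by
  tot$person_years <- sum(exp_tab$person_years)
  tot$rate <- NA_real_
  tot$expected <- sum(exp_tab$expected)
  tot$observed <- sum(exp_tab$observed)
  if ("year" %in% by) exp_tab$year <- as.character(exp_tab$year)
  out <- rbind(exp_tab, tot)
  o <- out$observed; e <- out$expected
  out$oe <- ifelse(e > 0, o / e, NA_real_)
  out$ci_lo <- ifelse(e > 0, ifelse(o == 0, 0, stats::qgamma(0.025, o) / e),
                      NA_real_)
  out$ci_hi <- ifelse(e > 0, stats::qgamma(0.975, o + 1) / e, NA_real_)
  out$flagged <- !is.na(out$oe) & (out$ci_lo > 1 | out$ci_hi < 1)
  rownames(out) <- NULL
  out
}

#' Record-linkage completeness summary
#'
#' @param subjects cohort data.frame with a logical `linked` column.
#' @return list (n_total, n_linked, pct_linked).
#' @export
linkage_summary <- function(subjects) {
  n <- nrow(subjects)
  if (n == 0) stop("empty cohort")
  nl <- sum(subjects$linked)
  list(n_total = n, n_linked = nl, pct_linked = 100 * nl / n)
}

#' Representativeness of the linked sample
#'
#' Compares the categorical covariate distributions of the full enrolled
#' sample and the linked subsample, flagging categories whose proportions
#' differ by more than a threshold (default 1 percentage point).
#'
#' @param full,linked data.frames sharing the covariate coding.
#' @param covariates covariate column names to compare.
#' @param threshold_pp flag threshold in percentage points.
#' @return data.frame (covariate, category, pct_full, pct_linked, diff_pp,
#'   flagged).
#' @export
representativeness <- function(full, linked, covariates, threshold_pp = 1) {
  miss <- setdiff(covariates, intersect(names(full), names(linked)))
  if (length(miss))
    stop("covariate absent from a sample: ", paste(miss, collapse = ", "))
  out <- lapply(covariates, function(cv) {
    lev <- if (is.factor(full[[cv]])) levels(full[[cv]]) else
      sort(unique(as.character(full[[cv]])))
    pf <- 100 * prop.table(table(factor(full[[cv]], levels = lev)))
    pl <- 100 * prop.table(table(factor(linked[[cv]], levels = lev)))
    data.frame(covariate = cv, category = lev,
               pct_full = as.numeric(pf), pct_linked = as.numeric(pl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$diff_pp <- out$pct_linked - out$pct_full
  out$flagged <- abs(out$diff_pp) > threshold_pp
  rownames(out) <- NULL
  out
}
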