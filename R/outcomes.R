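#' Cause-group definitions
#'
#' Loads the cause definitions shipped with the package (or a user-edited
#' copy): six mortality cause groups with ICD-9 and ICD-10 ranges, and the
#' hospital-admission cause list in ICD-9 with search scope (main cause only,
#' or all six diagnosis positions for diabetes and COPD) and washout windows
#' (28 days for myocardial infarction and angina, 90 days for lower
#' respiratory tract infections; all other causes are first-admission-only).
#'
#' @param path YAML file; default the copy under the package's `extdata`.
#' @return list with elements `death_causes` and `admission_causes`, each a
#'   named list of cause definitions.
#' @export
read_cause_definitions <- function(path = system.file(
  "extdata", "cause_definitions.yaml", package = "airsurv")) {
  raw <- yaml::read_yaml(path)
  fix <- function(lst, record_type) {
    out <- lapply(lst, function(cd) {
      cd$record_type <- cd$record_type %||% record_type
      cd$washout_days <- cd$washout_days %||% NULL
      for (r in cd$icd9$ranges)
        if (r[[1]] > r[[2]]) stop("ill-formed ICD-9 range in ", cd$cause_name)
      cd
    })
    names(out) <- vapply(out, `[[`, character(1), "cause_name")
    out
  }
  list(death_causes = fix(raw$death_causes, "death"),
       admission_causes = fix(raw$admission_causes, "admission"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 3-digit ICD-9 rubric as integer; V/E supplementary codes return NA (they
# can never match the numeric ranges); anything else is malformed
icd9_rubric <- function(code, strict = TRUE) {
  code <- toupper(trimws(as.character(code)))
  out <- rep(NA_integer_, length(code))
  num <- grepl("^[0-9]{3}", code)
  out[num] <- as.integer(substr(code[num], 1, 3))
  supp <- grepl("^[VE][0-9]+", code)
  bad <- !num & !supp & !is.na(code) & code != ""
  if (strict && any(bad)) stop("malformed ICD-9 code: ", code[bad][1])
  out
}

# ICD-10 letter+2-digit rubric mapped to an ordered integer key
icd10_key <- function(code, strict = TRUE) {
  code <- toupper(trimws(as.character(code)))
  ok <- grepl("^[A-Z][0-9]{2}", code)
  bad <- !ok & !is.na(code) & code != ""
  if (strict && any(bad)) stop("malformed ICD-10 code: ", code[bad][1])
  out <- rep(NA_integer_, length(code))
  out[ok] <- (match(substr(code[ok], 1, 1), LETTERS) - 1L) * 100L +
    as.integer(substr(code[ok], 2, 3))
  out
}

in_ranges9 <- function(rubric, ranges, exclude = NULL) {
  hit <- rep(FALSE, length(rubric))
  for (r in ranges) hit <- hit | (!is.na(rubric) & rubric >= r[[1]] & rubric <= r[[2]])
  for (r in exclude) hit <- hit & !(!is.na(rubric) & rubric >= r[[1]] & rubric <= r[[2]])
  hit
}

in_ranges10 <- function(key, ranges, exclude = NULL) {
  hit <- rep(FALSE, length(key))
  for (r in ranges) {
    lo <- icd10_key(r[[1]]); hi <- icd10_key(r[[2]])
    hit <- hit | (!is.na(key) & key >= lo & key <= hi)
  }
  for (r in exclude) {
    lo <- icd10_key(r[[1]]); hi <- icd10_key(r[[2]])
    hit <- hit & !(!is.na(key) & key >= lo & key <= hi)
  }
  hit
}

#' Classify an underlying cause-of-death code
#'
#' Maps one ICD code to the set of mortality cause groups it belongs to.
#' Groups overlap by design: any lung-cancer death is also a non-accidental
#' death. Codes outside all ranges (e.g. injuries) map to no group.
#'
#' @param code a single ICD code (e.g. `"162"`, `"C34"`).
#' @param system `"ICD9"` or `"ICD10"` (deaths through 2002 are ICD-9 coded,
#'   from 2003 ICD-10).
#' @param causes death-cause definitions, see [read_cause_definitions()].
#' @return character vector of matching cause names (possibly empty).
#' @export
classify_death <- function(code, system = c("ICD9", "ICD10"),
                           causes = read_cause_definitions()$death_causes) {
  system <- match.arg(system)
  if (length(code) != 1) stop("classify_death takes a single code")
  if (system == "ICD9") {
    r <- icd9_rubric(code, strict = TRUE)
    hit <- vapply(causes, function(cd)
      in_ranges9(r, cd$icd9$ranges, cd$icd9$exclude), logical(1))
  } else {
    k <- icd10_key(code, strict = TRUE)
    hit <- vapply(causes, function(cd)
      in_ranges10(k, cd$icd10$ranges, cd$icd10$exclude), logical(1))
  }
  names(causes)[hit]
}

#' Match a hospital admission against one cause definition
#'
#' Admission records carry up to six ICD-9 diagnosis codes (position 1 = main
#' cause). Causes with `main_code_only` scope inspect position 1 only;
#' `all_six_codes` causes (diabetes, COPD) are searched in every position.
#'
#' @param codes character vector of 1 to 6 ICD-9 codes (NA for unused
#'   positions); position 1 first.
#' @param cause_def one admission cause definition.
#' @return TRUE if the admission matches the cause.
#' @export
classify_admission <- function(codes, cause_def) {
  if (!identical(cause_def$record_type, "admission"))
    stop("cause_def must be an admission cause")
  codes <- codes[!is.na(codes) & codes != ""]
  if (length(codes) == 0) stop("empty code list")
  scope <- if (identical(cause_def$search_scope, "all_six_codes"))
    codes else codes[1]
  any(in_ranges9(icd9_rubric(scope, strict = TRUE),
                 cause_def$icd9$ranges, cause_def$icd9$exclude))
}

#' Reduce same-cause events to incident events
#'
#' Without a washout window only the earliest event is kept (first-admission
#' rule). With a washout of `d` days a greedy scan keeps an event iff it
#' falls `d` or more days after the last *kept* event.
#'
#' @param dates event dates (Date or numeric days) of one subject and cause;
#'   sorted internally.
#' @param washout_days integer washout, or NULL for first-event-only.
#' @return the kept dates, ascending. Idempotent.
#' @export
dedup_incident <- function(dates, washout_days = NULL) {
  if (length(dates) == 0) return(dates)
  dates <- sort(dates)
  if (is.null(washout_days)) return(dates[1])
  keep <- logical(length(dates))
  keep[1] <- TRUE
  last <- dates[1]
  for (k in seq_along(dates)[-1]) {
    if (as.numeric(dates[k] - last) >= washout_days) {
      keep[k] <- TRUE
      last <- dates[k]
    }
  }
  dates[keep]
}

#' Incident events of one cause across a cohort
#'
#' Filters event records by record type, classifies them against the cause
#' definition, and applies [dedup_incident()] per subject.
#'
#' @param events data.frame of event records (subject_id, event_date,
#'   record_type, code_system, code1..code6).
#' @param cause_def one cause definition (death or admission).
#' @return data.frame (subject_id, event_date) of incident events, ordered by
#'   subject and date.
#' @export
incident_events <- function(events, cause_def) {
  ev <- events[events$record_type == cause_def$record_type, , drop = FALSE]
  if (nrow(ev) == 0)
    return(data.frame(subject_id = character(0),
                      event_date = as.Date(character(0))))
  if (cause_def$record_type == "death") {
    hit <- logical(nrow(ev))
    is9 <- ev$code_system == "ICD9"
    hit[is9] <- in_ranges9(icd9_rubric(ev$code1[is9], strict = FALSE),
                           cause_def$icd9$ranges, cause_def$icd9$exclude)
    hit[!is9] <- in_ranges10(icd10_key(ev$code1[!is9], strict = FALSE),
                             cause_def$icd10$ranges, cause_def$icd10$exclude)
  } else {
    cols <- if (identical(cause_def$search_scope, "all_six_codes"))
      paste0("code", 1:6) else "code1"
    hit <- rep(FALSE, nrow(ev))
    for (cl in cols)
      hit <- hit | in_ranges9(icd9_rubric(ev[[cl]], strict = FALSE),
                              cause_def$icd9$ranges, cause_def$icd9$exclude)
  }
  ev <- ev[hit, , drop = FALSE]
  if (nrow(ev) == 0)
    return(data.frame(subject_id = character(0),
                      event_date = as.Date(character(0))))
  sp <- split(ev$event_date, ev$subject_id)
  kept <- lapply(sp, dedup_incident, washout_days = cause_def$washout_days)
  out <- data.frame(subject_id = rep(names(kept), lengths(kept)),
                    event_date = as.Date(unlist(kept),
                                         origin = "1970-01-01"),
                    stringsAsFactors = FALSE)
  out[order(out$subject_id, out$event_date), ]
}

#' Expand subjects into counting-process follow-up intervals
#'
#' Each linked subject's follow-up is split at risk-set boundaries and
#' 5-year age-class boundaries; intervals carry the municipality risk-set
#' exposure and the baseline covariates. Follow-up is censored at death (any
#' cause), end of window, or the subject's first analyzed incident event,
#' whichever comes first; for admission outcomes the clock starts 2001-01-01
#' (admission records are linkable only from 2001). Incident events dated
#' before a subject's follow-up start are dropped with a logged count
#' (attribute `n_dropped_events`).
#'
#' @param subjects cohort data.frame (see [sample_cohort()] for the schema);
#'   only `linked` subjects enter.
#' @param riskset_exposure risk-set exposure table from
#'   [build_risk_set_exposure()] (or [single_year_exposure()]), one
#'   pollutant.
#' @param events incident events of the analyzed cause
#'   (data.frame subject_id, event_date), e.g. from [incident_events()].
#' @param record_type `"death"` or `"admission"`; controls the follow-up
#'   start.
#' @param deaths data.frame (subject_id, event_date) of all-cause deaths used
#'   as censoring; NULL for none.
#' @param window overall follow-up Dates, default 1999-01-01 to 2008-12-31.
#' @param age_width age-class width in years.
#' @return data.frame of counting-process rows: subject_id, municipality_id,
#'   household_id, tstart, tstop (numeric days), age_class, riskset,
#'   exposure, event (0/1), and the baseline covariates.
#' @export
build_counting_process <- function(subjects, riskset_exposure, events,
                                   record_type = c("death", "admission"),
                                   deaths = NULL,
                                   window = as.Date(c("1999-01-01",
                                                      "2008-12-31")),
                                   age_width = 5) {
  record_type <- match.arg(record_type)
  subjects <- subjects[subjects$linked, , drop = FALSE]
  if (nrow(subjects) == 0) stop("no linked subjects")
  w <- as.Date(window)
  if (record_type == "admission")
    w[1] <- max(w[1], as.Date("2001-01-01"))
  w0 <- as.numeric(w[1])
  start <- pmax(as.numeric(subjects$enroll_date), w0)
  # first analyzed incident event at/after each subject's start
  ev_num <- as.numeric(events$event_date)
  ei <- match(events$subject_id, subjects$subject_id)
  live <- !is.na(ei) & ev_num >= start[ei]
  n_dropped <- sum(!is.na(ei) & ev_num < start[ei])
  if (n_dropped > 0)
    message(sprintf("build_counting_process: %d event(s) before follow-up start dropped",
                    n_dropped))
  first_ev <- rep(Inf, nrow(subjects))
  if (any(live)) {
    agg <- tapply(ev_num[live], ei[live], min)
    first_ev[as.integer(names(agg))] <- agg
  }
  death_num <- rep(Inf, nrow(subjects))
  if (!is.null(deaths) && nrow(deaths) > 0) {
    di <- match(deaths$subject_id, subjects$subject_id)
    ok <- !is.na(di)
    agg <- tapply(as.numeric(deaths$event_date)[ok], di[ok], min)
    death_num[as.integer(names(agg))] <- agg
  }
  # stop is exclusive: the event/death day itself contributes one day at risk
  end_override <- pmin(first_ev, death_num) + 1
  rows <- split_follow_up(subjects, w, age_width = age_width,
                          end_override = end_override)
  si <- match(rows$subject_id, subjects$subject_id)
  rows$event <- as.integer(is.finite(first_ev[si]) &
                             abs(rows$tstop - (first_ev[si] + 1)) < 1e-9)
  pol <- unique(riskset_exposure$pollutant)
  if (length(pol) > 1)
    stop("riskset_exposure must contain a single pollutant")
  m <- match(paste(rows$municipality_id, rows$riskset),
             paste(riskset_exposure$municipality_id,
                   riskset_exposure$interval))
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop("missing exposure for municipality ", rows$municipality_id[bad],
         " in risk set ", rows$riskset[bad])
  }
  rows$exposure <- riskset_exposure$exposure[m]
  covs <- c("sex", "education", "marital", "occupation", "smoking",
            "physical_activity", "bmi")
  covs <- covs[covs %in% names(subjects)]
  for (cl in covs) rows[[cl]] <- subjects[[cl]][si]
  attr(rows, "n_dropped_events") <- n_dropped
  attr(rows, "window") <- w
  rows
}
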