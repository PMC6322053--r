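defs <- read_cause_definitions()

test_that("death classification matches the printed cause ranges", {
  expect_setequal(classify_death("162", "ICD9"),
                  c("non_accidental", "lung_cancer"))
  expect_setequal(classify_death("C34", "ICD10"),
                  c("non_accidental", "lung_cancer"))
  expect_false("neoplasm_excl_lung" %in% classify_death("C34", "ICD10"))
  expect_false("neoplasm_excl_lung" %in% classify_death("162", "ICD9"))
  expect_setequal(classify_death("174", "ICD9"),
                  c("non_accidental", "neoplasm_excl_lung"))
  expect_equal(classify_death("800", "ICD9"), character(0))
  expect_equal(classify_death("V09", "ICD10"), character(0))
  expect_setequal(classify_death("410", "ICD9"), c("non_accidental", "cvd"))
  expect_setequal(classify_death("G20", "ICD10"),
                  c("non_accidental", "nervous"))
  expect_error(classify_death("xx", "ICD9"), "malformed")
  expect_error(classify_death("9", "ICD10"), "malformed")
})

test_that("ICD-9 classification agrees with a brute-force range oracle over all rubrics", {
  # independent oracle: direct numeric interval tests transcribed separately
  oracle <- function(k) {
    out <- character(0)
    if (k >= 1 && k <= 799) out <- c(out, "non_accidental")
    if (k >= 390 && k <= 459) out <- c(out, "cvd")
    if (k >= 460 && k <= 519) out <- c(out, "respiratory")
    if (k >= 140 && k <= 239 && k != 162) out <- c(out, "neoplasm_excl_lung")
    if (k == 162) out <- c(out, "lung_cancer")
    if (k >= 320 && k <= 359) out <- c(out, "nervous")
    out
  }
  for (k in 1:999) {
    code <- sprintf("%03d", k)
    expect_setequal(classify_death(code, "ICD9"), oracle(k))
  }
})

test_that("four/five-digit ICD-9 codes classify by their 3-digit rubric", {
  expect_setequal(classify_death("1620", "ICD9"),
                  c("non_accidental", "lung_cancer"))
  expect_true(classify_admission(c("4662"), defs$admission_causes$LRTI))
})

test_that("admission search scope separates main-cause from all-six causes", {
  codes <- c("428", "250", NA, NA, NA, NA)
  expect_true(classify_admission(codes, defs$admission_causes$diabetes))
  expect_true(classify_admission(codes, defs$admission_causes$heart))
  expect_true(classify_admission(codes, defs$admission_causes$circulatory))
  expect_false(classify_admission(c("428", "493"),
                                  defs$admission_causes$asthma))
  expect_true(classify_admission(c("493"), defs$admission_causes$asthma))
  expect_true(classify_admission(c("428", NA, NA, NA, NA, "496"),
                                 defs$admission_causes$COPD))
  expect_error(classify_admission(c(NA, NA), defs$admission_causes$asthma),
               "empty")
  expect_error(classify_admission("428", defs$death_causes$cvd), "admission")
})

test_that("washout deduplication reproduces the rule book", {
  d0 <- as.Date("2003-01-01")
  # MI: 28-day washout anchored at the last kept event
  expect_equal(dedup_incident(d0 + c(0, 10, 40), 28), d0 + c(0, 40))
  # LRTI: 90-day washout
  expect_equal(dedup_incident(d0 + c(0, 60), 90), d0)
  # first-admission-only
  expect_equal(dedup_incident(d0 + c(0, 400), NULL), d0)
  # anchoring: events at 0, 20, 40 with washout 28 keep {0, 40}
  expect_equal(dedup_incident(d0 + c(40, 0, 20), 28), d0 + c(0, 40))
})

test_that("deduplication is idempotent on random event lists", {
  set.seed(15)
  for (r in 1:1000) {
    dates <- sort(sample.int(1000, sample(1:8, 1)))
    w <- sample(list(NULL, 28, 90), 1)[[1]]
    once <- dedup_incident(dates, w)
    expect_identical(dedup_incident(once, w), once)
    if (!is.null(w)) expect_true(all(diff(once) >= w))
  }
})

test_that("incident extraction composes classification and dedup per subject", {
  ev <- data.frame(
    subject_id = c("A", "A", "A", "B"),
    event_date = as.Date("2003-01-01") + c(0, 10, 40, 5),
    record_type = "admission", code_system = "ICD9",
    code1 = c("410", "410", "410", "780"),
    code2 = c(NA, NA, NA, "250"), code3 = NA, code4 = NA, code5 = NA,
    code6 = NA, stringsAsFactors = FALSE)
  mi <- incident_events(ev, defs$admission_causes$MI)
  expect_equal(nrow(mi), 2)
  expect_equal(mi$subject_id, c("A", "A"))
  dia <- incident_events(ev, defs$admission_causes$diabetes)
  expect_equal(dia$subject_id, "B")  # found in position 2
})

test_that("counting process traces a hand-checked subject", {
  # enrolled 1999-01-01 at age 58; 5-year age boundary at 60 in 2001; dies of
  # the analyzed cause 2004-06-30: risk-set splits 2003-01-01, event terminal
  s <- toy_subject(age = 58)
  rse <- toy_riskset("M1", exposure = 0)
  rse$exposure <- c(10, 15, 20, 25)[match(rse$interval,
                                          risk_set_intervals()$interval)]
  death <- data.frame(subject_id = "P1",
                      event_date = as.Date("2004-06-30"))
  cp <- build_counting_process(s, rse, death, "death", deaths = death)
  expect_gte(nrow(cp), 3)
  expect_equal(sum(cp$event), 1)
  expect_equal(cp$event[nrow(cp)], 1)
  # interval covering 2003+ carries the risk-set-2 exposure
  in2003 <- cp[cp$tstart >= as.numeric(as.Date("2003-01-01")), ]
  expect_true(all(in2003$exposure == 15))
  expect_true(all(cp$tstop > cp$tstart))
  # contiguity and person-time conservation (event day inclusive)
  expect_equal(cp$tstart[-1], cp$tstop[-nrow(cp)])
  expect_equal(sum(cp$tstop - cp$tstart),
               as.numeric(as.Date("2004-06-30") - as.Date("1999-01-01")) + 1)
  # age class changes exactly at the 5-year boundary
  expect_equal(unique(cp$age_class), c("55-59", "60-64"))
})

test_that("admission outcomes start the clock in 2001 and drop earlier events", {
  s <- toy_subject(age = 40)
  rse <- toy_riskset("M1", exposure = 20)
  ev <- data.frame(subject_id = "P1",
                   event_date = as.Date(c("2000-06-01", "2004-03-01")))
  expect_message(
    cp <- build_counting_process(s, rse, ev, "admission"),
    "dropped")
  expect_equal(attr(cp, "n_dropped_events"), 1L)
  expect_equal(min(cp$tstart), as.numeric(as.Date("2001-01-01")))
  expect_equal(sum(cp$event), 1)
})

test_that("unlinked subjects are excluded and exposures must exist", {
  s <- rbind(toy_subject("P1"), toy_subject("P2", linked = FALSE))
  rse <- toy_riskset("M1", exposure = 20)
  none <- data.frame(subject_id = character(0),
                     event_date = as.Date(character(0)))
  cp <- build_counting_process(s, rse, none, "death")
  expect_setequal(unique(cp$subject_id), "P1")
  s2 <- toy_subject("P3", municipality_id = "M9")
  expect_error(build_counting_process(s2, rse, none, "death"),
               "M9")
})

test_that("cohort person-time matches a brute-force day-count oracle", {
  reg <- toy_region()
  subj <- sample_cohort(reg$munis, 6, 25, seed = 44)
  ann <- toy_annual(reg$munis$munis$municipality_id)
  w <- world_truth(baseline_hazard = default_baseline_hazard(scale = 6))
  ev <- simulate_events(subj, ann, w, admission_params = NULL, seed = 45)
  deaths <- ev[, c("subject_id", "event_date")]
  cp <- build_counting_process(subj, build_risk_set_exposure(ann), deaths,
                               "death", deaths = deaths)
  got_days <- sum(cp$tstop - cp$tstart)
  # oracle: per-subject day count from the raw tables
  lk <- subj[subj$linked, ]
  d <- as.numeric(deaths$event_date)[match(lk$subject_id,
                                           deaths$subject_id)]
  end <- pmin(ifelse(is.na(d), Inf, d + 1),
              as.numeric(as.Date("2008-12-31")) + 1)
  start <- pmax(as.numeric(lk$enroll_date),
                as.numeric(as.Date("1999-01-01")))
  expect_equal(got_days, sum(pmax(end - start, 0)))
  expect_equal(sum(cp$event), sum(!is.na(d) & d + 1 > start & d + 1 <= end))
  # each incident event appears in exactly one interval
  expect_equal(sum(cp$event), length(unique(cp$subject_id[cp$event == 1])))
})
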