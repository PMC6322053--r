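test_that("person-years decompose additively and respect simple cases", {
  # one subject, exactly 2 calendar years, no stratum change
  iv <- data.frame(tstart = as.numeric(as.Date("2000-01-01")),
                   tstop = as.numeric(as.Date("2002-01-01")),
                   sex = "F", age_class = "40-44")
  py <- person_years(iv)
  expect_equal(sum(py$person_years), 731 / 365.25)
  expect_equal(nrow(py), 2)  # split at the calendar-year boundary
  expect_equal(py$year, c(2000L, 2001L))
  # splitting at a birthday boundary conserves the total
  iv2 <- data.frame(tstart = as.numeric(as.Date("2000-03-01")) + c(0, 100),
                    tstop = as.numeric(as.Date("2000-03-01")) + c(100, 365),
                    sex = "M", age_class = c("44-44", "45-49"))
  expect_equal(sum(person_years(iv2)$person_years), 365 / 365.25,
               tolerance = 1e-9)
  expect_error(person_years(data.frame(tstart = 10, tstop = 10, sex = "F",
                                       age_class = "0-4")),
               "no valid calendar day")
})

test_that("stratified person-years equal a brute-force per-day tabulation", {
  reg <- toy_region()
  subj <- sample_cohort(reg$munis, 5, 15, seed = 51)
  rse <- toy_riskset(reg$munis$munis$municipality_id)
  none <- data.frame(subject_id = character(0),
                     event_date = as.Date(character(0)))
  cp <- build_counting_process(subj, rse, none, "death")
  py <- person_years(cp)
  # oracle: walk every calendar day of every row and accumulate the (possibly
  # fractional) overlap — interval ends at age-class boundaries are not whole
  # days
  pieces <- lapply(seq_len(nrow(cp)), function(k) {
    d <- seq(floor(cp$tstart[k]), ceiling(cp$tstop[k]) - 1)
    ov <- pmin(cp$tstop[k], d + 1) - pmax(cp$tstart[k], d)
    keep <- ov > 0
    data.frame(key = paste(format(as.Date(d[keep], origin = "1970-01-01"),
                                  "%Y"), cp$sex[k], cp$age_class[k]),
               ov = ov[keep])
  })
  pieces <- do.call(rbind, pieces)
  oracle <- tapply(pieces$ov, pieces$key, sum) / 365.25
  got <- structure(py$person_years,
                   names = paste(py$year, py$sex, py$age_class))
  expect_equal(sort(names(oracle)), sort(names(got)))
  expect_lt(max(abs(got[names(oracle)] - as.numeric(oracle))), 1e-6)
})

test_that("expected events are the rate-times-person-years product", {
  py <- data.frame(year = 2000L, sex = c("F", "M"), age_class = "60-64",
                   person_years = c(100, 50))
  rates <- data.frame(year = 2000L, sex = c("F", "M"), age_class = "60-64",
                      rate = c(0.01, 0.02))
  ee <- expected_events(py, rates)
  expect_equal(ee$expected, c(1.0, 1.0))
  rates0 <- transform(rates, rate = 0)
  expect_true(all(expected_events(py, rates0)$expected == 0))
  # linearity in both factors
  expect_equal(expected_events(transform(py, person_years = 2 * person_years),
                               rates)$expected, 2 * ee$expected)
  expect_equal(expected_events(py, transform(rates, rate = 3 * rate))$expected,
               3 * ee$expected)
  expect_error(expected_events(py, rates[1, ]), "cover")
})

test_that("linkage summary reports the survey percentages", {
  subj <- data.frame(linked = rep(c(TRUE, FALSE), c(128818, 140011 - 128818)))
  ls <- linkage_summary(subj)
  expect_equal(ls$n_total, 140011)
  expect_equal(ls$n_linked, 128818)
  expect_equal(round(ls$pct_linked), 92)
  expect_equal(linkage_summary(data.frame(linked = c(TRUE, TRUE)))$pct_linked,
               100)
  expect_equal(linkage_summary(data.frame(linked = FALSE))$pct_linked, 0)
  expect_error(linkage_summary(data.frame(linked = logical(0))), "empty")
})

test_that("representativeness flags only real distortions", {
  reg <- toy_region()
  subj <- sample_cohort(reg$munis, 8, 80, seed = 52)
  # identity comparison: all differences zero
  r0 <- representativeness(subj, subj, c("sex", "smoking", "education"))
  expect_true(all(r0$diff_pp == 0))
  expect_false(any(r0$flagged))
  # independent linkage at scale: sampling error stays below 1 pp nearly always
  set.seed(53)
  flags <- vapply(1:40, function(r) {
    big <- data.frame(smoking = sample(c("never", "former", "current"),
                                       1e5, TRUE, c(0.55, 0.22, 0.23)))
    linked <- big[runif(1e5) < 0.92, , drop = FALSE]
    any(representativeness(big, linked, "smoking")$flagged)
  }, logical(1))
  expect_gte(mean(!flags), 0.95)
  # constructed bias: smokers linked at 0.5 -> flagged
  set.seed(54)
  big <- data.frame(smoking = sample(c("never", "former", "current"),
                                     5e4, TRUE, c(0.55, 0.22, 0.23)))
  p <- ifelse(big$smoking == "current", 0.5, 1.0)
  linked <- big[runif(5e4) < p, , drop = FALSE]
  rb <- representativeness(big, linked, "smoking")
  expect_true(rb$flagged[rb$category == "current"])
  expect_error(representativeness(big, linked, "bmi"), "absent")
})

test_that("O/E report flags a cohort dying faster than its reference rates", {
  reg <- toy_region()
  subj <- sample_cohort(reg$munis, 8, 60, seed = 55)
  ann <- toy_annual(reg$munis$munis$municipality_id)
  w <- world_truth(beta_true = 0,
                   covariate_effects = list(education_per_level = 0,
                                            smoking_current = 0),
                   baseline_hazard = default_baseline_hazard(scale = 6))
  ev <- simulate_events(subj, ann, w, admission_params = NULL, seed = 56)
  deaths <- ev[, c("subject_id", "event_date")]
  cp <- build_counting_process(subj, build_risk_set_exposure(ann), deaths,
                               "death", deaths = deaths)
  rates <- do.call(rbind, lapply(1999:2008, function(y) {
    d <- w$baseline_hazard; d$year <- y; d
  }))
  oe <- oe_report(cp, rates)
  tot <- oe[nrow(oe), ]
  expect_true(tot$ci_lo < tot$oe & tot$oe < tot$ci_hi)
  expect_false(tot$flagged)  # matched rates: interval covers 1
  # halving the reference rates halves E and doubles O/E, which the exact
  # interval must flag at this sample size
  oe2 <- oe_report(cp, transform(rates, rate = rate / 2))
  expect_true(oe2$flagged[nrow(oe2)])
  expect_equal(oe2$expected[nrow(oe2)], tot$expected / 2)
})
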