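#' Default age- and sex-specific baseline mortality hazard
#'
#' A Gompertz-type schedule, `3e-5 * exp(0.085 * age_mid)` per person-year,
#' with a 1.5x male excess — the order of magnitude of all-cause mortality in
#' a western European population. Used both as the generator's ground truth
#' and as the rate table of the completeness self-consistency check.
#'
#' @param age_width age-class width in years.
#' @param max_age upper age covered by the table.
#' @param scale multiplier applied to all rates.
#' @return data.frame (age_class, sex, rate) with rate in events/person-year.
#' @export
default_baseline_hazard <- function(age_width = 5, max_age = 110, scale = 1) {
  lo <- seq(0, max_age, by = age_width)
  mid <- lo + age_width / 2
  rate <- 3e-5 * exp(0.085 * mid) * scale
  data.frame(age_class = rep(age_class(lo, age_width), 2),
             sex = rep(c("F", "M"), each = length(lo)),
             rate = c(rate, rate * 1.5),
             stringsAsFactors = FALSE)
}

#' Ground truth of the synthetic study world
#'
#' Bundles every parameter the generator uses, so downstream parameter
#' recovery can be checked against known values: the log hazard ratio per
#' 10 ug/m3, the true-field and model-bias parameters, station noise, the
#' baseline hazard schedule and the baseline covariate log-hazard effects.
#'
#' @param beta_true log hazard ratio per 10 ug/m3 of the driving pollutant.
#' @param pollutant pollutant driving the hazard.
#' @param field_params a [field_params()].
#' @param bias a [model_bias()] distorting the model surrogate.
#' @param station_noise_sd daily station noise sd, ug/m3 (>= 0).
#' @param baseline_hazard data.frame (age_class, sex, rate) in events per
#'   person-year; rates of 0 are allowed and simply produce no deaths.
#' @param covariate_effects list with `education_per_level` (log-HR per
#'   education level above the lowest) and `smoking_current` (log-HR for
#'   current smokers).
#' @param muni_frailty_sd sd of a shared log-normal municipality frailty on
#'   the hazard (0 = none); induces within-municipality hazard correlation
#'   that only cluster-robust variance estimators account for.
#' @param cause_mix named probabilities over the synthetic death causes.
#' @return list of class `world_truth`.
#' @export
world_truth <- function(beta_true = log(1.10), pollutant = "PM25",
                        field_params = airsurv::field_params(),
                        bias = model_bias(),
                        station_noise_sd = 2,
                        baseline_hazard = default_baseline_hazard(),
                        covariate_effects = list(education_per_level = 0.1,
                                                 smoking_current = 0.5),
                        muni_frailty_sd = 0,
                        cause_mix = c(cvd = 0.35, neoplasm_excl_lung = 0.22,
                                      lung_cancer = 0.07, respiratory = 0.08,
                                      nervous = 0.03, other = 0.17,
                                      accidental = 0.08)) {
  if (station_noise_sd < 0) stop("station_noise_sd must be >= 0")
  if (any(baseline_hazard$rate < 0)) stop("baseline hazard rates must be >= 0")
  if (muni_frailty_sd < 0) stop("muni_frailty_sd must be >= 0")
  structure(list(beta_true = beta_true, pollutant = pollutant,
                 field_params = field_params, bias = bias,
                 station_noise_sd = station_noise_sd,
                 baseline_hazard = baseline_hazard,
                 covariate_effects = covariate_effects,
                 muni_frailty_sd = muni_frailty_sd,
                 cause_mix = cause_mix / sum(cause_mix)),
            class = "world_truth")
}

# synthetic per-cause code pools; deaths switch coding system by year
death_code_pools <- list(
  cvd                = list(ICD9 = c("410", "431", "436"),
                            ICD10 = c("I21", "I64", "I25")),
  respiratory        = list(ICD9 = c("486", "491", "496"),
                            ICD10 = c("J18", "J44")),
  lung_cancer        = list(ICD9 = "162", ICD10 = "C34"),
  neoplasm_excl_lung = list(ICD9 = c("153", "174", "185"),
                            ICD10 = c("C18", "C50", "C61")),
  nervous            = list(ICD9 = c("332", "340"),
                            ICD10 = c("G20", "G35")),
  other              = list(ICD9 = c("250", "585"),
                            ICD10 = c("E11", "N18")),
  accidental         = list(ICD9 = c("812", "854"),
                            ICD10 = c("V09", "W19")))

#' Default admission-process parameters
#'
#' Per-cause admission rates (events per person-year) for a small set of
#' causes chosen to exercise the deduplication rules: a washout cause (MI),
#' an all-six-codes cause (diabetes), and two first-admission-only /
#' long-washout causes.
#'
#' @param scale multiplier on all rates.
#' @return data.frame (cause, rate, code, secondary_prob); `secondary_prob`
#'   is the probability the cause code lands in positions 2-6 with an
#'   unrelated main code, which only all-six-codes causes should detect.
#' @export
default_admission_params <- function(scale = 1) {
  data.frame(cause = c("MI", "diabetes", "asthma", "LRTI"),
             rate = c(0.004, 0.006, 0.003, 0.005) * scale,
             code = c("410", "250", "493", "466"),
             secondary_prob = c(0, 0.5, 0, 0),
             stringsAsFactors = FALSE)
}

#' Simulate deaths and hospital admissions for a cohort
#'
#' Death times are drawn from a piecewise-constant hazard
#' `baseline(age_class, sex) * exp(beta_true * exposure(t)/10 + covariate
#' effects)` where exposure(t) is the subject's municipality risk-set
#' exposure; admissions are a marked Poisson process per cause with codes in
#' positions 1-6. Death codes follow the coding-era rule (ICD-9 through 2002,
#' ICD-10 from 2003).
#'
#' @param subjects cohort from [sample_cohort()].
#' @param annual_exposure data.frame (municipality_id, pollutant, year, value)
#'   for the model years; risk-set exposures are built internally.
#' @param world a [world_truth()].
#' @param window follow-up Dates, default 1999-01-01 to 2008-12-31.
#' @param admission_params see [default_admission_params()]; NULL for none.
#' @param seed integer seed.
#' @return data.frame of event records: subject_id, event_date, record_type
#'   (death/admission), code_system, code1..code6 (NA for unused positions).
#' @export
simulate_events <- function(subjects, annual_exposure, world,
                            window = as.Date(c("1999-01-01", "2008-12-31")),
                            admission_params = default_admission_params(),
                            seed = 1) {
  stopifnot(inherits(world, "world_truth"))
  set.seed(seed)
  rse <- build_risk_set_exposure(
    annual_exposure[annual_exposure$pollutant == world$pollutant, ])
  rows <- split_follow_up(subjects, window)
  key <- paste(rows$municipality_id, rows$riskset)
  expo <- rse$exposure[match(key, paste(rse$municipality_id, rse$interval))]
  if (anyNA(expo)) {
    bad <- unique(key[is.na(expo)])[1]
    stop("missing exposure for municipality/risk set: ", bad)
  }
  si <- match(rows$subject_id, subjects$subject_id)
  bh_key <- paste(world$baseline_hazard$age_class, world$baseline_hazard$sex)
  base <- world$baseline_hazard$rate[
    match(paste(rows$age_class, subjects$sex[si]), bh_key)]
  if (anyNA(base)) stop("baseline hazard table does not cover all strata")
  edu <- as.integer(subjects$education[si]) - 1L
  smk <- as.integer(subjects$smoking[si] == "current")
  lp <- world$beta_true * expo / 10 +
    world$covariate_effects$education_per_level * edu +
    world$covariate_effects$smoking_current * smk
  fr <- world$muni_frailty_sd %||% 0
  if (fr > 0) {
    mids <- unique(rows$municipality_id)
    u <- stats::rnorm(length(mids), 0, fr)
    lp <- lp + u[match(rows$municipality_id, mids)]
  }
  death_t <- sim_piecewise_exponential(rows, base * exp(lp))
  sid <- unique(rows$subject_id)
  dead <- !is.na(death_t)
  out <- list()
  if (any(dead)) {
    dday <- floor(death_t[dead])
    dyear <- as.integer(format(as.Date(dday, origin = "1970-01-01"), "%Y"))
    cause <- sample(names(world$cause_mix), sum(dead), TRUE, world$cause_mix)
    system <- ifelse(dyear <= 2002, "ICD9", "ICD10")
    code <- vapply(seq_along(cause), function(k) {
      pool <- death_code_pools[[cause[k]]][[system[k]]]
      pool[sample.int(length(pool), 1L)]
    }, character(1))
    out$death <- data.frame(subject_id = sid[dead],
                            event_date = as.Date(dday, origin = "1970-01-01"),
                            record_type = "death", code_system = system,
                            code1 = code, code2 = NA_character_,
                            code3 = NA_character_, code4 = NA_character_,
                            code5 = NA_character_, code6 = NA_character_,
                            stringsAsFactors = FALSE)
  }
  if (!is.null(admission_params) && nrow(admission_params) > 0) {
    # at-risk span per subject: enrolment (or window start) to death/window end
    s0 <- pmax(as.numeric(subjects$enroll_date),
               as.numeric(as.Date(window[1])))
    s1 <- rep(as.numeric(as.Date(window[2])), nrow(subjects))
    di <- match(subjects$subject_id, sid)
    s1 <- pmin(s1, ifelse(is.na(death_t[di]), Inf, death_t[di]))
    yrs <- pmax(s1 - s0, 0) / DAYS_PER_YEAR
    adm <- list()
    for (k in seq_len(nrow(admission_params))) {
      ap <- admission_params[k, ]
      cnt <- stats::rpois(length(yrs), ap$rate * yrs)
      tot <- sum(cnt)
      if (tot == 0) next
      who <- rep(seq_along(yrs), cnt)
      t_ev <- floor(s0[who] + stats::runif(tot) * (s1[who] - s0[who]))
      secondary <- stats::runif(tot) < ap$secondary_prob
      codes <- matrix(NA_character_, tot, 6)
      codes[, 1] <- ifelse(secondary, "780", ap$code)  # 780: symptoms filler
      pos <- sample(2:6, tot, replace = TRUE)
      codes[cbind(which(secondary), pos[secondary])] <- ap$code
      adm[[k]] <- data.frame(subject_id = subjects$subject_id[who],
                             event_date = as.Date(t_ev, origin = "1970-01-01"),
                             record_type = "admission", code_system = "ICD9",
                             code1 = codes[, 1], code2 = codes[, 2],
                             code3 = codes[, 3], code4 = codes[, 4],
                             code5 = codes[, 5], code6 = codes[, 6],
                             stringsAsFactors = FALSE)
    }
    out$adm <- do.call(rbind, adm)
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(subject_id = character(0), event_date = as.Date(character(0)),
                     record_type = character(0), code_system = character(0),
                     code1 = character(0), code2 = character(0),
                     code3 = character(0), code4 = character(0),
                     code5 = character(0), code6 = character(0),
                     stringsAsFactors = FALSE)
  ev <- ev[order(ev$subject_id, ev$event_date), ]
  rownames(ev) <- NULL
  ev
}
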