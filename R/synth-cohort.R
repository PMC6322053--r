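#' Baseline covariate model for the synthetic cohort
#'
#' Category probabilities and continuous-variable parameters for the survey
#' covariates. Ages cover 0-95 with an adult-weighted mixture (a household
#' survey enrols all members, children included).
#'
#' @param linkage_prob probability that a subject survives record linkage
#'   (independent Bernoulli per subject; default 0.92, the completeness a
#'   fiscal-code linkage of a national survey typically achieves).
#' @param child_fraction fraction of ages drawn uniformly on (0, 18).
#' @param sex_female,education,marital,occupation,smoking,activity category
#'   probabilities (in the closed category orders documented in the return).
#' @param bmi_mean,bmi_sd body-mass-index distribution (kg/m2), truncated to
#'   (14, 55).
#' @return list of class `covariate_model`. Category orders: education
#'   up_to_primary < lower_secondary < upper_secondary < post_secondary;
#'   smoking never/former/current; activity levels 1-4.
#' @export
covariate_model <- function(linkage_prob = 0.92, child_fraction = 0.18,
                            sex_female = 0.52,
                            education = c(0.35, 0.30, 0.25, 0.10),
                            marital = 0.60, occupation = 0.45,
                            smoking = c(0.55, 0.22, 0.23),
                            activity = c(0.30, 0.30, 0.25, 0.15),
                            bmi_mean = 25.5, bmi_sd = 4) {
  stopifnot(linkage_prob >= 0, linkage_prob <= 1,
            length(education) == 4, length(smoking) == 3,
            length(activity) == 4)
  structure(as.list(environment()), class = "covariate_model")
}

education_levels <- c("up_to_primary", "lower_secondary",
                      "upper_secondary", "post_secondary")
smoking_levels <- c("never", "former", "current")

#' Draw a two-stage survey cohort
#'
#' First stage samples municipalities, second stage samples households within
#' each sampled municipality; all members of a sampled household are enrolled.
#' Household counts per municipality are derived from population (2.5 persons
#' per household); requesting more households than a municipality holds is an
#' error (no replacement).
#'
#' @param municipalities a `muni_set` from [make_municipalities()].
#' @param n_munis_sampled municipalities drawn at the first stage.
#' @param households_per_muni households drawn within each sampled
#'   municipality.
#' @param size_dist probabilities of household sizes `1:length(size_dist)`.
#' @param covariates a [covariate_model()].
#' @param enroll_window Dates (length 2) between which household interview
#'   dates fall.
#' @param seed integer seed.
#' @return data.frame of subjects: ids, municipality, sex, age_at_baseline,
#'   birth_date, enroll_date, the baseline covariates, and the `linked` flag.
#' @export
sample_cohort <- function(municipalities, n_munis_sampled, households_per_muni,
                          size_dist = c(0.25, 0.27, 0.20, 0.18, 0.07, 0.03),
                          covariates = covariate_model(),
                          enroll_window = as.Date(c("1999-01-01",
                                                    "2000-12-31")),
                          seed = 1) {
  stopifnot(inherits(municipalities, "muni_set"),
            inherits(covariates, "covariate_model"))
  mm <- municipalities$munis
  if (n_munis_sampled > nrow(mm))
    stop("n_munis_sampled exceeds the number of municipalities")
  set.seed(seed)
  picked <- mm[sample.int(nrow(mm), n_munis_sampled), ]
  n_house <- ceiling(picked$population / 2.5)
  short <- picked$municipality_id[n_house < households_per_muni]
  if (length(short))
    stop("households_per_muni exceeds the household count of: ",
         paste(short, collapse = ", "))
  n_hh <- n_munis_sampled * households_per_muni
  hh_muni <- rep(picked$municipality_id, each = households_per_muni)
  hh_size <- sample.int(length(size_dist), n_hh, replace = TRUE,
                        prob = size_dist)
  hh_enroll <- enroll_window[1] +
    floor(stats::runif(n_hh) *
            (as.numeric(enroll_window[2] - enroll_window[1]) + 1))
  n <- sum(hh_size)
  hh_of <- rep(seq_len(n_hh), hh_size)
  cm <- covariates
  age <- ifelse(stats::runif(n) < cm$child_fraction,
                stats::runif(n, 0, 18),
                18 + 77 * stats::rbeta(n, 2, 2.5))
  enroll <- hh_enroll[hh_of]
  bmi <- pmin(pmax(stats::rnorm(n, cm$bmi_mean, cm$bmi_sd), 14), 55)
  subj <- data.frame(
    subject_id = sprintf("P%06d", seq_len(n)),
    household_id = sprintf("H%05d", hh_of),
    municipality_id = hh_muni[hh_of],
    sex = ifelse(stats::runif(n) < cm$sex_female, "F", "M"),
    age_at_baseline = age,
    enroll_date = enroll,
    birth_date = enroll - round(age * 365.25),
    education = factor(sample(education_levels, n, TRUE, cm$education),
                       levels = education_levels, ordered = TRUE),
    marital = factor(ifelse(stats::runif(n) < cm$marital, "with_partner",
                            "without_partner"),
                     levels = c("with_partner", "without_partner")),
    occupation = factor(ifelse(stats::runif(n) < cm$occupation, "employed",
                               "not_employed"),
                        levels = c("employed", "not_employed")),
    smoking = factor(sample(smoking_levels, n, TRUE, cm$smoking),
                     levels = smoking_levels),
    physical_activity = factor(sample(1:4, n, TRUE, cm$activity),
                               levels = 1:4, ordered = TRUE),
    bmi = bmi,
    linked = stats::runif(n) < cm$linkage_prob,
    stringsAsFactors = FALSE)
  subj
}
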