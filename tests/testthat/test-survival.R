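# direct single-interval cohort for focused hazard-model checks: `n` subjects
# in `n_grp` municipality clusters with cluster-level exposure, optional
# current-smoker interaction, exponential event times censored at 10 years
make_simple_cp <- function(n, beta10, rate0 = 0.02, smk_extra10 = 0,
                           n_grp = 40, frailty_sd = 0, seed = 1) {
  set.seed(seed)
  grp <- sample.int(n_grp, n, replace = TRUE)
  expo <- runif(n_grp, 5, 45)[grp]
  smoking <- factor(ifelse(runif(n) < 0.25, "current", "never"),
                    levels = c("never", "current"))
  u <- rnorm(n_grp, 0, frailty_sd)[grp]
  lp <- (beta10 + smk_extra10 * (smoking == "current")) * expo / 10 + u
  t_yr <- rexp(n, rate0 * exp(lp))
  event <- as.integer(t_yr < 10)
  data.frame(subject_id = sprintf("P%06d", seq_len(n)),
             municipality_id = sprintf("M%03d", grp),
             household_id = sprintf("H%06d", seq_len(n)),
             tstart = 0, tstop = pmin(t_yr, 10) * 365.25, event = event,
             exposure = expo, age_class = "50-54",
             sex = sample(c("F", "M"), n, TRUE), smoking = smoking,
             stringsAsFactors = FALSE)
}

test_that("the fit equals a brute-force partial-likelihood maximisation on tiny data", {
  rows <- data.frame(
    subject_id = rep(c("A", "B", "C"), each = 2),
    municipality_id = "M1", household_id = "H1",
    tstart = c(0, 100, 0, 100, 0, 100),
    tstop = c(100, 250, 100, 380, 100, 420),
    event = c(0, 1, 0, 1, 0, 0),
    exposure = c(10, 30, 20, 15, 25, 40),
    age_class = "60-64", stringsAsFactors = FALSE)
  hf <- fit_cox(rows, covariates = character(0), cluster = NULL)
  # oracle: maximise the (start, stop] partial likelihood by direct search
  pl <- function(b) {
    ll <- 0
    for (e in which(rows$event == 1)) {
      te <- rows$tstop[e]
      risk <- rows$tstart < te & te <= rows$tstop
      ll <- ll + b * rows$exposure[e] / 10 -
        log(sum(exp(b * rows$exposure[risk] / 10)))
    }
    ll
  }
  b_hat <- optimize(pl, c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(unname(hf$log_hr), b_hat, tolerance = 1e-6)
  expect_equal(hf$n_events, 2L)
})

test_that("the hazard ratio is invariant to a constant exposure shift", {
  cp <- make_simple_cp(2000, beta10 = log(1.3), seed = 5)
  h1 <- fit_cox(cp, covariates = "sex")
  cp2 <- cp; cp2$exposure <- cp2$exposure + 100
  h2 <- fit_cox(cp2, covariates = "sex")
  expect_equal(h1$log_hr, h2$log_hr, tolerance = 1e-8)
})

test_that("zero events and collinear covariates raise errors", {
  cp <- make_simple_cp(100, 0, seed = 2)
  cp$event <- 0
  expect_error(fit_cox(cp), "zero events")
  cp2 <- make_simple_cp(500, 0, seed = 3)
  cp2$dup <- cp2$exposure  # exactly collinear with the exposure term
  expect_error(fit_cox(cp2, covariates = c("sex", "dup")), "collinear")
})

test_that("cluster-robust variance exceeds the naive one under shared frailty", {
  ratios <- vapply(1:30, function(r) {
    cp <- make_simple_cp(1500, beta10 = log(1.1), frailty_sd = 0.5,
                         n_grp = 25, seed = 600 + r)
    hf <- fit_cox(cp, covariates = "sex")
    i <- which(names(coef(hf$fit)) == "expo")
    sqrt(hf$fit$var[i, i] / hf$fit$naive.var[i, i])
  }, numeric(1))
  expect_gt(mean(ratios), 1.1)
})

test_that("PH diagnostics keep truly proportional predictors most of the time", {
  n_flag <- 0; n_tot <- 0
  for (r in 1:25) {
    cp <- make_simple_cp(1200, beta10 = log(1.2), seed = 300 + r)
    ph <- test_ph(fit_cox(cp, covariates = c("sex", "smoking")))
    n_flag <- n_flag + sum(ph$decision == "stratify")
    n_tot <- n_tot + nrow(ph)
  }
  expect_lte(n_flag / n_tot, 0.10)
})

test_that("a time-crossing covariate effect is detected and stratified away", {
  hits <- 0
  for (r in 1:10) {
    set.seed(800 + r)
    n <- 3000
    z <- rbinom(n, 1, 0.5)
    # effect +0.8 for 3 years, then -0.8: grossly non-proportional
    rows <- data.frame(subject_id = rep(sprintf("P%05d", 1:n), each = 2),
                       tstart = rep(c(0, 3) * 365.25, n),
                       tstop = rep(c(3, 10) * 365.25, n))
    rate <- 0.03 * exp(ifelse(rows$tstart == 0, 0.8, -0.8) * z[rep(1:n, each = 2)])
    tt <- airsurv:::sim_piecewise_exponential(rows, rate)
    stop_d <- pmin(ifelse(is.na(tt), Inf, tt), 10 * 365.25)
    cp <- data.frame(subject_id = sprintf("P%05d", 1:n),
                     municipality_id = "M1", tstart = 0, tstop = stop_d,
                     event = as.integer(!is.na(tt) & tt < 10 * 365.25),
                     exposure = runif(n, 10, 30),
                     age_class = "50-54",
                     zz = factor(z), stringsAsFactors = FALSE)
    hf <- fit_cox(cp, covariates = "zz", cluster = NULL)
    ph <- test_ph(hf)
    if (ph$decision[ph$covariate == "zz"] == "stratify") hits <- hits + 1
  }
  expect_gte(hits, 8)
  # stratified refit drops the coefficient of the stratified covariate
  cp <- make_simple_cp(1000, log(1.2), seed = 4)
  hs <- fit_cox(cp, covariates = c("sex", "smoking"),
                strata_covs = "smoking")
  expect_false(any(grepl("smoking", rownames(hs$coef_table))))
})

test_that("the interaction LRT is calibrated under no effect modification", {
  ps <- vapply(1:60, function(r) {
    cp <- make_simple_cp(800, beta10 = log(1.15), rate0 = 0.03,
                         seed = 900 + r)
    fit_with_interaction(cp, "smoking", covariates = c("sex", "smoking"))$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("the interaction LRT detects an exposure effect doubled in smokers", {
  rej <- 0
  for (r in 1:15) {
    cp <- make_simple_cp(20000, beta10 = log(1.10), rate0 = 0.02,
                         smk_extra10 = log(1.10), seed = 950 + r)
    it <- fit_with_interaction(cp, "smoking", covariates = c("sex", "smoking"))
    expect_gte(it$ll_full, it$ll_reduced)  # nesting property
    expect_equal(it$df, 1)
    if (it$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 15, 0.8)
})
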