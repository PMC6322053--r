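# shared fixtures, all generated in code

# small annual exposure table with between-municipality spread
toy_annual <- function(ids, seed = 2, spread = c(10, 35), noise = 2,
                       pollutant = "PM25") {
  set.seed(seed)
  base <- stats::runif(length(ids), spread[1], spread[2])
  out <- expand.grid(municipality_id = ids, pollutant = pollutant,
                     year = c(1999L, 2003L, 2005L, 2007L),
                     stringsAsFactors = FALSE)
  out$value <- pmax(base[match(out$municipality_id, ids)] +
                      stats::rnorm(nrow(out), 0, noise), 0)
  out
}

# a small study region reused across tests
toy_region <- function(seed = 5, nx = 12, ny = 10, n_munis = 12) {
  g <- grid_spec(nx, ny)
  list(grid = g, munis = make_municipalities(g, n_munis, seed = seed))
}

# hand-built subject rows (bypasses the sampler) for traced examples
toy_subject <- function(subject_id = "P1", age = 60,
                        enroll = as.Date("1999-01-01"),
                        municipality_id = "M1", sex = "M",
                        linked = TRUE) {
  data.frame(subject_id = subject_id, household_id = paste0("H", subject_id),
             municipality_id = municipality_id, sex = sex,
             age_at_baseline = age, enroll_date = enroll,
             birth_date = enroll - round(age * 365.25),
             linked = linked, stringsAsFactors = FALSE)
}

# constant risk-set exposure table for given municipalities
toy_riskset <- function(ids, exposure = 20, pollutant = "PM25") {
  rs <- risk_set_intervals()
  out <- expand.grid(municipality_id = ids, interval = rs$interval,
                     stringsAsFactors = FALSE)
  out$pollutant <- pollutant
  out$interval_start <- rs$start[match(out$interval, rs$interval)]
  out$interval_end <- rs$end[match(out$interval, rs$interval)]
  out$exposure <- exposure
  out
}
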