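#' Run the full surveillance pipeline on a synthetic world
#'
#' End-to-end orchestration: generate (or accept) a synthetic world, fuse the
#' model fields with station observations per pollutant and year, upscale to
#' municipality risk-set exposures, build counting-process data per analyzed
#' cause, and fit the hazard model with PH diagnostics and optional
#' effect-modification tests. Any stage failure aborts with the stage name;
#' when `outdir` is set, partial results already written are accompanied by
#' an `INCOMPLETE` marker naming the failed stage.
#'
#' @param config world configuration (see [default_world_config()]), or a
#'   path to a YAML file holding overrides of the scalar settings.
#' @param seed integer master seed.
#' @param causes names of mortality cause groups to analyze.
#' @param pollutants pollutants to analyze (must exist in the config).
#' @param covariates adjustment covariates passed to [fit_cox()].
#' @param modifier optional covariate for an exposure interaction test.
#' @param sensitivity_2005 also produce a parallel results table using the
#'   single-year 2005 exposure.
#' @param min_completeness station QC threshold.
#' @param outdir optional directory for CSV results and a JSON manifest.
#' @param world optionally, a pre-built `synth_world` (config then ignored
#'   for generation).
#' @return list of class `surveillance_report`: `results` (cause, pollutant,
#'   hr, ci, events), `results_2005` (if requested), `ph`, `interactions`,
#'   `qc`, `linkage`, `oe`, `representativeness`, `exposure`, `manifest`.
#' @export
run_surveillance <- function(config = default_world_config(), seed = 1,
                             causes = c("non_accidental", "cvd",
                                        "respiratory"),
                             pollutants = NULL,
                             covariates = c("sex", "education", "marital",
                                            "occupation", "smoking",
                                            "physical_activity", "bmi"),
                             modifier = NULL, sensitivity_2005 = FALSE,
                             min_completeness = 0.80, outdir = NULL,
                             world = NULL) {
  if (is.character(config)) {
    over <- yaml::read_yaml(config)
    config <- do.call(default_world_config, over)
  }
  if (is.null(pollutants)) pollutants <- names(config$pollutants)
  stage <- "init"
  mark_incomplete <- function(e) {
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      writeLines(c(paste("INCOMPLETE at stage:", stage),
                   conditionMessage(e)),
                 file.path(outdir, "INCOMPLETE"))
    }
    stop("surveillance stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
      stage <- "simulate"
      if (is.null(world)) world <- make_world(config, seed = seed)
      stage <- "fuse"
      fused <- list(); qc_rows <- list()
      for (nm in names(world$model_fields)) {
        mf <- world$model_fields[[nm]]
        av <- annual_station_values(world$stations, mf$pollutant, mf$year,
                                    min_completeness)
        qc_rows[[nm]] <- av
        sel <- select_assimilation_stations(av)
        vgm <- fit_residual_variogram(sel, mf)
        fused[[nm]] <- ked_fuse(sel, mf, vgm)
      }
      qc <- do.call(rbind, qc_rows); rownames(qc) <- NULL
      stage <- "upscale"
      annual <- exposure_table(fused, world$munis$cells)
      risksets <- build_risk_set_exposure(annual)
      rs2005 <- if (sensitivity_2005) single_year_exposure(annual) else NULL
      stage <- "outcomes"
      defs <- read_cause_definitions()
      deaths_all <- world$events[world$events$record_type == "death",
                                 c("subject_id", "event_date")]
      cp <- list()
      for (cs in causes) {
        cd <- defs$death_causes[[cs]]
        if (is.null(cd)) stop("unknown death cause: ", cs)
        inc <- incident_events(world$events, cd)
        for (pol in pollutants) {
          rse <- risksets[risksets$pollutant == pol, ]
          cp[[paste(cs, pol)]] <- build_counting_process(
            world$subjects, rse, inc, record_type = "death",
            deaths = deaths_all, window = config$window)
        }
      }
      stage <- "fit"
      rows <- list(); ph <- list(); inter <- list(); rows05 <- list()
      for (key in names(cp)) {
        parts <- strsplit(key, " ")[[1]]
        hf <- fit_cox(cp[[key]], covariates, cause_name = parts[1],
                      pollutant = parts[2])
        rows[[key]] <- data.frame(cause = parts[1], pollutant = parts[2],
                                  hr = hf$hr_per_increment,
                                  ci_lo = hf$ci95[1], ci_hi = hf$ci95[2],
                                  robust_se = hf$robust_se,
                                  n_events = hf$n_events,
                                  n_subjects = hf$n_subjects,
                                  stringsAsFactors = FALSE)
        d <- test_ph(hf)
        d$cause <- parts[1]; d$pollutant <- parts[2]
        ph[[key]] <- d
        if (!is.null(modifier)) {
          it <- fit_with_interaction(cp[[key]], modifier, covariates)
          inter[[key]] <- data.frame(cause = parts[1], pollutant = parts[2],
                                     modifier = modifier, lrt = it$lrt,
                                     df = it$df, p = it$p,
                                     stringsAsFactors = FALSE)
        }
        if (sensitivity_2005) {
          parts2 <- parts
          cd <- defs$death_causes[[parts2[1]]]
          inc <- incident_events(world$events, cd)
          cp05 <- build_counting_process(
            world$subjects, rs2005[rs2005$pollutant == parts2[2], ], inc,
            record_type = "death", deaths = deaths_all,
            window = config$window)
          hf05 <- fit_cox(cp05, covariates, cause_name = parts2[1],
                          pollutant = parts2[2])
          rows05[[key]] <- data.frame(cause = parts2[1],
                                      pollutant = parts2[2],
                                      hr = hf05$hr_per_increment,
                                      ci_lo = hf05$ci95[1],
                                      ci_hi = hf05$ci95[2],
                                      n_events = hf05$n_events,
                                      stringsAsFactors = FALSE)
        }
      }
      stage <- "linkage_qc"
      linkage <- linkage_summary(world$subjects)
      rates <- rate_table_from_truth(world$truth, config$window)
      cp0 <- cp[[1]]
      oe <- oe_report(cp0[, c("tstart", "tstop", "sex", "age_class",
                              "event")], rates)
      repr <- representativeness(world$subjects,
                                 world$subjects[world$subjects$linked, ],
                                 c("sex", "education", "smoking"))
      stage <- "report"
      results <- do.call(rbind, rows); rownames(results) <- NULL
      phtab <- do.call(rbind, ph); rownames(phtab) <- NULL
      manifest <- list(seed = seed,
                       config_hash = config_hash(config),
                       package_version =
                         as.character(utils::packageVersion("airsurv")),
                       r_version = R.version.string,
                       n_subjects = nrow(world$subjects),
                       n_events = nrow(world$events),
                       causes = causes, pollutants = pollutants)
      out <- structure(list(
        results = results,
        results_2005 = if (length(rows05)) do.call(rbind, rows05),
        ph = phtab,
        interactions = if (length(inter)) do.call(rbind, inter),
        qc = qc, linkage = linkage, oe = oe,
        representativeness = repr,
        exposure = list(annual = annual, risksets = risksets,
                        single_2005 = rs2005),
        manifest = manifest, world = world),
        class = "surveillance_report")
      if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(results, file.path(outdir, "results.csv"),
                         row.names = FALSE)
        if (!is.null(out$results_2005))
          utils::write.csv(out$results_2005,
                           file.path(outdir, "results_2005.csv"),
                           row.names = FALSE)
        utils::write.csv(phtab, file.path(outdir, "ph_diagnostics.csv"),
                         row.names = FALSE)
        utils::write.csv(qc, file.path(outdir, "station_qc.csv"),
                         row.names = FALSE)
        for (nm in names(fused)) {
          fd <- field_df(fused[[nm]])
          names(fd)[names(fd) == "value"] <- "prediction"
          utils::write.csv(fd[, c("cell_i", "cell_j", "prediction",
                                  "kriging_variance")],
                           file.path(outdir, sprintf("fused_%s.csv", nm)),
                           row.names = FALSE)
        }
        for (key in names(cp))
          utils::write.csv(cp[[key]],
                           file.path(outdir,
                                     sprintf("counting_process_%s.csv",
                                             gsub(" ", "_", key))),
                           row.names = FALSE)
        utils::write.csv(data.frame(n_total = linkage$n_total,
                                    n_linked = linkage$n_linked,
                                    pct_linked = linkage$pct_linked),
                         file.path(outdir, "linkage_report.csv"),
                         row.names = FALSE)
        utils::write.csv(annual, file.path(outdir, "exposure_annual.csv"),
                         row.names = FALSE)
        utils::write.csv(risksets,
                         file.path(outdir, "exposure_risksets.csv"),
                         row.names = FALSE)
        utils::write.csv(oe, file.path(outdir, "oe_report.csv"),
                         row.names = FALSE)
        utils::write.csv(repr,
                         file.path(outdir, "representativeness.csv"),
                         row.names = FALSE)
        jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE)
        inc_f <- file.path(outdir, "INCOMPLETE")
        if (file.exists(inc_f)) file.remove(inc_f)
      }
      out
  }, error = mark_incomplete)
}

# expand the generator's baseline hazard into a (year, sex, age_class) table
rate_table_from_truth <- function(truth, window) {
  yrs <- seq(as.integer(format(as.Date(window[1]), "%Y")),
             as.integer(format(as.Date(window[2]), "%Y")))
  bh <- truth$baseline_hazard
  out <- do.call(rbind, lapply(yrs, function(y) {
    d <- bh; d$year <- y; d
  }))
  out[, c("year", "sex", "age_class", "rate")]
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

#' @export
print.surveillance_report <- function(x, ...) {
  cat("surveillance_report\n")
  print(x$results, digits = 4)
  cat(sprintf("linkage: %d/%d (%.1f%%)\n", x$linkage$n_linked,
              x$linkage$n_total, x$linkage$pct_linked))
  invisible(x)
}
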