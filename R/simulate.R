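# Two-site synthetic EHR + weather generator with a configurable logistic
# readmission model. This is first-class, tested code: it defines the study
# conditions every downstream stage is exercised under, since the hospital
# EHR data the pipeline is designed for are private.
#
# Random streams are seeded independently per site and per artefact
# (weather, clinical, outcomes), so e.g. adding persons never perturbs the
# weather series.

# ICD-10 code pools per disease chapter for index (discharge) diagnoses.
# Several overlap the Charlson map on purpose so index stays contribute to
# comorbidity.
INDEX_CODE_POOLS <- list(
  F = c("F00", "F03", "F05", "F20", "F32", "F41"),
  I = c("I10", "I20", "I21", "I25", "I48", "I50", "I63"),
  J = c("J12", "J18", "J20", "J44", "J45", "J96"),
  M = c("M16", "M17", "M25", "M48", "M54", "M81"))

# historical condition pool: Charlson-mapped codes (for nonzero comorbidity
# prevalence) mixed with neutral chronic codes; sampling weights keep severe
# categories rare so the cohort mean Charlson lands near the ~0.5-1 typical
# of elderly general cohorts
HISTORY_CODE_POOL <- c("I21", "I50", "I63", "E119", "E112", "J44", "N18",
                       "C349", "C78", "K25", "F01", "M05", "B18", "G81",
                       "I10", "E785", "K21", "N40", "H25", "M47")
HISTORY_CODE_WEIGHTS <- c(2, 3, 2, 4, 1, 3, 1,
                          1, 0.5, 1, 2, 1, 0.5, 0.5,
                          8, 6, 4, 3, 3, 4)
DRUG_POOL <- sprintf("ING%02d", 1:20)

#' Weather generator parameters
#'
#' Seasonal sinusoid-plus-noise parameters per element, chosen once to
#' emulate a temperate, monsoon-influenced metropolitan climate: maximum
#' temperature with a late-July peak, a positive temperature gap to the
#' minimum, summer-peaking humidity and rainfall occurrence, and log-normal
#' PM10 with winter elevation (episodic exceedances of the fine-dust
#' advisory level).
#'
#' @param tmax_mean,tmax_amplitude,tmax_phase,tmax_sd annual mean (deg C),
#'   seasonal amplitude, phase day-of-year and daily noise sd of the maximum
#'   temperature sinusoid `mean + amplitude * sin(2*pi*(doy - phase)/365)`.
#' @param temp_gap_mean,temp_gap_sd mean/sd of the (positive) tmax - tmin gap.
#' @param humidity_mean,humidity_amplitude,humidity_sd relative humidity (%).
#' @param rain_prob,rain_prob_amplitude zero-inflation: probability of a wet
#'   day and its seasonal swing (logit scale additive).
#' @param rain_logmean,rain_logsd log-normal positive rainfall (mm).
#' @param pm10_logmedian,pm10_seasonal,pm10_logsd log-scale PM10 (ug/m3)
#'   median, winter elevation and sd.
#' @return a `weather_params` list.
#' @export
weather_params <- function(tmax_mean = 17.5, tmax_amplitude = 13,
                           tmax_phase = 114, tmax_sd = 3,
                           temp_gap_mean = 8, temp_gap_sd = 1.5,
                           humidity_mean = 62, humidity_amplitude = 12,
                           humidity_sd = 8,
                           rain_prob = 0.28, rain_prob_amplitude = 0.8,
                           rain_logmean = log(8), rain_logsd = 1.1,
                           pm10_logmedian = log(48), pm10_seasonal = 0.30,
                           pm10_logsd = 0.55) {
  p <- as.list(environment())
  stopifnot(p$tmax_sd >= 0, p$humidity_sd >= 0, p$rain_logsd >= 0,
            p$pm10_logsd >= 0, p$rain_prob >= 0, p$rain_prob <= 1,
            p$temp_gap_mean > 0)
  structure(p, class = "weather_params")
}

#' Logistic outcome model for the generator
#'
#' Linear predictor (logit of the readmission probability) for each
#' prospective index event:
#' `intercept + beta_age*(age-80) + beta_los*(los-2) +
#'  beta_charlson*(cci-1) + beta_condition[group] + sum(beta_w * W)`,
#' where `W` is the TRUE five-element W-score of the event computed from the
#' generated series. Covariates are centred at cohort-typical values (age
#' 80 in a 65-99 cohort, 2-day stay, Charlson 1) so the intercept is
#' interpretable as the baseline logit incidence.
#'
#' @param intercept baseline logit; default `qlogis(0.09)` (~9% incidence,
#'   matching a tertiary-care elderly cohort).
#' @param beta_age,beta_los,beta_charlson per-unit log-odds.
#' @param beta_condition named log-odds per disease group (F, I, J, M;
#'   "other" contributes 0).
#' @param beta_w named log-odds per W-score point for the five elements,
#'   default concentrated on PM10, rainfall and maximum temperature.
#' @return an `outcome_model` list.
#' @export
outcome_model <- function(intercept = stats::qlogis(0.09),
                          beta_age = 0.025, beta_los = 0.07,
                          beta_charlson = 0.25,
                          beta_condition = c(F = 0.30, I = 0.15,
                                             J = 0.25, M = 0),
                          beta_w = c(pm10 = 0.2, rainfall = 0.1,
                                     humidity = 0, tmin = 0, tmax = 0.1)) {
  m <- list(intercept = intercept, beta_age = beta_age, beta_los = beta_los,
            beta_charlson = beta_charlson,
            beta_condition = beta_condition[c("F", "I", "J", "M")],
            beta_w = beta_w[SCORED_ELEMENTS])
  stopifnot(all(is.finite(unlist(m))))
  structure(m, class = "outcome_model")
}

#' Simulation configuration
#'
#' @param seed master seed; all artefacts derive their streams from it.
#' @param n_persons_per_site persons generated per site.
#' @param study_window length-2 Date vector.
#' @param regions data frame `region_id`, `weight` (residence sampling
#'   weights), `temp_offset` (deg C added to both temperatures),
#'   `pm10_log_offset` (log-scale PM10 shift).
#' @param disease_group_mix named probabilities over chapters F, I, J, M for
#'   the principal index diagnosis; must sum to 1.
#' @param mean_visits_per_person Poisson mean of hospitalizations per person.
#' @param los_mean_days mean length of stay (geometric-like, capped at 30).
#' @param outcome_model an [outcome_model()].
#' @param weather a [weather_params()].
#' @param site_shift list of additive offsets applied to the external site's
#'   generating parameters: `age` (years), `los` (days), `temp` (deg C),
#'   `pm10_log` (log scale).
#' @param missing_weather_rate probability a station record is missing.
#' @param n_stations_per_region stations per region (default 1; >1 exercises
#'   the cross-station median).
#' @param emergency_rate fraction of generated visits that are
#'   emergency-route; `planned_rate` fraction of emergency visits carrying a
#'   planned-care code; `death_rate` in-hospital death fraction.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_persons_per_site = 1000L,
                       study_window = as.Date(c("2017-01-01", "2018-12-31")),
                       regions = data.frame(
                         region_id = sprintf("R%02d", 1:5),
                         weight = c(0.3, 0.25, 0.2, 0.15, 0.1),
                         temp_offset = c(0, 0.5, -0.5, 1, -1),
                         pm10_log_offset = c(0, 0.05, -0.05, 0.1, -0.1),
                         stringsAsFactors = FALSE),
                       disease_group_mix = c(F = 0.09, I = 0.26,
                                             J = 0.28, M = 0.37),
                       mean_visits_per_person = 1.5,
                       los_mean_days = 2,
                       outcome_model = readmitw::outcome_model(),
                       weather = weather_params(),
                       site_shift = list(age = 1, los = 0.1, temp = 0.5,
                                         pm10_log = 0.05),
                       missing_weather_rate = 0.02,
                       n_stations_per_region = 1L,
                       emergency_rate = 0.2,
                       planned_rate = 0.03,
                       death_rate = 0.03) {
  cfg <- as.list(environment())
  cfg$study_window <- as.Date(cfg$study_window)
  stopifnot(abs(sum(cfg$disease_group_mix) - 1) < 1e-8,
            cfg$missing_weather_rate >= 0, cfg$missing_weather_rate <= 1,
            cfg$n_persons_per_site >= 0, cfg$los_mean_days > 0,
            cfg$study_window[1] <= cfg$study_window[2])
  structure(cfg, class = "sim_config")
}

seasonal <- function(doy, phase) sin(2 * pi * (doy - phase) / 365)

#' Generate station-level daily weather/air-quality records
#'
#' One record per station, day and element over the window, drawn from the
#' seasonal models in [weather_params()] with per-region offsets, and with
#' missing values injected at `missing_rate`. The minimum temperature is
#' generated as the maximum minus a positive gap, so tmin < tmax on every
#' day.
#'
#' @param params a [weather_params()].
#' @param regions region data frame (see [sim_config()]).
#' @param window length-2 Date vector.
#' @param seed integer seed (full determinism).
#' @param n_stations_per_region stations per region.
#' @param missing_rate per-record missingness probability.
#' @return station record data frame (`station_id`, `date`, `element`,
#'   `value`) plus a `station_map` attribute (`station_id`, `region_id`).
#' @export
generate_weather_series <- function(params, regions, window, seed,
                                    n_stations_per_region = 1L,
                                    missing_rate = 0) {
  window <- as.Date(window)
  stopifnot(window[1] <= window[2])
  dates <- seq(window[1], window[2], by = "day")
  doy <- as.integer(format(dates, "%j"))
  nd <- length(dates)
  out <- list()
  map <- list()
  with_seed(seed, {
    for (r in seq_len(nrow(regions))) {
      for (s in seq_len(n_stations_per_region)) {
        sid <- sprintf("%s_S%d", regions$region_id[r], s)
        map[[sid]] <- regions$region_id[r]
        tmax <- params$tmax_mean + regions$temp_offset[r] +
          params$tmax_amplitude * seasonal(doy, params$tmax_phase) +
          stats::rnorm(nd, 0, params$tmax_sd)
        gap <- pmax(0.5, stats::rnorm(nd, params$temp_gap_mean,
                                      params$temp_gap_sd))
        tmin <- tmax - gap
        humidity <- pmin(100, pmax(2, params$humidity_mean +
          params$humidity_amplitude * seasonal(doy, params$tmax_phase) +
          stats::rnorm(nd, 0, params$humidity_sd)))
        wet <- stats::runif(nd) < stats::plogis(stats::qlogis(params$rain_prob) +
          params$rain_prob_amplitude * seasonal(doy, params$tmax_phase))
        rainfall <- ifelse(wet, stats::rlnorm(nd, params$rain_logmean,
                                              params$rain_logsd), 0)
        pm10 <- stats::rlnorm(nd, params$pm10_logmedian +
          regions$pm10_log_offset[r] -
          params$pm10_seasonal * seasonal(doy, params$tmax_phase),
          params$pm10_logsd)
        pm25 <- pm10 * stats::runif(nd, 0.4, 0.6)
        so2 <- stats::rlnorm(nd, log(5), 0.3)
        no2 <- stats::rlnorm(nd, log(30), 0.3)
        o3 <- stats::rlnorm(nd, log(50), 0.3)
        vals <- list(tmax = tmax, tmin = tmin, humidity = humidity,
                     rainfall = rainfall, pm10 = pm10, pm25 = pm25,
                     so2 = so2, no2 = no2, o3 = o3)
        for (el in names(vals)) {
          v <- round(vals[[el]], 2)
          if (missing_rate > 0)
            v[stats::runif(nd) < missing_rate] <- NA_real_
          out[[paste(sid, el)]] <- data.frame(
            station_id = sid, date = dates, element = el, value = v,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  stations <- do.call(rbind, out)
  rownames(stations) <- NULL
  attr(stations, "station_map") <- data.frame(
    station_id = names(map), region_id = unlist(map, use.names = FALSE),
    stringsAsFactors = FALSE)
  stations
}

#' Generate one site's clinical CDM bundle (without outcomes)
#'
#' Persons aged 60-99 at window start (so the >= 65 cohort filter makes
#' genuine exclusions) with region-weighted residences; inpatient and
#' emergency visits with admissions uniform over the window and geometric
#' lengths of stay; a principal discharge diagnosis drawn from the
#' configured disease-group mix and dated at admission; historical
#' conditions and drug exposures sampled so Charlson prevalence is nonzero.
#' A small fraction of emergency visits carries a planned-care code
#' (chemotherapy sessions) to exercise the planned-readmission exclusion.
#'
#' @param config a [sim_config()].
#' @param site_id site identifier.
#' @param age_shift,los_shift additive site shifts (used by
#'   [generate_study()] for the external site).
#' @return a validated [cdm_bundle()].
#' @export
generate_clinical <- function(config, site_id, age_shift = 0, los_shift = 0) {
  n <- config$n_persons_per_site
  w <- config$study_window
  seed <- sub_seed(config$seed, paste0("clinical_", site_id))
  if (n == 0L)
    return(cdm_bundle(site_id = site_id,
                      locations = data.frame(
                        location_id = paste0("L_", config$regions$region_id),
                        postal_code = sprintf("%05d", seq_len(nrow(config$regions))),
                        region_id = config$regions$region_id)))
  with_seed(seed, {
    regions <- config$regions
    locations <- data.frame(
      location_id = paste0("L_", regions$region_id),
      postal_code = sprintf("%05d", seq_len(nrow(regions))),
      region_id = regions$region_id, stringsAsFactors = FALSE)
    age0 <- pmin(99, stats::runif(n, 60, 99) + age_shift)
    persons <- data.frame(
      person_id = sprintf("%s_p%05d", site_id, seq_len(n)),
      gender = sample(c("male", "female"), n, replace = TRUE),
      year_of_birth = as.integer(format(w[1], "%Y")) - floor(age0),
      location_id = sample(locations$location_id, n, replace = TRUE,
                           prob = regions$weight),
      stringsAsFactors = FALSE)

    nv <- stats::rpois(n, config$mean_visits_per_person)
    vp <- rep(persons$person_id, nv)
    m <- length(vp)
    last_admit <- w[2] - 37
    admit <- w[1] + floor(stats::runif(m) *
                            (as.numeric(last_admit - w[1]) + 1))
    # enforce >= 80 days between one person's spontaneous admissions (and a
    # 14-day stay cap below): with the 30-day outcome window and up-to-3-day
    # readmission stays this guarantees that the only visit that can fall in
    # an index event's outcome window is that event's own planted
    # readmission, so label recovery against the truth record is exact
    ord <- order(vp, admit)
    keep <- logical(m)
    last_seen <- list()
    for (i in ord) {
      prev <- last_seen[[vp[i]]]
      if (is.null(prev) || as.numeric(admit[i] - prev) >= 80) {
        keep[i] <- TRUE
        last_seen[[vp[i]]] <- admit[i]
      }
    }
    vp <- vp[keep]; admit <- admit[keep]; m <- sum(keep)
    los_mean <- max(0.2, config$los_mean_days + los_shift)
    los <- pmin(14L, stats::rgeom(m, 1 / (los_mean + 1)))
    kind <- ifelse(stats::runif(m) < config$emergency_rate,
                   "emergency", "inpatient")
    alive <- stats::runif(m) >= config$death_rate
    visits <- data.frame(
      visit_id = sprintf("%s_v%06d", site_id, seq_len(m)),
      person_id = vp, visit_kind = kind, admit_date = admit,
      discharge_date = admit + los, discharged_alive = alive,
      site_id = site_id, stringsAsFactors = FALSE)

    # principal discharge diagnosis per visit, dated at admission
    mix <- config$disease_group_mix
    chap <- sample(names(mix), m, replace = TRUE, prob = mix)
    code <- vapply(chap, function(ch) sample(INDEX_CODE_POOLS[[ch]], 1),
                   character(1))
    planned <- kind == "emergency" & stats::runif(m) < config$planned_rate
    code[planned] <- "Z511"
    idx_conditions <- data.frame(person_id = vp, icd10_code = code,
                                 start_date = admit, stringsAsFactors = FALSE)

    # historical comorbidity conditions, dated before window start
    nh <- stats::rpois(n, 1)
    hp <- rep(persons$person_id, nh)
    hist_conditions <- data.frame(
      person_id = hp,
      icd10_code = sample(HISTORY_CODE_POOL, length(hp), replace = TRUE,
                          prob = HISTORY_CODE_WEIGHTS),
      start_date = w[1] - floor(stats::runif(length(hp), 30, 1500)),
      stringsAsFactors = FALSE)

    nd <- stats::rpois(n, 2)
    dp <- rep(persons$person_id, nd)
    dstart <- w[1] + floor(stats::runif(length(dp), -400,
                                        as.numeric(w[2] - w[1]) - 60))
    drugs <- data.frame(
      person_id = dp,
      ingredient_code = sample(DRUG_POOL, length(dp), replace = TRUE),
      start_date = dstart,
      end_date = dstart + floor(stats::runif(length(dp), 7, 90)),
      stringsAsFactors = FALSE)

    cdm_bundle(persons = persons, visits = visits,
               conditions = rbind(idx_conditions, hist_conditions),
               drugs = drugs, locations = locations, site_id = site_id)
  })
}

#' Inject readmission outcomes into a clinical bundle
#'
#' For each prospective index event (the same qualification rules the cohort
#' module applies), the readmission probability is the logistic of the
#' outcome model's linear predictor evaluated on the TRUE covariates,
#' including the true W-score recomputed from the generated series. On
#' success an emergency-route readmission visit (no diagnosis, hence
#' unplanned) is appended at a uniform day in 1..30 after discharge. Events
#' whose 7-day exposure window exceeds the series are skipped with a
#' warning.
#'
#' @param bundle bundle from [generate_clinical()].
#' @param series imputed regional series covering the window.
#' @param model an [outcome_model()].
#' @param seed integer seed.
#' @param criteria a [warning_criteria()].
#' @return list: `bundle` (with readmission visits appended, study window
#'   extended accordingly) and `truth` (per-event linear predictor,
#'   probability, true W-score elements, injected readmission visit/date).
#' @export
inject_outcomes <- function(bundle, series, model, seed,
                            criteria = warning_criteria()) {
  events <- suppressMessages(
    identify_index_admissions(bundle, range(series$date)))
  covered_end <- max(series$date)
  feasible <- events$discharge_date + 6 <= covered_end
  if (any(!feasible)) {
    warning(sprintf("%d index event(s) skipped: exposure window exceeds the weather series",
                    sum(!feasible)))
    events <- events[feasible, , drop = FALSE]
  }
  if (nrow(events) == 0L)
    return(list(bundle = bundle,
                truth = cbind(empty_index_events()[, c("visit_id", "person_id")],
                              lp = numeric(0), prob = numeric(0))))
  ws <- wscore_cohort(events, series, criteria)
  wmat <- as.matrix(ws[, SCORED_ELEMENTS])
  beta_cond <- ifelse(events$disease_group %in% names(model$beta_condition),
                      model$beta_condition[events$disease_group], 0)
  beta_cond[is.na(beta_cond)] <- 0
  lp <- model$intercept +
    model$beta_age * (events$age_at_index - 80) +
    model$beta_los * (events$length_of_stay - 2) +
    model$beta_charlson * (events$charlson - 1) +
    beta_cond +
    as.numeric(wmat %*% model$beta_w)
  prob <- stats::plogis(lp)
  with_seed(seed, {
    hit <- stats::runif(nrow(events)) < prob
    day <- sample.int(30L, nrow(events), replace = TRUE)
    stay <- sample.int(4L, nrow(events), replace = TRUE) - 1L
  })
  readmit_admit <- events$discharge_date + ifelse(hit, day, NA)
  readmit_ids <- rep(NA_character_, nrow(events))
  readmit_ids[hit] <- sprintf("%s_r%06d", bundle$site_id, seq_len(sum(hit)))
  new_visits <- if (!any(hit)) NULL else data.frame(
    visit_id = readmit_ids[hit],
    person_id = events$person_id[hit], visit_kind = "emergency",
    admit_date = readmit_admit[hit],
    discharge_date = readmit_admit[hit] + stay[hit],
    discharged_alive = TRUE, site_id = bundle$site_id,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    visit_id = events$visit_id, person_id = events$person_id,
    lp = lp, prob = prob, readmitted = as.integer(hit),
    readmission_visit_id = readmit_ids,
    readmission_date = readmit_admit, stringsAsFactors = FALSE)
  truth <- cbind(truth, stats::setNames(as.data.frame(wmat),
                                        paste0("w_", SCORED_ELEMENTS)))
  out_bundle <- cdm_bundle(
    persons = bundle$persons,
    visits = if (is.null(new_visits)) bundle$visits
             else rbind(bundle$visits, new_visits),
    conditions = bundle$conditions, drugs = bundle$drugs,
    locations = bundle$locations, site_id = bundle$site_id)
  list(bundle = out_bundle, truth = truth)
}

#' Generate the full two-site study
#'
#' Internal (training) and external (validation) sites: the external site is
#' drawn with `site_shift` applied to its covariate- and weather-generating
#' parameters, each site with its own seeded streams. The truth record keeps
#' every prospective index event's true linear predictor and true W-score
#' for recovery tests.
#'
#' @param config a [sim_config()].
#' @param criteria a [warning_criteria()].
#' @return list with `internal` and `external`, each holding `bundle`,
#'   `stations`, `station_map`, `series` (imputed) and `truth`; plus the
#'   `config`.
#' @export
generate_study <- function(config = sim_config(),
                           criteria = warning_criteria()) {
  make_site <- function(site_id, shift) {
    params <- config$weather
    regions <- config$regions
    if (!is.null(shift)) {
      params$tmax_mean <- params$tmax_mean + shift$temp
      params$pm10_logmedian <- params$pm10_logmedian + shift$pm10_log
    }
    stations <- generate_weather_series(
      params, regions, config$study_window,
      seed = sub_seed(config$seed, paste0("weather_", site_id)),
      n_stations_per_region = config$n_stations_per_region,
      missing_rate = config$missing_weather_rate)
    smap <- attr(stations, "station_map")
    series <- impute_missing(harmonize(stations, smap, config$study_window))
    bundle <- generate_clinical(config, site_id,
                                age_shift = if (is.null(shift)) 0 else shift$age,
                                los_shift = if (is.null(shift)) 0 else shift$los)
    inj <- inject_outcomes(bundle, series, config$outcome_model,
                           seed = sub_seed(config$seed,
                                           paste0("outcome_", site_id)),
                           criteria = criteria)
    list(bundle = inj$bundle, stations = stations, station_map = smap,
         series = series, truth = inj$truth)
  }
  list(internal = make_site("internal", NULL),
       external = make_site("external", config$site_shift),
       config = config)
}

#' Write a generated study to disk
#'
#' Produces `cdm_internal/`, `cdm_external/` (CDM-lite CSVs),
#' `weather_internal.csv`, `weather_external.csv`, `station_map_*.csv` and
#' `truth.csv`, all deterministic.
#'
#' @param study output of [generate_study()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (site in c("internal", "external")) {
    s <- study[[site]]
    write_cdm_bundle(s$bundle, file.path(dir, paste0("cdm_", site)))
    write_weather(s$stations, file.path(dir, paste0("weather_", site, ".csv")))
    utils::write.csv(s$station_map,
                     file.path(dir, paste0("station_map_", site, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  truth <- rbind(cbind(site = "internal", study$internal$truth),
                 cbind(site = "external", study$external$truth))
  truth$readmission_date <- format(truth$readmission_date, "%Y-%m-%d")
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(dir)
}
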