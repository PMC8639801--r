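test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 404, n_persons_per_site = 120)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$internal$bundle$visits, s2$internal$bundle$visits)
  expect_identical(s1$internal$truth, s2$internal$truth)
  expect_identical(s1$external$stations$value, s2$external$stations$value)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 5)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("weather generation respects missingness, ordering and the seasonal mean", {
  cfg <- sim_config(seed = 2)
  st0 <- generate_weather_series(cfg$weather, cfg$regions[1, ],
                                 as.Date(c("2017-01-01", "2017-12-31")),
                                 seed = 99, missing_rate = 0)
  expect_false(anyNA(st0$value))

  wide <- split(st0, st0$element)
  expect_true(all(wide$tmin$value < wide$tmax$value))

  # annual mean of tmax ~ configured mean (sinusoid integrates to ~0);
  # 99% Monte-Carlo interval of the mean of 365 days: sd ~ sqrt(amp^2/2+sd^2)/sqrt(365)
  mc_sd <- sqrt(cfg$weather$tmax_amplitude^2 / 2 + cfg$weather$tmax_sd^2) /
    sqrt(365)
  expect_lt(abs(mean(wide$tmax$value) - cfg$weather$tmax_mean), 2.58 * mc_sd * 1.5)

  st_miss <- generate_weather_series(cfg$weather, cfg$regions[1, ],
                                     as.Date(c("2017-01-01", "2017-12-31")),
                                     seed = 99, missing_rate = 0.1)
  frac <- mean(is.na(st_miss$value))
  expect_gt(frac, 0.07); expect_lt(frac, 0.13)

  expect_identical(
    generate_weather_series(cfg$weather, cfg$regions, cfg$study_window,
                            seed = 7, missing_rate = 0.05)$value,
    generate_weather_series(cfg$weather, cfg$regions, cfg$study_window,
                            seed = 7, missing_rate = 0.05)$value)
})

test_that("clinical generation honours the disease mix and passes validation", {
  cfg0 <- sim_config(seed = 3, n_persons_per_site = 0)
  empty <- generate_clinical(cfg0, "s")
  expect_equal(nrow(empty$persons), 0L)
  expect_silent(validate_cdm_bundle(empty))

  cfgJ <- sim_config(seed = 3, n_persons_per_site = 200,
                     disease_group_mix = c(F = 0, I = 0, J = 1, M = 0),
                     planned_rate = 0)
  bJ <- generate_clinical(cfgJ, "s")
  idx <- bJ$conditions[bJ$conditions$start_date >= cfgJ$study_window[1], ]
  expect_true(all(startsWith(idx$icd10_code, "J")))

  # empirical mix within the binomial 99% CI at n = 5000 persons
  cfg <- sim_config(seed = 4, n_persons_per_site = 5000, planned_rate = 0)
  b <- generate_clinical(cfg, "s")
  idx <- b$conditions[b$conditions$start_date >= cfg$study_window[1], ]
  chap <- substr(idx$icd10_code, 1, 1)
  n <- length(chap)
  for (g in names(cfg$disease_group_mix)) {
    p <- cfg$disease_group_mix[[g]]
    half <- 2.58 * sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(chap == g) - p), half + 1e-9, label = g)
  }
})

test_that("outcome injection matches its logistic model", {
  # all coefficients zero, intercept logit(0.1): incidence in the 99% CI
  om0 <- outcome_model(intercept = qlogis(0.1), beta_age = 0, beta_los = 0,
                       beta_charlson = 0,
                       beta_condition = c(F = 0, I = 0, J = 0, M = 0),
                       beta_w = c(pm10 = 0, rainfall = 0, humidity = 0,
                                  tmin = 0, tmax = 0))
  cfg <- sim_config(seed = 6, n_persons_per_site = 5000, outcome_model = om0)
  st <- generate_study(cfg)
  tr <- st$internal$truth
  expect_gt(nrow(tr), 5000)
  half <- 2.58 * sqrt(0.1 * 0.9 / nrow(tr))
  expect_lt(abs(mean(tr$readmitted) - 0.1), half)
  expect_equal(unique(round(tr$prob, 10)), 0.1)

  # saturated-negative intercept -> zero readmissions
  omneg <- outcome_model(intercept = -20)
  cfgn <- sim_config(seed = 6, n_persons_per_site = 300, outcome_model = omneg)
  stn <- generate_study(cfgn)
  expect_equal(sum(stn$internal$truth$readmitted), 0L)

  # strongly positive PM10 coefficient separates the with/without-outcome
  # mean PM10 element
  omw <- outcome_model(beta_w = c(pm10 = 0.8, rainfall = 0, humidity = 0,
                                  tmin = 0, tmax = 0))
  cfgw <- sim_config(seed = 8, n_persons_per_site = 5000, outcome_model = omw)
  stw <- generate_study(cfgw)
  trw <- stw$internal$truth
  expect_gt(mean(trw$w_pm10[trw$readmitted == 1]),
            mean(trw$w_pm10[trw$readmitted == 0]))
})

test_that("the truth W-score equals the exposure module's recomputation", {
  cfg <- sim_config(seed = 14, n_persons_per_site = 150)
  st <- generate_study(cfg)
  tr <- st$internal$truth
  ev <- suppressMessages(
    identify_index_admissions(st$internal$bundle, range(st$internal$series$date)))
  ev <- ev[ev$visit_id %in% tr$visit_id, ]
  ws <- wscore_cohort(ev, st$internal$series)
  i <- match(ws$visit_id, tr$visit_id)
  for (el in c("pm10", "rainfall", "humidity", "tmin", "tmax"))
    expect_equal(ws[[el]], tr[[paste0("w_", el)]][i], info = el)
})

test_that("labelled outcomes trace back to generator-planted readmissions", {
  cfg <- sim_config(seed = 15, n_persons_per_site = 400)
  st <- generate_study(cfg)
  ev <- suppressMessages(build_cohort(st$internal$bundle, cfg$study_window))
  tr <- st$internal$truth
  planted <- st$internal$bundle$visits[
    grepl("_r", st$internal$bundle$visits$visit_id), ]
  pos <- ev[ev$outcome == 1L, ]
  # every positive label is explained by a planted emergency readmission of
  # that person on that date
  key <- paste(planted$person_id, planted$admit_date)
  expect_true(all(paste(pos$person_id, pos$readmission_date) %in% key))
  # and every event the generator flagged readmitted is labelled positive
  flagged <- tr$visit_id[tr$readmitted == 1 & tr$visit_id %in% ev$visit_id]
  expect_true(all(ev$outcome[match(flagged, ev$visit_id)] == 1L))
})

test_that("site shift moves the external cohort as configured", {
  cfg <- sim_config(seed = 16, n_persons_per_site = 5000,
                    site_shift = list(age = 2, los = 0, temp = 0,
                                      pm10_log = 0))
  int <- generate_clinical(cfg, "internal")
  ext <- generate_clinical(cfg, "external", age_shift = cfg$site_shift$age)
  yob_int <- mean(int$persons$year_of_birth)
  yob_ext <- mean(ext$persons$year_of_birth)
  expect_gt(yob_int - yob_ext, 1)  # external older by ~2 years

  # zero shift: identical generating parameters, only the seed stream differs
  ext0 <- generate_clinical(cfg, "external")
  expect_equal(mean(int$persons$year_of_birth),
               mean(ext0$persons$year_of_birth), tolerance = 0.01)
})
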