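crit <- warning_criteria()

test_that("criteria validate tier ordering and round-trip through YAML", {
  expect_s3_class(crit, "warning_criteria")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_criteria(crit, path)
  crit2 <- warning_criteria(path)
  expect_equal(unclass(crit2), unclass(crit))

  bad <- unclass(crit)
  bad$tmax$warning <- 30  # laxer than the advisory for an exceed-above element
  path2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, path2)
  expect_error(warning_criteria(path2), "stricter")
})

test_that("harmonize takes the cross-station median and flags unmapped stations", {
  days <- as.Date("2017-06-01") + 0:2
  stations <- do.call(rbind, lapply(1:3, function(s)
    data.frame(station_id = paste0("S", s), date = days, element = "pm10",
               value = c(10, 20, 90)[s])))
  map <- data.frame(station_id = paste0("S", 1:3), region_id = "R01")
  series <- harmonize(stations, map, range(days))
  expect_equal(unique(series$value), 20)

  map_bad <- map[1:2, ]
  expect_error(harmonize(stations, map_bad, range(days)), "no region mapping")
  map_orphan <- rbind(map, data.frame(station_id = "S9", region_id = "R02"))
  expect_error(harmonize(stations, map_orphan, range(days)),
               "zero reporting stations")
})

test_that("stations with disjoint missing days give union coverage before imputation", {
  days <- as.Date("2017-06-01") + 0:2
  s1 <- data.frame(station_id = "S1", date = days, element = "pm10",
                   value = c(10, NA, NA))
  s2 <- data.frame(station_id = "S2", date = days, element = "pm10",
                   value = c(NA, 30, NA))
  map <- data.frame(station_id = c("S1", "S2"), region_id = "R01")
  series <- harmonize(rbind(s1, s2), map, range(days))
  expect_equal(series$value[order(series$date)], c(10, 30, NA))
})

test_that("imputation fills with the average of daily values and conserves counts", {
  days <- as.Date("2017-06-01") + 0:3
  stations <- data.frame(station_id = "S1", date = days, element = "pm10",
                         value = c(10, NA, 20, 30))
  map <- data.frame(station_id = "S1", region_id = "R01")
  series <- harmonize(stations, map, range(days))
  filled <- impute_missing(series)
  expect_equal(filled$value[filled$date == days[2]], 20)  # mean of 10,20,30
  expect_equal(sum(filled$imputed), 1L)
  expect_false(anyNA(filled$value))

  # no missing values -> identity
  complete <- harmonize(data.frame(station_id = "S1", date = days,
                                   element = "pm10", value = 1:4),
                        map, range(days))
  expect_identical(impute_missing(complete), complete)

  # element never observed -> fatal
  allna <- harmonize(data.frame(station_id = "S1", date = days,
                                element = "pm10", value = NA_real_),
                     map, range(days))
  expect_error(impute_missing(allna), "never observed")
})

test_that("daily scores implement tiers, persistence runs and fall-below direction", {
  mk <- function(values) tiny_series(values = values)
  # unremarkable day -> all zero
  s <- mk(list(tmax = rep(20, 3), tmin = rep(10, 3), humidity = rep(60, 3),
               rainfall = rep(0, 3), pm10 = rep(40, 3)))
  expect_true(all(daily_element_scores(s, "R01", "2017-06-03", crit) == 0))

  # heat advisory needs a 2-day qualifying run; day 1 alone scores 0
  s <- mk(list(tmax = c(34, 34, 20)))
  expect_equal(daily_element_scores(s, "R01", "2017-06-01", crit)[["tmax"]], 0)
  expect_equal(daily_element_scores(s, "R01", "2017-06-02", crit)[["tmax"]], 1)

  # warning tier needs its own run at the warning threshold
  s <- mk(list(tmax = c(34, 36, 36)))
  expect_equal(daily_element_scores(s, "R01", "2017-06-02", crit)[["tmax"]], 1)
  expect_equal(daily_element_scores(s, "R01", "2017-06-03", crit)[["tmax"]], 2)

  # PM10 warning fires same-day (persistence 1)
  s <- mk(list(pm10 = c(40, 320, 160)))
  expect_equal(daily_element_scores(s, "R01", "2017-06-02", crit)[["pm10"]], 2)
  expect_equal(daily_element_scores(s, "R01", "2017-06-03", crit)[["pm10"]], 1)

  # dryness: fall-below with persistence
  s <- mk(list(humidity = c(30, 30, 80)))
  expect_equal(daily_element_scores(s, "R01", "2017-06-02", crit)[["humidity"]], 1)
  expect_equal(daily_element_scores(s, "R01", "2017-06-03", crit)[["humidity"]], 0)

  # cold wave: fall-below warning tier
  s <- tiny_series(start = "2017-01-01", values = list(tmin = c(-16, -16)))
  expect_equal(daily_element_scores(s, "R01", "2017-01-02", crit)[["tmin"]], 2)
})

test_that("the W-score sums daily points over exactly days 0..6 after discharge", {
  # heat points pattern (1,0,2,0,0,0,0) by construction, plus a warning on
  # day +7 that must not contribute
  tmax <- c(33, 34, 20, 35, 36, 20, 20, 20, 36, 36)
  s <- tiny_series(start = "2017-08-01", values = list(tmax = tmax))
  ev <- data.frame(visit_id = "v1", region_id = "R01",
                   discharge_date = as.Date("2017-08-02"))
  w <- wscore(ev, s, crit)
  expect_equal(w$tmax, 3)  # day0 advisory (1) + day3 warning (2)
  expect_equal(w$window_start, as.Date("2017-08-02"))
  expect_equal(w$window_end, as.Date("2017-08-08"))

  # all-zero week
  s0 <- tiny_series(values = list(tmax = rep(20, 10)))
  ev0 <- data.frame(visit_id = "v0", region_id = "R01",
                    discharge_date = as.Date("2017-06-02"))
  expect_equal(wscore(ev0, s0, crit)$tmax, 0)

  # uncovered window errors with the event and date
  ev_bad <- data.frame(visit_id = "vX", region_id = "R01",
                       discharge_date = as.Date("2017-08-06"))
  expect_error(wscore(ev_bad, s, crit), "vX.*2017-08-11")
})

test_that("wscore matches the brute-force oracle on random instances", {
  set.seed(20260902)
  for (i in 1:1000) {
    start <- as.Date("2016-12-01") + sample(0:400, 1)  # crosses year ends
    ndays <- 14
    vals <- list(
      tmax = round(runif(ndays, 25, 38), 1),
      tmin = round(runif(ndays, -18, -5), 1),
      humidity = round(runif(ndays, 15, 60), 1),
      rainfall = round(rexp(ndays, 1 / 60), 1),
      pm10 = round(rexp(ndays, 1 / 120), 1))
    s <- tiny_series(start = as.character(start), values = vals)
    discharge <- start + sample(0:(ndays - 7), 1)
    got <- wscore(data.frame(visit_id = "v", region_id = "R01",
                             discharge_date = discharge), s, crit)
    want <- oracle_wscore(s, "R01", discharge, crit)
    expect_equal(unlist(got[c("pm10", "rainfall", "humidity", "tmin", "tmax")]),
                 want[c("pm10", "rainfall", "humidity", "tmin", "tmax")],
                 ignore_attr = TRUE,
                 info = sprintf("instance %d start %s", i, start))
  }
})

test_that("raising a day's pm10 never decreases the pm10 element", {
  set.seed(12)
  for (i in 1:30) {
    vals <- list(pm10 = round(rexp(10, 1 / 100), 1))
    s <- tiny_series(values = vals)
    ev <- data.frame(visit_id = "v", region_id = "R01",
                     discharge_date = as.Date("2017-06-02"))
    base <- wscore(ev, s, crit)$pm10
    day <- sample(2:8, 1)
    s2 <- s
    s2$value[day] <- s2$value[day] + 200
    expect_gte(wscore(ev, s2, crit)$pm10, base)
  }
})

test_that("shifting the discharge date shifts the window without drift", {
  set.seed(13)
  ndays <- 430  # crosses a year boundary
  vals <- list(pm10 = round(rexp(ndays, 1 / 120), 1),
               tmax = round(runif(ndays, 20, 38), 1))
  s <- tiny_series(start = "2016-11-20", values = vals)
  daily <- score_series(s, crit)
  for (i in 1:25) {
    d <- as.Date("2016-11-25") + sample(0:390, 1)
    w <- wscore(data.frame(visit_id = "v", region_id = "R01",
                           discharge_date = d), s, crit)
    for (el in c("pm10", "tmax")) {
      days <- daily[daily$element == el & daily$date >= d &
                      daily$date <= d + 6, ]
      expect_equal(w[[el]], sum(days$points), info = paste(el, d))
    }
  }
})
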