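# Environmental exposure: harmonize station weather/air-quality records into
# per-region daily series, and score each index event's 7-day post-discharge
# window against advisory/warning criteria (the W-score).
#
# Scoring form: graded points per day — advisory_points (default 1) when the
# advisory criterion is met, warning_points (default 2) when the stricter
# warning criterion is met — summed per element over the 7 consecutive days
# starting at the discharge date (day 0 included). Multi-day persistence
# requirements are evaluated retrospectively: a tier fires on a day only if
# that day ends a run of at least `persistence_days` consecutive days all
# meeting the tier's threshold. Among pollutants only PM10 is scored; PM2.5,
# SO2, NO2 and O3 are ingested and exported but never scored (PM2.5 is
# collinear with PM10 and patchier).

WEATHER_ELEMENTS <- c("tmax", "tmin", "humidity", "rainfall", "pm10",
                      "pm25", "so2", "no2", "o3")
SCORED_ELEMENTS <- c("pm10", "rainfall", "humidity", "tmin", "tmax")

#' Advisory/warning criteria for W-score elements
#'
#' Builds (or loads from YAML) the per-element criteria table. Each scored
#' element carries an advisory threshold, a stricter warning threshold, a
#' direction (`"above"`: value >= threshold fires; `"below"`: value <=
#' threshold fires), a persistence requirement in days, and the points each
#' tier contributes per qualifying day.
#'
#' The shipped defaults restate special-weather-report criteria at daily
#' resolution: heat (tmax >= 33 / >= 35 deg C, 2-day persistence), cold wave
#' (tmin <= -12 / <= -15 deg C, 2-day), dryness (relative humidity <= 35 /
#' <= 25 %, 2-day), heavy rain (daily rainfall >= 80 / >= 150 mm) and fine
#' dust (PM10 >= 150 / >= 300 ug/m3). All thresholds and points are config,
#' not code, so alternative criteria are a file edit.
#'
#' @param path optional YAML file with one entry per element mirroring the
#'   fields above; `NULL` returns the shipped defaults (a copy of which is
#'   installed at `system.file("extdata", "criteria.yaml",
#'   package = "readmitw")`).
#' @return a named list of per-element criteria, class `warning_criteria`.
#' @export
warning_criteria <- function(path = NULL) {
  defaults <- list(
    tmax = list(direction = "above", advisory = 33, warning = 35,
                persistence_days = 2L, advisory_points = 1, warning_points = 2),
    tmin = list(direction = "below", advisory = -12, warning = -15,
                persistence_days = 2L, advisory_points = 1, warning_points = 2),
    humidity = list(direction = "below", advisory = 35, warning = 25,
                    persistence_days = 2L, advisory_points = 1, warning_points = 2),
    rainfall = list(direction = "above", advisory = 80, warning = 150,
                    persistence_days = 1L, advisory_points = 1, warning_points = 2),
    pm10 = list(direction = "above", advisory = 150, warning = 300,
                persistence_days = 1L, advisory_points = 1, warning_points = 2))
  crit <- if (is.null(path)) defaults else {
    raw <- yaml::read_yaml(path)
    lapply(raw, function(el) {
      el$persistence_days <- as.integer(el$persistence_days)
      el
    })
  }
  for (nm in names(crit)) {
    el <- crit[[nm]]
    stopifnot(el$direction %in% c("above", "below"),
              el$persistence_days >= 1L,
              el$warning_points >= el$advisory_points,
              el$advisory_points >= 0)
    stricter <- if (el$direction == "above") el$warning >= el$advisory
                else el$warning <= el$advisory
    if (!stricter)
      stop(sprintf("criteria '%s': warning must be stricter than advisory", nm),
           call. = FALSE)
  }
  structure(crit, class = "warning_criteria")
}

#' Write criteria to YAML
#' @param criteria a [warning_criteria()] object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_criteria <- function(criteria, path) {
  yaml::write_yaml(lapply(unclass(criteria), function(el) {
    el$persistence_days <- as.integer(el$persistence_days)
    el
  }), path)
  invisible(path)
}

check_station_records <- function(stations) {
  stopifnot(all(c("station_id", "date", "element", "value") %in% names(stations)))
  stations$date <- as.Date(stations$date)
  stations$value <- as.numeric(stations$value)
  bad <- stations$element == "humidity" & !is.na(stations$value) &
    (stations$value < 0 | stations$value > 100)
  if (any(bad)) stop("humidity values must lie in [0, 100]", call. = FALSE)
  bad <- stations$element %in% c("rainfall", "pm10", "pm25", "so2", "no2", "o3") &
    !is.na(stations$value) & stations$value < 0
  if (any(bad)) stop("rainfall/pollutant values must be non-negative", call. = FALSE)
  unknown <- setdiff(unique(stations$element), WEATHER_ELEMENTS)
  if (length(unknown))
    stop(sprintf("unknown weather element '%s'", unknown[1]), call. = FALSE)
  stations
}

#' Harmonize station records into per-region daily series
#'
#' For every region, calendar day in the window, and element reported by any
#' of that region's stations, the harmonized value is the median across the
#' region's reporting (non-missing) stations. Days on which no station
#' reports remain missing until [impute_missing()].
#'
#' @param stations long data frame: `station_id`, `date`, `element`, `value`
#'   (NA = missing record).
#' @param station_map data frame `station_id`, `region_id` (a station belongs
#'   to exactly one region).
#' @param window length-2 Date vector: the study window to cover.
#' @return long data frame `region_id`, `date`, `element`, `value`,
#'   `imputed` (all FALSE here), covering every region/element/day.
#' @export
harmonize <- function(stations, station_map, window) {
  stations <- check_station_records(stations)
  window <- as.Date(window)
  unmapped <- setdiff(unique(stations$station_id), station_map$station_id)
  if (length(unmapped))
    stop(sprintf("station '%s' has no region mapping", unmapped[1]), call. = FALSE)
  regions <- unique(station_map$region_id)
  covered <- unique(station_map$region_id[station_map$station_id %in%
                                            stations$station_id])
  orphan <- setdiff(regions, covered)
  if (length(orphan))
    stop(sprintf("region '%s' has zero reporting stations", orphan[1]),
         call. = FALSE)

  stations$region_id <- station_map$region_id[match(stations$station_id,
                                                    station_map$station_id)]
  elements <- sort(unique(stations$element))
  dates <- seq(window[1], window[2], by = "day")
  grid <- expand.grid(date = dates, region_id = sort(regions),
                      element = elements, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  obs <- stations[!is.na(stations$value) & stations$date >= window[1] &
                    stations$date <= window[2], , drop = FALSE]
  key <- paste(obs$region_id, obs$date, obs$element, sep = "\r")
  med <- tapply(obs$value, key, stats::median)
  gkey <- paste(grid$region_id, grid$date, grid$element, sep = "\r")
  grid$value <- as.numeric(med[gkey])
  grid$imputed <- FALSE
  grid <- grid[order(grid$region_id, grid$element, grid$date),
               c("region_id", "date", "element", "value", "imputed")]
  rownames(grid) <- NULL
  grid
}

#' Fill missing region-days with the element's window average
#'
#' A missing region-day is filled with the average of that element's
#' regional daily medians over the study window (the mean of the observed
#' harmonized values for that region and element), and flagged as imputed.
#' An element never observed in a region is fatal. Because fills are
#' climatological means, an imputed minimum temperature is capped at the
#' same day's maximum so the per-day ordering survives imputation.
#'
#' @param series output of [harmonize()].
#' @return the series with no missing values and `imputed` flags set.
#' @export
impute_missing <- function(series) {
  key <- paste(series$region_id, series$element, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    vals <- series$value[idx]
    if (all(is.na(vals)))
      stop(sprintf("element '%s' never observed in region '%s'",
                   series$element[idx[1]], series$region_id[idx[1]]),
           call. = FALSE)
    fill <- mean(vals, na.rm = TRUE)
    miss <- idx[is.na(vals)]
    series$value[miss] <- fill
    series$imputed[miss] <- TRUE
  }
  # keep tmin <= tmax on days where imputation broke the ordering
  if (all(c("tmin", "tmax") %in% series$element)) {
    tmin_i <- which(series$element == "tmin")
    dkey <- paste(series$region_id, series$date, sep = "\r")
    tmax_at <- stats::setNames(series$value[series$element == "tmax"],
                               dkey[series$element == "tmax"])
    cap <- as.numeric(tmax_at[dkey[tmin_i]])
    fix <- which(!is.na(cap) & series$value[tmin_i] > cap & series$imputed[tmin_i])
    series$value[tmin_i[fix]] <- cap[fix]
  }
  series
}

# points per day for one region/element vector ordered by consecutive dates
tier_points <- function(values, dates, el) {
  meets <- function(threshold) {
    if (el$direction == "above") values >= threshold else values <= threshold
  }
  run_len <- function(flag) {
    # length of the TRUE-run ending at each position; resets on calendar gaps
    r <- integer(length(flag))
    gap <- c(TRUE, diff(as.numeric(dates)) != 1)
    for (i in seq_along(flag)) {
      r[i] <- if (!flag[i]) 0L else if (i == 1L || gap[i]) 1L else r[i - 1L] + 1L
    }
    r
  }
  warn_run <- run_len(meets(el$warning))
  adv_run <- run_len(meets(el$advisory))
  ifelse(warn_run >= el$persistence_days, el$warning_points,
         ifelse(adv_run >= el$persistence_days, el$advisory_points, 0))
}

#' Score every region-day of a series
#'
#' Applies the advisory/warning criteria to each scored element of the
#' harmonized series and returns daily points (the building block of the
#' W-score).
#'
#' @param series imputed series from [impute_missing()].
#' @param criteria a [warning_criteria()].
#' @return long data frame `region_id`, `date`, `element`, `points`.
#' @export
score_series <- function(series, criteria = warning_criteria()) {
  scored <- intersect(names(criteria), unique(series$element))
  out <- lapply(scored, function(elname) {
    el <- criteria[[elname]]
    rows <- series[series$element == elname, , drop = FALSE]
    parts <- lapply(split(seq_len(nrow(rows)), rows$region_id), function(idx) {
      idx <- idx[order(rows$date[idx])]
      data.frame(region_id = rows$region_id[idx], date = rows$date[idx],
                 element = elname,
                 points = tier_points(rows$value[idx], rows$date[idx], el),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$region_id, out$element, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Daily advisory/warning points for one region-day
#'
#' Convenience single-day view of [score_series()]: for each scored element,
#' `warning_points` if the warning criterion (including its persistence run
#' ending at `date`) is met, else `advisory_points` if the advisory
#' criterion is met, else 0.
#'
#' @param series imputed series.
#' @param region region_id.
#' @param date the day to score.
#' @param criteria a [warning_criteria()].
#' @return named numeric vector over the scored elements.
#' @export
daily_element_scores <- function(series, region, date,
                                 criteria = warning_criteria()) {
  date <- as.Date(date)
  sub <- series[series$region_id == region & series$date <= date &
                  series$date > date - 31, , drop = FALSE]
  if (!any(sub$date == date))
    stop(sprintf("region '%s' has no series coverage on %s", region, date),
         call. = FALSE)
  pts <- score_series(sub, criteria)
  day <- pts[pts$date == date, , drop = FALSE]
  out <- stats::setNames(numeric(length(SCORED_ELEMENTS)), SCORED_ELEMENTS)
  out[day$element] <- day$points
  out[intersect(SCORED_ELEMENTS, names(criteria))]
}

#' W-score of one index event
#'
#' Sums, per element, the daily advisory/warning points over the 7
#' consecutive days starting at the discharge date (day 0 included), for the
#' event's residence region. This is the retrospective analogue of feeding
#' the 7-day forecast for the patient's address at the moment of discharge.
#'
#' @param event one index-event row (needs `visit_id`, `region_id`,
#'   `discharge_date`).
#' @param series imputed regional series covering the window.
#' @param criteria a [warning_criteria()].
#' @return one-row data frame: `visit_id`, the five element scores
#'   (`pm10`, `rainfall`, `humidity`, `tmin`, `tmax`), `window_start`,
#'   `window_end`.
#' @export
wscore <- function(event, series, criteria = warning_criteria()) {
  wscore_cohort(event[1, , drop = FALSE], series, criteria)
}

#' W-scores for a whole cohort
#'
#' Vectorised [wscore()]: scores the series once, then sums each event's
#' 7-day window by lookup. An event whose window is not fully covered by its
#' region's series is fatal, naming the visit and the missing dates.
#'
#' @param events index-event data frame.
#' @param series imputed regional series.
#' @param criteria a [warning_criteria()].
#' @return data frame with one row per event (see [wscore()]).
#' @export
wscore_cohort <- function(events, series, criteria = warning_criteria()) {
  scored_el <- intersect(SCORED_ELEMENTS, names(criteria))
  out <- data.frame(visit_id = as.character(events$visit_id),
                    stringsAsFactors = FALSE)
  for (el in scored_el) out[[el]] <- 0
  out$window_start <- as.Date(events$discharge_date)
  out$window_end <- as.Date(events$discharge_date) + 6
  if (nrow(events) == 0L) return(out)

  pts <- score_series(series, criteria)
  for (el in scored_el) {
    sub <- pts[pts$element == el, , drop = FALSE]
    if (nrow(sub) == 0L) next  # element not ingested anywhere: scores 0
    lookup <- stats::setNames(sub$points, paste(sub$region_id, sub$date,
                                                sep = "\r"))
    total <- numeric(nrow(events))
    for (k in 0:6) {
      key <- paste(events$region_id, as.Date(events$discharge_date) + k,
                   sep = "\r")
      day_pts <- as.numeric(lookup[key])
      if (anyNA(day_pts)) {
        bad <- which(is.na(day_pts))[1]
        stop(sprintf("event '%s': no series coverage for region '%s' on %s",
                     events$visit_id[bad], events$region_id[bad],
                     as.Date(events$discharge_date[bad]) + k), call. = FALSE)
      }
      total <- total + day_pts
    }
    out[[el]] <- total
  }
  out
}

#' Write/read station weather files
#'
#' Long CSV (`station_id`, `date`, `element`, `value`) with empty cells for
#' missing records; ISO dates; deterministic row order.
#' @param stations station record data frame.
#' @param path CSV path.
#' @return invisibly `path` (write); the data frame (read).
#' @export
write_weather <- function(stations, path) {
  stations <- stations[order(stations$station_id, stations$element,
                             stations$date), , drop = FALSE]
  stations$date <- format(as.Date(stations$date), "%Y-%m-%d")
  utils::write.csv(stations[, c("station_id", "date", "element", "value")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_weather
#' @export
read_weather <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character",
                                       "numeric"))
  df$date <- parse_iso_date(df$date, "weather", "date")
  check_station_records(df)
}
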