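# Shared fixtures and independent oracles used across the suite.

# ---- bundle builders ---------------------------------------------------

fixture_locations <- function(regions = c("R01", "R02")) {
  data.frame(location_id = paste0("L_", regions),
             postal_code = sprintf("%05d", seq_along(regions)),
             region_id = regions, stringsAsFactors = FALSE)
}

fixture_person <- function(id, yob = 1940, gender = "female",
                           location = "L_R01") {
  data.frame(person_id = id, gender = gender, year_of_birth = yob,
             location_id = location, stringsAsFactors = FALSE)
}

fixture_visit <- function(id, person, admit, los = 3, kind = "inpatient",
                          alive = TRUE, site = "A") {
  admit <- as.Date(admit)
  data.frame(visit_id = id, person_id = person, visit_kind = kind,
             admit_date = admit, discharge_date = admit + los,
             discharged_alive = alive, site_id = site,
             stringsAsFactors = FALSE)
}

fixture_condition <- function(person, code, date) {
  data.frame(person_id = person, icd10_code = code,
             start_date = as.Date(date), stringsAsFactors = FALSE)
}

# a random valid bundle for round-trip property tests
random_bundle <- function(seed, n_persons = 5) {
  set.seed(seed)
  regions <- c("R01", "R02", "R03")
  locations <- fixture_locations(regions)
  persons <- do.call(rbind, lapply(seq_len(n_persons), function(i)
    fixture_person(sprintf("p%02d", i), yob = sample(1920:1955, 1),
                   gender = sample(c("male", "female"), 1),
                   location = sample(locations$location_id, 1))))
  visits <- do.call(rbind, lapply(seq_len(n_persons * 2), function(i)
    fixture_visit(sprintf("v%02d", i),
                  sample(persons$person_id, 1),
                  as.Date("2017-01-01") + sample(0:600, 1),
                  los = sample(0:8, 1),
                  kind = sample(c("inpatient", "emergency"), 1),
                  alive = runif(1) > 0.1)))
  conditions <- do.call(rbind, lapply(seq_len(n_persons * 3), function(i)
    fixture_condition(sample(persons$person_id, 1),
                      sample(c("I50", "J44.0", "E11.9", "M16", "C78"), 1),
                      as.Date("2016-01-01") + sample(0:900, 1))))
  dstart <- as.Date("2016-06-01") + sample(0:700, n_persons, replace = TRUE)
  drugs <- data.frame(person_id = persons$person_id,
                      ingredient_code = sprintf("ING%02d", sample(1:9, n_persons,
                                                                  replace = TRUE)),
                      start_date = dstart, end_date = dstart + sample(5:60, n_persons,
                                                                      replace = TRUE),
                      stringsAsFactors = FALSE)
  cdm_bundle(persons = persons, visits = visits, conditions = conditions,
             drugs = drugs, locations = locations, site_id = "A")
}

# ---- independent oracles -----------------------------------------------

# O(n^2) pairwise interval-merge oracle: repeatedly merge any two intervals
# whose gap is <= gap_days until a fixed point, then report per-era extent
# and occurrence counts.
oracle_merge_eras <- function(starts, ends, gap_days) {
  groups <- as.list(seq_along(starts))
  lo <- as.numeric(starts); hi <- as.numeric(ends)
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      if (is.null(groups[[i]])) next
      for (j in seq_along(groups)) {
        if (i == j || is.null(groups[[j]]) || is.null(groups[[i]])) next
        gap <- max(lo[i], lo[j]) - min(hi[i], hi[j])
        if (gap <= gap_days) {
          groups[[i]] <- c(groups[[i]], groups[[j]])
          lo[i] <- min(lo[i], lo[j]); hi[i] <- max(hi[i], hi[j])
          groups[j] <- list(NULL)
          merged <- TRUE
        }
      }
    }
    if (!merged) break
  }
  keep <- !vapply(groups, is.null, logical(1))
  out <- data.frame(start = lo[keep], end = hi[keep],
                    count = vapply(groups[keep], length, integer(1)))
  out[order(out$start), , drop = FALSE]
}

# brute-force Charlson: match every code against every prefix, longest
# prefix wins, dedup categories, apply hierarchy, sum weights
oracle_charlson <- function(codes, map) {
  codes <- unique(gsub(".", "", toupper(codes), fixed = TRUE))
  cats <- character(0)
  for (code in codes) {
    best <- ""; best_cat <- NULL
    for (r in seq_len(nrow(map))) {
      pf <- map$prefix[r]
      if (startsWith(code, pf) && nchar(pf) > nchar(best)) {
        best <- pf; best_cat <- map$category[r]
      }
    }
    if (!is.null(best_cat)) cats <- union(cats, best_cat)
  }
  for (pair in list(c("diabetes_complicated", "diabetes_uncomplicated"),
                    c("severe_liver_disease", "mild_liver_disease"),
                    c("metastatic_solid_tumor", "any_malignancy")))
    if (all(pair %in% cats)) cats <- setdiff(cats, pair[2])
  sum(map$weight[match(cats, map$category)])
}

# brute-force daily scoring + 7-day sum oracle for the W-score
oracle_daily_points <- function(values_by_date, date, el) {
  meets <- function(v, thr) {
    if (is.na(v)) return(FALSE)
    if (el$direction == "above") v >= thr else v <= thr
  }
  run_ok <- function(thr) {
    for (k in seq_len(el$persistence_days) - 1L) {
      v <- values_by_date[[as.character(date - k)]]
      if (is.null(v) || !meets(v, thr)) return(FALSE)
    }
    TRUE
  }
  if (run_ok(el$warning)) el$warning_points
  else if (run_ok(el$advisory)) el$advisory_points
  else 0
}

oracle_wscore <- function(series, region, discharge, criteria) {
  out <- numeric(0)
  for (elname in intersect(c("pm10", "rainfall", "humidity", "tmin", "tmax"),
                           names(criteria))) {
    rows <- series[series$region_id == region & series$element == elname, ]
    vals <- as.list(stats::setNames(rows$value, as.character(rows$date)))
    total <- 0
    for (k in 0:6)
      total <- total + oracle_daily_points(vals, discharge + k,
                                           criteria[[elname]])
    out[elname] <- total
  }
  out
}

# O(n^2) pair-counting AUROC oracle, ties count one half
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# tiny complete regional series built by hand: one region, consecutive days
tiny_series <- function(region = "R01", start = "2017-06-01", values) {
  # `values` is a named list element -> numeric vector (one per day)
  days <- seq(as.Date(start), by = "day",
              length.out = length(values[[1]]))
  do.call(rbind, lapply(names(values), function(el)
    data.frame(region_id = region, date = days, element = el,
               value = values[[el]], imputed = FALSE,
               stringsAsFactors = FALSE)))
}
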