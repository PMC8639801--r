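# Cohort construction: index admissions, planned/unplanned classification of
# subsequent visits, the 30-day unplanned-readmission outcome, disease-group
# and season assignment.
#
# Conventions pinned here (day resolution throughout):
#   * inclusion: age >= 65 at admission, discharged alive, discharge inside
#     the analysis window, residence resolvable to a covered region;
#   * outcome window: (discharge, discharge + window_days] — a visit starting
#     on the discharge day itself is a transfer, not a readmission, and day
#     +window_days (30) still counts;
#   * only emergency-route admissions can be readmissions, and only when not
#     matched by the planned-care code lists (chemotherapy, transplant,
#     rehabilitation by default);
#   * each qualifying discharge is its own index event, even when its
#     admission falls inside an earlier event's open outcome window.

#' Load planned-readmission code lists
#'
#' Reads a `category,prefix` CSV of ICD-10 prefixes describing planned care
#' (at minimum chemotherapy, organ transplant and rehabilitation), following
#' the CMS hospital-wide readmission measure's planned/unplanned split.
#'
#' @param path CSV file; defaults to the editable list shipped with the
#'   package.
#' @return a `planned_code_lists` data frame.
#' @export
planned_code_lists <- function(path = system.file("extdata", "planned_codes.csv",
                                                  package = "readmitw")) {
  lists <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(identical(names(lists), c("category", "prefix")), nrow(lists) > 0)
  lists$prefix <- normalize_icd10(lists$prefix)
  class(lists) <- c("planned_code_lists", class(lists))
  lists
}

#' Classify a visit as planned or unplanned
#'
#' A visit is planned iff any of its diagnoses prefix-matches a planned-care
#' category; a visit with no diagnosis, or none matching, is unplanned.
#'
#' @param diagnoses character vector of ICD-10 codes recorded at the visit.
#' @param lists a [planned_code_lists()].
#' @return logical scalar.
#' @export
classify_planned <- function(diagnoses, lists = planned_code_lists()) {
  if (length(diagnoses) == 0L) return(FALSE)
  codes <- normalize_icd10(diagnoses)
  any(vapply(codes, function(code) any(startsWith(code, lists$prefix)),
             logical(1)))
}

#' Season of an admission date
#'
#' Meteorological seasons: Mar–May spring, Jun–Aug summer, Sep–Nov fall,
#' Dec–Feb winter.
#'
#' @param admit_date Date vector.
#' @return character vector in {spring, summer, fall, winter}.
#' @export
assign_season <- function(admit_date) {
  m <- as.integer(format(as.Date(admit_date), "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "fall", "fall", "fall", "winter")[m]
}

# Diagnoses recorded during one person's stay, principal first. The
# principal diagnosis is the earliest-dated condition inside the stay (the
# admission diagnosis); ties keep table order. `conditions` may be the full
# table or one person's pre-split rows (person_id = NULL).
stay_diagnoses <- function(conditions, person_id, admit_date, discharge_date) {
  if (!is.null(person_id))
    conditions <- conditions[conditions$person_id == person_id, , drop = FALSE]
  rows <- conditions[conditions$start_date >= admit_date &
                       conditions$start_date <= discharge_date, , drop = FALSE]
  rows$icd10_code[order(rows$start_date)]
}

split_conditions <- function(conditions) {
  split(conditions[, c("icd10_code", "start_date")],
        as.character(conditions$person_id))
}

#' Disease chapter group of an index event
#'
#' Returns the ICD-10 chapter of the principal (first-listed) discharge
#' diagnosis when it falls in one of the four weather-sensitive chapters —
#' mental/behavioural (F), circulatory (I), respiratory (J),
#' musculoskeletal/connective-tissue (M) — and `"other"` otherwise. An event
#' with no discharge diagnosis maps to `"other"` with a warning.
#'
#' @param diagnoses character vector of the event's discharge diagnoses,
#'   principal first.
#' @return one of "F", "I", "J", "M", "other".
#' @export
assign_disease_group <- function(diagnoses) {
  if (length(diagnoses) == 0L) {
    warning("index event has no discharge diagnosis; assigning group 'other'")
    return("other")
  }
  chapter <- substr(normalize_icd10(diagnoses[1]), 1, 1)
  if (chapter %in% c("F", "I", "J", "M")) chapter else "other"
}

age_band <- function(age) {
  cut(age, breaks = c(-Inf, 69, 79, 89, Inf),
      labels = c("60s", "70s", "80s", "90s"), right = TRUE)
}

#' Identify index admissions
#'
#' One candidate index event per hospitalization (inpatient or emergency
#' visit) of a person aged at least 65 at admission, discharged alive, with
#' discharge inside the analysis window and a residence that resolves to a
#' covered region. Assigns demographics, season, length of stay, disease
#' group and the Charlson score (lookback up to the discharge date); the
#' outcome is left unset. Exclusion counts per criterion are attached as the
#' `"exclusions"` attribute and reported via `message()`.
#'
#' @param bundle a validated [cdm_bundle()].
#' @param window length-2 Date vector: discharges outside it are excluded.
#' @param covered_regions optional character vector of region_ids with
#'   weather coverage; defaults to all regions in the bundle's locations.
#' @param map a [charlson_map()].
#' @param inpatient_only if TRUE, emergency visits cannot be index events.
#' @param include_outcome_window if TRUE, reproduce the literal
#'   all-conditions-before-end-of-readmission-interval covariate lookback
#'   (extends the Charlson cutoff by `window_days` days); default FALSE to
#'   avoid outcome-window leakage.
#' @param window_days outcome window length used only when
#'   `include_outcome_window` is TRUE.
#' @return data frame of index events (one row per qualifying visit).
#' @export
identify_index_admissions <- function(bundle, window,
                                      covered_regions = NULL,
                                      map = charlson_map(),
                                      inpatient_only = FALSE,
                                      include_outcome_window = FALSE,
                                      window_days = 30) {
  validate_cdm_bundle(bundle)
  window <- as.Date(window)
  v <- bundle$visits
  p <- bundle$persons
  lo <- bundle$locations
  if (nrow(v) == 0L) return(empty_index_events())

  pi <- match(v$person_id, p$person_id)
  region <- lo$region_id[match(p$location_id[pi], lo$location_id)]
  if (is.null(covered_regions)) covered_regions <- unique(lo$region_id)
  age <- as.integer(format(v$admit_date, "%Y")) - p$year_of_birth[pi]

  excl <- c(kind = 0L, age = 0L, death = 0L, window = 0L, location = 0L)
  keep <- rep(TRUE, nrow(v))
  drop_for <- function(keep, cond, label) {
    excl[label] <<- excl[label] + sum(keep & cond)
    keep & !cond
  }
  if (inpatient_only) keep <- drop_for(keep, v$visit_kind != "inpatient", "kind")
  keep <- drop_for(keep, age < 65, "age")
  keep <- drop_for(keep, !v$discharged_alive, "death")
  keep <- drop_for(keep, v$discharge_date < window[1] |
                     v$discharge_date > window[2], "window")
  keep <- drop_for(keep, is.na(region) | !(region %in% covered_regions),
                   "location")
  if (any(excl > 0))
    message(sprintf("index exclusions: %s",
                    paste(sprintf("%s=%d", names(excl), excl), collapse = ", ")))

  v <- v[keep, , drop = FALSE]
  if (nrow(v) == 0L) {
    out <- empty_index_events()
    attr(out, "exclusions") <- excl
    return(out)
  }
  pi <- pi[keep]; region <- region[keep]; age <- age[keep]

  cond_by_person <- split_conditions(bundle$conditions)
  diagnoses <- lapply(seq_len(nrow(v)), function(i) {
    rows <- cond_by_person[[v$person_id[i]]]
    if (is.null(rows)) return(character(0))
    stay_diagnoses(rows, NULL, v$admit_date[i], v$discharge_date[i])
  })
  group <- vapply(diagnoses, function(d)
    suppressWarnings(assign_disease_group(d)), character(1))

  cutoff <- v$discharge_date
  if (include_outcome_window) cutoff <- cutoff + window_days
  cci <- charlson_scores(bundle$conditions,
                         data.frame(person_id = v$person_id, as_of = cutoff),
                         map)

  out <- data.frame(
    visit_id = v$visit_id, person_id = v$person_id, site_id = v$site_id,
    region_id = region, admit_date = v$admit_date,
    discharge_date = v$discharge_date, age_at_index = age,
    age_band = as.character(age_band(age)),
    gender = p$gender[match(v$person_id, p$person_id)],
    season = assign_season(v$admit_date),
    length_of_stay = as.integer(v$discharge_date - v$admit_date),
    disease_group = group, charlson = cci,
    outcome = NA_integer_,
    readmission_date = as.Date(NA),
    stringsAsFactors = FALSE)
  out <- out[order(out$visit_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

empty_index_events <- function() {
  data.frame(visit_id = character(0), person_id = character(0),
             site_id = character(0), region_id = character(0),
             admit_date = as.Date(character(0)),
             discharge_date = as.Date(character(0)),
             age_at_index = integer(0), age_band = character(0),
             gender = character(0), season = character(0),
             length_of_stay = integer(0), disease_group = character(0),
             charlson = integer(0), outcome = integer(0),
             readmission_date = as.Date(character(0)),
             stringsAsFactors = FALSE)
}

#' Label the 30-day unplanned-readmission outcome
#'
#' For each index event, `outcome` is 1 iff the same person has a subsequent
#' emergency-route admission with admit date in
#' `(discharge_date, discharge_date + window_days]` within the same site's
#' bundle that is classified unplanned; the earliest such visit supplies
#' `readmission_date`. An admission on the discharge date itself is treated
#' as a transfer, not a readmission.
#'
#' @param events index events from [identify_index_admissions()].
#' @param bundle the same site's [cdm_bundle()].
#' @param lists a [planned_code_lists()].
#' @param window_days outcome window length in days (default 30).
#' @return the events with `outcome` and `readmission_date` set.
#' @export
label_outcome <- function(events, bundle, lists = planned_code_lists(),
                          window_days = 30) {
  if (nrow(events) == 0L) return(events)
  v <- bundle$visits
  er <- v[v$visit_kind == "emergency", , drop = FALSE]
  er <- er[order(er$admit_date), , drop = FALSE]
  cond_by_person <- split_conditions(bundle$conditions)
  er_by_person <- split(seq_len(nrow(er)), er$person_id)
  planned_cache <- rep(NA, nrow(er))
  is_planned <- function(i) {
    if (!is.na(planned_cache[i])) return(planned_cache[i])
    rows <- cond_by_person[[er$person_id[i]]]
    diag <- if (is.null(rows)) character(0)
      else stay_diagnoses(rows, NULL, er$admit_date[i], er$discharge_date[i])
    planned_cache[i] <<- classify_planned(diag, lists)
    planned_cache[i]
  }
  events$outcome <- 0L
  events$readmission_date <- as.Date(NA)
  for (j in seq_len(nrow(events))) {
    pe <- er_by_person[[events$person_id[j]]]
    if (is.null(pe)) next
    cand <- pe[er$admit_date[pe] > events$discharge_date[j] &
                 er$admit_date[pe] <= events$discharge_date[j] + window_days]
    for (i in cand) {
      if (!is_planned(i)) {
        events$outcome[j] <- 1L
        events$readmission_date[j] <- er$admit_date[i]
        break
      }
    }
  }
  events
}

#' Build a labelled cohort in one call
#'
#' Convenience wrapper: [identify_index_admissions()] followed by
#' [label_outcome()].
#'
#' @inheritParams identify_index_admissions
#' @inheritParams label_outcome
#' @param ... passed to [identify_index_admissions()].
#' @return labelled index-event data frame.
#' @export
build_cohort <- function(bundle, window, lists = planned_code_lists(),
                         window_days = 30, ...) {
  events <- identify_index_admissions(bundle, window, ...)
  label_outcome(events, bundle, lists, window_days)
}

#' Split a cohort into disease-subgroup cohorts
#'
#' In subgroup mode an event belongs to every chapter in {F, I, J, M} that
#' any of its stay diagnoses opens with, so one event can appear in several
#' subgroup cohorts.
#'
#' @param events labelled index events.
#' @param bundle the site's [cdm_bundle()].
#' @return named list of event data frames, one per chapter with members.
#' @export
subgroup_cohorts <- function(events, bundle) {
  chapters <- c("F", "I", "J", "M")
  members <- lapply(seq_len(nrow(events)), function(j) {
    diag <- stay_diagnoses(bundle$conditions, events$person_id[j],
                           events$admit_date[j], events$discharge_date[j])
    intersect(chapters, unique(substr(normalize_icd10(diag), 1, 1)))
  })
  out <- lapply(stats::setNames(chapters, chapters), function(ch) {
    idx <- vapply(members, function(m) ch %in% m, logical(1))
    events[idx, , drop = FALSE]
  })
  out[vapply(out, nrow, integer(1)) > 0]
}
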