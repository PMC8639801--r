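# CDM-lite core: domain tables, file I/O and referential-integrity validation.
#
# The data model is a deliberately flat subset of the OMOP common data model:
# five tables (persons, visits, conditions, drugs, locations) as comma-
# delimited UTF-8 files with ISO-8601 dates, which keeps fixtures diffable and
# round-trippable. Visit concepts are collapsed to the two kinds that drive
# index/outcome logic: inpatient and emergency.

CDM_TABLES <- c("persons", "visits", "conditions", "drugs", "locations")

CDM_COLUMNS <- list(
  persons    = c("person_id", "gender", "year_of_birth", "location_id"),
  visits     = c("visit_id", "person_id", "visit_kind", "admit_date",
                 "discharge_date", "discharged_alive", "site_id"),
  conditions = c("person_id", "icd10_code", "start_date"),
  drugs      = c("person_id", "ingredient_code", "start_date", "end_date"),
  locations  = c("location_id", "postal_code", "region_id")
)

empty_cdm_table <- function(table) {
  cols <- CDM_COLUMNS[[table]]
  df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  coerce_cdm_table(df, table)
}

coerce_cdm_table <- function(df, table) {
  cols <- CDM_COLUMNS[[table]]
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("table '%s': missing column(s) %s", table,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df <- df[, cols, drop = FALSE]
  chr <- function(x) as.character(x)
  switch(table,
    persons = {
      df$person_id <- chr(df$person_id)
      df$gender <- check_enum(df$gender, c("male", "female"), table, "gender")
      df$year_of_birth <- as.integer(df$year_of_birth)
      df$location_id <- chr(df$location_id)
    },
    visits = {
      df$visit_id <- chr(df$visit_id)
      df$person_id <- chr(df$person_id)
      df$visit_kind <- check_enum(df$visit_kind, c("inpatient", "emergency"),
                                  table, "visit_kind")
      df$admit_date <- if (inherits(df$admit_date, "Date")) df$admit_date
        else parse_iso_date(df$admit_date, table, "admit_date")
      df$discharge_date <- if (inherits(df$discharge_date, "Date")) df$discharge_date
        else parse_iso_date(df$discharge_date, table, "discharge_date")
      df$discharged_alive <- as.logical(df$discharged_alive)
      if (anyNA(df$discharged_alive))
        stop(sprintf("table 'visits': unparseable boolean at row %d",
                     which(is.na(df$discharged_alive))[1]), call. = FALSE)
      df$site_id <- chr(df$site_id)
    },
    conditions = {
      df$person_id <- chr(df$person_id)
      df$icd10_code <- toupper(chr(df$icd10_code))
      df$start_date <- if (inherits(df$start_date, "Date")) df$start_date
        else parse_iso_date(df$start_date, table, "start_date")
    },
    drugs = {
      df$person_id <- chr(df$person_id)
      df$ingredient_code <- chr(df$ingredient_code)
      df$start_date <- if (inherits(df$start_date, "Date")) df$start_date
        else parse_iso_date(df$start_date, table, "start_date")
      df$end_date <- if (inherits(df$end_date, "Date")) df$end_date
        else parse_iso_date(df$end_date, table, "end_date")
    },
    locations = {
      df$location_id <- chr(df$location_id)
      df$postal_code <- chr(df$postal_code)
      df$region_id <- chr(df$region_id)
    })
  rownames(df) <- NULL
  df
}

#' Construct a validated CDM-lite bundle
#'
#' A bundle holds the five CDM-lite tables for one hospital site plus
#' provenance metadata. Construction validates types, enum values,
#' referential integrity and, when a study window is declared, that all dates
#' fall inside it.
#'
#' @param persons,visits,conditions,drugs,locations data frames with the
#'   documented columns (see `CDM_COLUMNS`); character/date coercion applied.
#' @param site_id identifier of the contributing site.
#' @param study_window optional length-2 `Date` vector declaring the window
#'   all visit/condition/drug dates must fall inside.
#' @return an object of class `cdm_bundle`.
#' @export
#' @examples
#' b <- cdm_bundle(
#'   persons = data.frame(person_id = "p1", gender = "female",
#'                        year_of_birth = 1940, location_id = "l1"),
#'   visits = data.frame(visit_id = "v1", person_id = "p1",
#'                       visit_kind = "inpatient", admit_date = "2017-03-01",
#'                       discharge_date = "2017-03-04",
#'                       discharged_alive = TRUE, site_id = "A"),
#'   conditions = data.frame(person_id = "p1", icd10_code = "I50",
#'                           start_date = "2017-03-01"),
#'   drugs = NULL, locations = data.frame(location_id = "l1",
#'                                        postal_code = "03080",
#'                                        region_id = "R01"),
#'   site_id = "A")
#' nrow(b$visits)
cdm_bundle <- function(persons = NULL, visits = NULL, conditions = NULL,
                       drugs = NULL, locations = NULL, site_id,
                       study_window = NULL) {
  tabs <- list(persons = persons, visits = visits, conditions = conditions,
               drugs = drugs, locations = locations)
  tabs <- lapply(stats::setNames(CDM_TABLES, CDM_TABLES), function(tb) {
    df <- tabs[[tb]]
    if (is.null(df) || nrow(df) == 0L) empty_cdm_table(tb)
    else coerce_cdm_table(df, tb)
  })
  bundle <- structure(
    c(tabs, list(site_id = as.character(site_id),
                 study_window = if (!is.null(study_window)) as.Date(study_window))),
    class = "cdm_bundle")
  validate_cdm_bundle(bundle)
  bundle
}

#' Validate a CDM-lite bundle's invariants
#'
#' Checks primary-key uniqueness, date ordering, ICD-10 code shape,
#' foreign-key resolution (visit/condition/drug person, person location) and
#' containment of dates in the declared study window. Errors name the
#' offending table, row and key.
#'
#' @param bundle a `cdm_bundle`.
#' @return the bundle, invisibly, if valid.
#' @export
validate_cdm_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "cdm_bundle"))
  p <- bundle$persons; v <- bundle$visits
  co <- bundle$conditions; dr <- bundle$drugs; lo <- bundle$locations

  dup <- duplicated(p$person_id)
  if (any(dup))
    stop(sprintf("table 'persons': duplicate person_id '%s' at row %d",
                 p$person_id[which(dup)[1]], which(dup)[1]), call. = FALSE)
  dup <- duplicated(v$visit_id)
  if (any(dup))
    stop(sprintf("table 'visits': duplicate visit_id '%s' at row %d",
                 v$visit_id[which(dup)[1]], which(dup)[1]), call. = FALSE)
  dup <- duplicated(lo$location_id)
  if (any(dup))
    stop(sprintf("table 'locations': duplicate location_id '%s' at row %d",
                 lo$location_id[which(dup)[1]], which(dup)[1]), call. = FALSE)

  bad <- which(v$admit_date > v$discharge_date)
  if (length(bad))
    stop(sprintf("table 'visits': admit_date after discharge_date at row %d (visit_id '%s')",
                 bad[1], v$visit_id[bad[1]]), call. = FALSE)
  bad <- which(dr$start_date > dr$end_date)
  if (length(bad))
    stop(sprintf("table 'drugs': start_date after end_date at row %d", bad[1]),
         call. = FALSE)

  bad <- which(!grepl("^[A-Z][0-9]{2}([.0-9A-Z]*)?$", co$icd10_code))
  if (length(bad))
    stop(sprintf("table 'conditions': malformed ICD-10 code '%s' at row %d",
                 co$icd10_code[bad[1]], bad[1]), call. = FALSE)

  fk <- function(child, keys, parent_keys, table, column) {
    bad <- which(!(keys %in% parent_keys))
    if (length(bad))
      stop(sprintf("table '%s': %s '%s' at row %d does not resolve",
                   table, column, keys[bad[1]], bad[1]), call. = FALSE)
  }
  fk(v, v$person_id, p$person_id, "visits", "person_id")
  fk(co, co$person_id, p$person_id, "conditions", "person_id")
  fk(dr, dr$person_id, p$person_id, "drugs", "person_id")
  fk(p, p$location_id, lo$location_id, "persons", "location_id")

  if (nrow(v) && nrow(p)) {
    yob <- p$year_of_birth[match(v$person_id, p$person_id)]
    admit_year <- as.integer(format(v$admit_date, "%Y"))
    bad <- which(admit_year < yob)
    if (length(bad))
      stop(sprintf("table 'visits': visit at row %d predates the person's birth year",
                   bad[1]), call. = FALSE)
  }

  if (!is.null(bundle$study_window)) {
    w <- bundle$study_window
    all_dates <- c(v$admit_date, v$discharge_date, co$start_date,
                   dr$start_date, dr$end_date)
    if (length(all_dates) && (min(all_dates) < w[1] || max(all_dates) > w[2]))
      stop("bundle dates fall outside the declared study window", call. = FALSE)
  }
  invisible(bundle)
}

#' @export
print.cdm_bundle <- function(x, ...) {
  cat(sprintf("<cdm_bundle> site '%s'\n", x$site_id))
  for (tb in CDM_TABLES) cat(sprintf("  %-10s %6d rows\n", tb, nrow(x[[tb]])))
  if (!is.null(x$study_window))
    cat(sprintf("  window     %s .. %s\n", x$study_window[1], x$study_window[2]))
  invisible(x)
}

format_cdm_table <- function(df) {
  for (nm in names(df)) {
    if (inherits(df[[nm]], "Date")) df[[nm]] <- format(df[[nm]], "%Y-%m-%d")
    if (is.logical(df[[nm]])) df[[nm]] <- ifelse(df[[nm]], "TRUE", "FALSE")
  }
  df
}

cdm_sort_keys <- list(
  persons = "person_id", visits = "visit_id",
  conditions = c("person_id", "icd10_code", "start_date"),
  drugs = c("person_id", "ingredient_code", "start_date"),
  locations = "location_id")

#' Write a CDM-lite bundle to a directory
#'
#' Emits one CSV per table (persons.csv, visits.csv, conditions.csv,
#' drugs.csv, locations.csv) with a stable column order, ISO-8601 dates and
#' deterministic row order (sorted by primary key), so two writes of the same
#' bundle are byte-identical.
#'
#' @param bundle a validated `cdm_bundle`.
#' @param directory output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cdm_bundle <- function(bundle, directory) {
  validate_cdm_bundle(bundle)
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", directory), call. = FALSE)
  paths <- character(0)
  for (tb in CDM_TABLES) {
    df <- bundle[[tb]]
    ord <- do.call(order, unname(df[, cdm_sort_keys[[tb]], drop = FALSE]))
    df <- format_cdm_table(df[ord, , drop = FALSE])
    path <- file.path(directory, paste0(tb, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a CDM-lite bundle from a directory
#'
#' Counterpart of [write_cdm_bundle()]: reads the five table files, parses
#' ISO-8601 dates, checks enum values and validates the bundle. A missing
#' table file is fatal; an empty file with a valid header yields an empty
#' table.
#'
#' @param directory directory containing persons.csv .. locations.csv.
#' @param site_id site identifier to stamp on the bundle.
#' @param study_window optional declared study window (length-2 Date).
#' @return a validated `cdm_bundle`.
#' @export
read_cdm_bundle <- function(directory, site_id, study_window = NULL) {
  tabs <- list()
  for (tb in CDM_TABLES) {
    path <- file.path(directory, paste0(tb, ".csv"))
    if (!file.exists(path))
      stop(sprintf("missing CDM table file '%s'", path), call. = FALSE)
    df <- utils::read.csv(path, colClasses = "character",
                          stringsAsFactors = FALSE)
    tabs[[tb]] <- if (nrow(df) == 0L) NULL else df
  }
  cdm_bundle(persons = tabs$persons, visits = tabs$visits,
             conditions = tabs$conditions, drugs = tabs$drugs,
             locations = tabs$locations, site_id = site_id,
             study_window = study_window)
}
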