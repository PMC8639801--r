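# Era derivation: collapse repeated occurrences of one concept into
# continuous periods under a persistence gap, mirroring the OMOP
# CONDITION_ERA / DRUG_ERA convention. The gap comparison is inclusive
# (distance <= gap merges), and the default gap of 30 days follows the OHDSI
# persistence-window convention; both era kinds take the gap as an argument.

era_frame <- function(person_id = character(0), concept_code = character(0),
                      start_date = as.Date(character(0)),
                      end_date = as.Date(character(0)),
                      occurrence_count = integer(0)) {
  data.frame(person_id = person_id, concept_code = concept_code,
             start_date = start_date, end_date = end_date,
             occurrence_count = occurrence_count, stringsAsFactors = FALSE)
}

# Merge intervals within one (person, concept) group. `starts`/`ends` are
# numeric day offsets, already sorted by start. A new era opens when the gap
# between the previous era's running end and the next start exceeds gap_days.
merge_intervals <- function(starts, ends, gap_days) {
  n <- length(starts)
  grp <- integer(n)
  g <- 1L
  grp[1L] <- g
  run_end <- ends[1L]
  if (n > 1L) for (i in 2:n) {
    if (starts[i] - run_end > gap_days) {
      g <- g + 1L
      run_end <- ends[i]
    } else run_end <- max(run_end, ends[i])
    grp[i] <- g
  }
  grp
}

build_eras <- function(person_id, concept_code, start_date, end_date, gap_days) {
  stopifnot(gap_days >= 0)
  n <- length(person_id)
  if (n == 0L) return(era_frame())
  s <- as.numeric(start_date); e <- as.numeric(end_date)
  key <- paste(person_id, concept_code, sep = "\r")
  ord <- order(key, s, e)
  out <- lapply(split(ord, key[ord]), function(idx) {
    grp <- merge_intervals(s[idx], e[idx], gap_days)
    first <- idx[!duplicated(grp)]
    data.frame(person_id = person_id[first],
               concept_code = concept_code[first],
               start_date = as.Date(tapply(s[idx], grp, min),
                                    origin = "1970-01-01"),
               end_date = as.Date(tapply(e[idx], grp, max),
                                  origin = "1970-01-01"),
               occurrence_count = as.integer(tabulate(grp)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$person_id, out$concept_code, out$start_date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive condition eras from condition occurrences
#'
#' Within each (person, code) group sorted by date, consecutive occurrences
#' whose inter-date distance is at most `gap_days` merge into one era; the era
#' spans from the first to the last merged date and records how many
#' occurrences it absorbed. Different codes never merge.
#'
#' @param occurrences data frame with columns `person_id`, `icd10_code`,
#'   `start_date` (as in a `cdm_bundle`).
#' @param gap_days persistence gap in days (inclusive comparison); default 30.
#' @return data frame with columns `person_id`, `concept_code`, `start_date`,
#'   `end_date`, `occurrence_count`.
#' @export
#' @examples
#' occ <- data.frame(person_id = "p", icd10_code = "J44",
#'                   start_date = as.Date("2017-01-01") + c(0, 10, 60))
#' build_condition_eras(occ, gap_days = 30)  # two eras: days 0-10 and day 60
build_condition_eras <- function(occurrences, gap_days = 30) {
  build_eras(as.character(occurrences$person_id),
             as.character(occurrences$icd10_code),
             as.Date(occurrences$start_date), as.Date(occurrences$start_date),
             gap_days)
}

#' Derive drug eras from drug exposures
#'
#' As [build_condition_eras()], but an exposure occupies the interval
#' `[start_date, end_date]` and merging uses the gap between one exposure's
#' end and the next exposure's start. Overlapping exposures always merge.
#'
#' @param exposures data frame with columns `person_id`, `ingredient_code`,
#'   `start_date`, `end_date`.
#' @inheritParams build_condition_eras
#' @return data frame as in [build_condition_eras()].
#' @export
build_drug_eras <- function(exposures, gap_days = 30) {
  build_eras(as.character(exposures$person_id),
             as.character(exposures$ingredient_code),
             as.Date(exposures$start_date), as.Date(exposures$end_date),
             gap_days)
}

#' Export eras as CSV
#'
#' Mirrors the CDM-lite file conventions (ISO dates, deterministic order).
#' @param eras era data frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_eras <- function(eras, path) {
  eras <- eras[order(eras$person_id, eras$concept_code, eras$start_date), ,
               drop = FALSE]
  eras$start_date <- format(eras$start_date, "%Y-%m-%d")
  eras$end_date <- format(eras$end_date, "%Y-%m-%d")
  utils::write.csv(eras, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
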