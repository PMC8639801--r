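# Covariate assembly: one row per index event, in two configurations
# (clinical-only and clinical + W-score). Era covariates are grouped at the
# 3-character ICD-10 level for conditions and the ingredient code for drugs
# (a vocabulary-level concept rollup would require vocabulary tables this
# package deliberately does not depend on; the grouping depth is an
# argument). Column order is deterministic (fixed demographic block, then
# lexicographic era blocks, then the W block), so repeated runs are
# byte-identical.

FIXED_FEATURES <- c("age", "gender_male",
                    "age_band_60s", "age_band_70s", "age_band_80s",
                    "age_band_90s",
                    "season_spring", "season_summer", "season_fall",
                    "season_winter",
                    "length_of_stay", "charlson")
W_FEATURES <- paste0("w_", SCORED_ELEMENTS)

era_indicator <- function(events, eras, prefix, group_depth = NULL) {
  if (is.null(eras) || nrow(eras) == 0L)
    return(matrix(0, nrow(events), 0,
                  dimnames = list(NULL, character(0))))
  grp <- as.character(eras$concept_code)
  if (!is.null(group_depth)) grp <- substr(normalize_icd10(grp), 1, group_depth)
  hit <- merge(
    data.frame(row = seq_len(nrow(events)), person_id = events$person_id,
               cutoff = events$discharge_date, stringsAsFactors = FALSE),
    data.frame(person_id = eras$person_id, grp = grp,
               start_date = eras$start_date, stringsAsFactors = FALSE),
    by = "person_id")
  hit <- hit[hit$start_date <= hit$cutoff, , drop = FALSE]
  cols <- sort(unique(grp))
  m <- matrix(0, nrow(events), length(cols),
              dimnames = list(NULL, paste0(prefix, cols)))
  if (nrow(hit)) m[cbind(hit$row, match(hit$grp, cols))] <- 1
  m
}

#' Assemble the per-event feature matrix
#'
#' Fixed block: continuous age, gender indicator, age-band and season
#' indicators, length of stay, Charlson score. Era blocks: one binary column
#' per condition-era group (prefix `cond_`) and drug-era group (`drug_`),
#' set to 1 iff the person has an era of that group starting on or before
#' the index discharge date. In `clinical_w` mode the five W-score element
#' columns (`w_pm10` .. `w_tmax`) are appended; the label column is the
#' outcome. Era columns with fewer than `min_count` positive cells are
#' dropped (rare-concept filter).
#'
#' @param events labelled index events (outcome set).
#' @param condition_eras,drug_eras era data frames from the era builder.
#' @param wscores W-score data frame from [wscore_cohort()] (required in
#'   `clinical_w` mode; a missing event is fatal and named).
#' @param mode `"clinical"` or `"clinical_w"`.
#' @param min_count rare-concept filter threshold (default 10).
#' @param group_depth ICD-10 grouping depth for condition eras (default 3).
#' @return a `feature_matrix`: list with `features` (data frame keyed by
#'   `visit_id`, feature columns, `outcome`), `columns` (the manifest) and
#'   `mode`.
#' @export
assemble_features <- function(events, condition_eras, drug_eras,
                              wscores = NULL,
                              mode = c("clinical", "clinical_w"),
                              min_count = 10, group_depth = 3) {
  mode <- match.arg(mode)
  if (anyNA(events$outcome))
    stop("events must be labelled before feature assembly", call. = FALSE)
  fixed <- data.frame(
    age = as.numeric(events$age_at_index),
    gender_male = as.numeric(events$gender == "male"),
    age_band_60s = as.numeric(events$age_band == "60s"),
    age_band_70s = as.numeric(events$age_band == "70s"),
    age_band_80s = as.numeric(events$age_band == "80s"),
    age_band_90s = as.numeric(events$age_band == "90s"),
    season_spring = as.numeric(events$season == "spring"),
    season_summer = as.numeric(events$season == "summer"),
    season_fall = as.numeric(events$season == "fall"),
    season_winter = as.numeric(events$season == "winter"),
    length_of_stay = as.numeric(events$length_of_stay),
    charlson = as.numeric(events$charlson))

  cond <- era_indicator(events, condition_eras, "cond_", group_depth)
  drug <- era_indicator(events, drug_eras, "drug_", NULL)
  keep <- function(m) m[, colSums(m) >= min_count, drop = FALSE]
  cond <- keep(cond); drug <- keep(drug)

  out <- cbind(fixed, as.data.frame(cond), as.data.frame(drug))
  if (mode == "clinical_w") {
    if (is.null(wscores))
      stop("clinical_w mode requires W-scores", call. = FALSE)
    i <- match(events$visit_id, wscores$visit_id)
    if (anyNA(i))
      stop(sprintf("missing W-score for visit_id(s): %s",
                   paste(utils::head(events$visit_id[is.na(i)], 5),
                         collapse = ", ")), call. = FALSE)
    for (el in SCORED_ELEMENTS)
      out[[paste0("w_", el)]] <- as.numeric(wscores[[el]][i])
  }
  if (anyNA(out)) stop("feature matrix contains missing cells", call. = FALSE)
  feature_matrix(cbind(data.frame(visit_id = events$visit_id,
                                  stringsAsFactors = FALSE),
                       out,
                       data.frame(outcome = as.integer(events$outcome))),
                 mode)
}

feature_matrix <- function(features, mode) {
  structure(list(features = features,
                 columns = setdiff(names(features), c("visit_id", "outcome")),
                 mode = mode),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d events x %d features (mode %s), %.1f%% positive\n",
              nrow(x$features), length(x$columns), x$mode,
              100 * mean(x$features$outcome)))
  invisible(x)
}

#' Conform a feature matrix to a training manifest
#'
#' Reorders columns to match the manifest exactly, zero-filling manifest
#' columns absent from the matrix (e.g. concepts unseen at the external
#' site) and dropping extra columns (logged via `message()`). The label
#' column must be present.
#'
#' @param fm a `feature_matrix`.
#' @param manifest character vector of training feature columns (a
#'   `feature_matrix`'s `columns`, or the object itself).
#' @return a conformed `feature_matrix`.
#' @export
conform_features <- function(fm, manifest) {
  if (inherits(manifest, "feature_matrix")) manifest <- manifest$columns
  if (!("outcome" %in% names(fm$features)))
    stop("label column 'outcome' absent", call. = FALSE)
  extra <- setdiff(fm$columns, manifest)
  if (length(extra))
    message(sprintf("conform: dropping %d column(s) not in manifest (%s)",
                    length(extra),
                    paste(utils::head(extra, 5), collapse = ", ")))
  missing <- setdiff(manifest, fm$columns)
  f <- fm$features
  for (col in missing) f[[col]] <- 0
  f <- f[, c("visit_id", manifest, "outcome"), drop = FALSE]
  feature_matrix(f, fm$mode)
}

# numeric model matrix + label vector
fm_xy <- function(fm) {
  x <- as.matrix(fm$features[, fm$columns, drop = FALSE])
  storage.mode(x) <- "double"
  list(x = x, y = as.integer(fm$features$outcome))
}

#' Write features and manifest
#' @param fm a `feature_matrix`.
#' @param path CSV path; the manifest is written alongside as
#'   `<path>.manifest.json`.
#' @return invisibly, `path`.
#' @export
write_features <- function(fm, path) {
  utils::write.csv(fm$features, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(mode = fm$mode, columns = fm$columns),
                       paste0(path, ".manifest.json"), auto_unbox = TRUE)
  invisible(path)
}
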