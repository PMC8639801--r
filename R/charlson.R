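# Charlson comorbidity index, Romano adaptation, over ICD-10-coded condition
# history. The category/prefix/weight table ships as an editable CSV so the
# mapping is auditable and swappable (other adaptations can be dropped in).

# Severity hierarchies: when both members of a pair are matched, only the
# more severe (first) category contributes.
CHARLSON_HIERARCHY <- list(
  c("diabetes_complicated", "diabetes_uncomplicated"),
  c("severe_liver_disease", "mild_liver_disease"),
  c("metastatic_solid_tumor", "any_malignancy"))

#' Load a Charlson category mapping table
#'
#' Reads a `category,prefix,weight` CSV mapping ICD-10 code prefixes (dots
#' ignored) to the 17 Charlson comorbidity categories with Romano-adaptation
#' weights, and validates its shape.
#'
#' @param path CSV file; default is the Romano-adaptation map shipped with
#'   the package.
#' @return a `charlson_map` data frame with columns `category`, `prefix`,
#'   `weight`.
#' @export
charlson_map <- function(path = system.file("extdata", "charlson_map_romano.csv",
                                            package = "readmitw")) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "integer"))
  stopifnot(identical(names(map), c("category", "prefix", "weight")))
  map$prefix <- normalize_icd10(map$prefix)
  cats <- unique(map$category)
  if (length(cats) != 17L)
    stop(sprintf("Charlson map must define 17 categories, found %d",
                 length(cats)), call. = FALSE)
  if (!all(map$weight %in% c(1L, 2L, 3L, 6L)))
    stop("Charlson weights must be in {1, 2, 3, 6}", call. = FALSE)
  w <- tapply(map$weight, map$category, function(x) length(unique(x)))
  if (any(w != 1L))
    stop("each Charlson category must have a single weight", call. = FALSE)
  ncat <- tapply(map$category, map$prefix, function(x) length(unique(x)))
  if (any(ncat > 1L))
    stop(sprintf("prefix '%s' maps to more than one category",
                 names(ncat)[ncat > 1L][1]), call. = FALSE)
  class(map) <- c("charlson_map", class(map))
  map
}

# Match one normalised code against the map; ambiguity across categories is
# resolved by longest-prefix match. Returns matched category names (possibly
# none).
match_charlson_categories <- function(codes, map) {
  codes <- unique(normalize_icd10(codes))
  hits <- lapply(codes, function(code) {
    m <- startsWith(code, map$prefix)
    if (!any(m)) return(character(0))
    lens <- nchar(map$prefix[m])
    map$category[m][lens == max(lens)][1]
  })
  unique(unlist(hits))
}

#' Charlson comorbidity score for one patient
#'
#' Sums the weights of the distinct Charlson categories matched by any
#' condition dated on or before `as_of`. Each category counts once; severity
#' hierarchies apply (complicated diabetes over uncomplicated, severe liver
#' disease over mild, metastatic tumor over non-metastatic malignancy), so a
#' graded comorbidity contributes only its highest matched weight. Unmatched
#' codes contribute nothing.
#'
#' The lookback cutoff defaults to the index discharge date so that no
#' information from the outcome window leaks into the covariate.
#'
#' @param conditions data frame with columns `person_id` (ignored; pass one
#'   patient's rows), `icd10_code`, `start_date`.
#' @param as_of lookback cutoff date (inclusive).
#' @param map a [charlson_map()].
#' @return a single non-negative integer score.
#' @export
#' @examples
#' m <- charlson_map()
#' conds <- data.frame(person_id = "p",
#'                     icd10_code = c("I21", "I22", "C78"),
#'                     start_date = as.Date("2016-06-01"))
#' charlson_score(conds, as.Date("2017-01-01"), m)  # 1 (MI once) + 6 = 7
charlson_score <- function(conditions, as_of, map = charlson_map()) {
  if (is.null(conditions) || nrow(conditions) == 0L) return(0L)
  keep <- as.Date(conditions$start_date) <= as.Date(as_of)
  codes <- conditions$icd10_code[keep]
  if (!length(codes)) return(0L)
  cats <- match_charlson_categories(codes, map)
  for (pair in CHARLSON_HIERARCHY)
    if (all(pair %in% cats)) cats <- setdiff(cats, pair[2])
  if (!length(cats)) return(0L)
  weights <- map$weight[match(cats, map$category)]
  as.integer(sum(weights))
}

#' Charlson scores for many patients at once
#'
#' Vectorised convenience over [charlson_score()]: scores every person in
#' `persons_as_of` against the full conditions table.
#'
#' @param conditions conditions table (`person_id`, `icd10_code`, `start_date`).
#' @param persons_as_of data frame with columns `person_id` and `as_of` (Date).
#' @param map a [charlson_map()].
#' @return integer vector aligned with `persons_as_of` rows.
#' @export
charlson_scores <- function(conditions, persons_as_of, map = charlson_map()) {
  if (nrow(persons_as_of) == 0L) return(integer(0))
  by_person <- split(conditions[, c("icd10_code", "start_date")],
                     as.character(conditions$person_id))
  # Precompute per-condition category at 4-char resolution to avoid
  # re-matching the same code repeatedly.
  vapply(seq_len(nrow(persons_as_of)), function(i) {
    rows <- by_person[[as.character(persons_as_of$person_id[i])]]
    if (is.null(rows)) return(0L)
    charlson_score(cbind(person_id = "x", rows), persons_as_of$as_of[i], map)
  }, integer(1))
}
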