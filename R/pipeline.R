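# End-to-end pipeline: simulate -> build cohort -> W-score -> featurize ->
# train -> external validation -> report. This is the package's "one call"
# surface and the backbone of the reproducibility checks: with a fixed
# config the produced report files are byte-identical across runs.

#' Run the full readmission study end to end
#'
#' Generates (or accepts) a two-site study, builds the labelled cohorts,
#' computes W-scores, assembles clinical and clinical+W feature matrices
#' (external conformed to the training manifest), trains the requested
#' model families with grid-search CV, validates them on the external site
#' and, when `out` is given, writes the report files.
#'
#' @param config a [sim_config()].
#' @param families character vector of model families to train.
#' @param modes feature configurations (`"clinical"`, `"clinical_w"`).
#' @param specs optional named list of [model_spec()]s per family
#'   (defaults to each family's default grid).
#' @param criteria a [warning_criteria()].
#' @param out optional output directory for report files.
#' @param study optional pre-generated [generate_study()] output (so the
#'   same study can be re-analysed).
#' @param k CV folds.
#' @return list: `runs` (list of `model_run`s keyed `family_mode`),
#'   `cohorts`, `features`, `summaries`, `table` (the table-3 frame when
#'   `out` is given), `study`.
#' @export
run_study <- function(config = sim_config(),
                      families = c("GBM"),
                      modes = c("clinical", "clinical_w"),
                      specs = NULL,
                      criteria = warning_criteria(),
                      out = NULL, study = NULL, k = 10) {
  if (is.null(study)) study <- generate_study(config, criteria)
  # an index discharge needs 7 days of series coverage, so the last
  # admissible discharge is 6 days before the series ends
  window <- c(config$study_window[1], config$study_window[2] - 6)

  prep_site <- function(site) {
    s <- study[[site]]
    events <- suppressMessages(build_cohort(s$bundle, window))
    ws <- wscore_cohort(events, s$series, criteria)
    cond_eras <- build_condition_eras(s$bundle$conditions)
    drug_eras <- build_drug_eras(s$bundle$drugs)
    list(events = events, wscores = ws, cond_eras = cond_eras,
         drug_eras = drug_eras)
  }
  int <- prep_site("internal")
  ext <- prep_site("external")

  features <- list()
  for (mode in modes) {
    fm_int <- assemble_features(int$events, int$cond_eras, int$drug_eras,
                                int$wscores, mode = mode)
    fm_ext <- conform_features(
      suppressMessages(assemble_features(ext$events, ext$cond_eras,
                                         ext$drug_eras, ext$wscores,
                                         mode = mode)),
      fm_int)
    features[[mode]] <- list(internal = fm_int, external = fm_ext)
  }

  runs <- list()
  for (family in families) {
    spec <- if (!is.null(specs) && !is.null(specs[[family]])) specs[[family]]
            else model_spec(family)
    for (mode in modes) {
      run <- grid_search_cv(features[[mode]]$internal, spec, k = k,
                            seed = config$seed)
      run <- external_validate(run, features[[mode]]$external)
      runs[[sprintf("%s_%s", family, mode)]] <- run
    }
  }

  summaries <- lapply(features, function(f) covariate_summary(f$internal))
  tab <- NULL
  if (!is.null(out))
    tab <- report(runs, out, covariate_summaries = summaries)
  list(runs = runs, cohorts = list(internal = int$events,
                                   external = ext$events),
       features = features, summaries = summaries, table = tab,
       study = study)
}
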