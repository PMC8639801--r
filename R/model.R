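# Model training and validation: the four tree-based families (decision
# tree, random forest, AdaBoost, gradient boosting) with grid-search
# stratified 10-fold cross-validation, a held-out internal test split,
# frozen-model external-site validation, and the AUROC statistic.
#
# Standard learner implementations are called (rpart, ranger, xgboost); the
# AdaBoost (SAMME) boosting loop is written here over rpart stumps because
# no boosting wrapper is installed — the base learner itself is still rpart.
# Default grids live in config (the grid is data, not code).

#' Model specification with hyper-parameter grid
#'
#' Families: `"DT"` (decision tree), `"RF"` (random forest), `"ADA"`
#' (AdaBoost), `"GBM"` (gradient boosting). Default grids: DT explores
#' classWeight in {balance, none} with maxDepth 10, minSamplesLeaf 10,
#' minSamplesSplit 2 and impurity-split threshold 1e-7; RF crosses maxDepth
#' {4, 10, 17} with features-per-split {sqrt(p), 5, 20} at 500 trees; ADA
#' uses learning rate 1 with 4 estimators; GBM crosses learning rate
#' {0.005, 0.01, 0.1}, maxDepth {4, 6, 17} and trees {100, 1000} with 25
#' early-stopping rounds and minimum 2 rows per node. Grid rows are
#' evaluated in declared order; ties in CV performance keep the first row.
#'
#' @param family one of DT, RF, ADA, GBM.
#' @param grid optional data frame overriding the default grid (columns as
#'   in the defaults; smaller grids make quick runs).
#' @return a `model_spec` list.
#' @export
model_spec <- function(family = c("GBM", "DT", "RF", "ADA"), grid = NULL) {
  family <- match.arg(family)
  default_grid <- switch(family,
    DT = expand.grid(class_weight = c("balance", "none"),
                     max_depth = 10, min_samples_leaf = 10,
                     min_samples_split = 2, min_impurity = 1e-7,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    RF = expand.grid(max_depth = c(4, 10, 17), mtry = c(-1, 5, 20),
                     num_trees = 500,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    ADA = data.frame(learning_rate = 1, n_estimators = 4),
    GBM = expand.grid(learning_rate = c(0.005, 0.01, 0.1),
                      max_depth = c(4, 6, 17), n_trees = c(100, 1000),
                      early_stop = 25, min_rows = 2,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  grid <- if (is.null(grid)) default_grid else as.data.frame(grid)
  if (nrow(grid) == 0L) stop("hyper-parameter grid must be non-empty",
                             call. = FALSE)
  structure(list(family = family, grid = grid), class = "model_spec")
}

#' Area under the ROC curve (rank / Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counting one half. Errors (rather than returning a
#' default) when a class is absent.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 labels.
#' @return AUROC in [0, 1].
#' @export
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Stepwise (FPR, TPR) pairs from (0, 0) to (1, 1), one step per distinct
#' score.
#' @inheritParams auroc
#' @return data frame `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)
  data.frame(fpr = c(0, fp[last] / sum(1 - y)),
             tpr = c(0, tp[last] / sum(y)))
}

# ---- family fit/predict ------------------------------------------------

fit_dt <- function(x, y, params) {
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c(0, 1))
  w <- rep(1, length(y))
  if (identical(as.character(params$class_weight), "balance")) {
    tab <- table(df$.y)
    w <- as.numeric(length(y) / (2 * tab[as.character(df$.y)]))
  }
  rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
               control = rpart::rpart.control(
                 maxdepth = params$max_depth,
                 minbucket = params$min_samples_leaf,
                 minsplit = params$min_samples_split,
                 cp = params$min_impurity, xval = 0))
}

fit_rf <- function(x, y, params, seed) {
  p <- ncol(x)
  mtry <- if (params$mtry < 0) max(1L, floor(sqrt(p))) else min(p, params$mtry)
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c(0, 1))
  ranger::ranger(dependent.variable.name = ".y", data = df,
                 probability = TRUE, num.trees = params$num_trees,
                 mtry = mtry, max.depth = params$max_depth,
                 seed = seed, num.threads = 1)
}

# Discrete AdaBoost (SAMME) over rpart stumps; returns the additive
# decision function (real-valued score, monotone in P(y = 1)).
fit_ada <- function(x, y, params) {
  n <- length(y)
  w <- rep(1 / n, n)
  yy <- ifelse(y == 1L, 1, -1)
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c(0, 1))
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(params$n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w * n, method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       minsplit = 2, cp = 0,
                                                       xval = 0))
    pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != yy))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- params$learning_rate * 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit; alphas[m] <- alpha
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (err < 1e-9) break
  }
  structure(list(stumps = stumps, alphas = alphas), class = "ada_boost")
}

predict_ada <- function(model, x) {
  df <- as.data.frame(x)
  score <- numeric(nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- ifelse(predict(model$stumps[[m]], df, type = "class") == "1",
                   1, -1)
    score <- score + model$alphas[m] * pred
  }
  score
}

fit_gbm <- function(x, y, params, seed) {
  # seeded internal validation fraction (10%) provides the early-stopping
  # partition
  n <- length(y)
  val <- with_seed(seed, sample.int(n, max(2L, floor(0.1 * n))))
  if (length(unique(y[val])) < 2L || length(unique(y[-val])) < 2L)
    val <- c(which(y == 1L)[1:2], which(y == 0L)[1:2])
  dtr <- xgboost::xgb.DMatrix(x[-val, , drop = FALSE], label = y[-val])
  dva <- xgboost::xgb.DMatrix(x[val, , drop = FALSE], label = y[val])
  xgboost::xgb.train(
    params = xgboost::xgb.params(objective = "binary:logistic",
                                 learning_rate = params$learning_rate,
                                 max_depth = params$max_depth,
                                 min_child_weight = params$min_rows,
                                 eval_metric = "auc",
                                 nthread = 1, seed = seed),
    data = dtr, nrounds = params$n_trees, evals = list(val = dva),
    early_stopping_rounds = params$early_stop, verbose = 0)
}

fit_family <- function(family, x, y, params, seed) {
  if (length(unique(y)) < 2L)
    stop("training data contain a single class", call. = FALSE)
  switch(family,
         DT = fit_dt(x, y, params),
         RF = fit_rf(x, y, params, seed),
         ADA = fit_ada(x, y, params),
         GBM = fit_gbm(x, y, params, seed))
}

predict_family <- function(family, model, x) {
  switch(family,
         DT = unname(predict(model, as.data.frame(x))[, "1"]),
         RF = unname(predict(model, as.data.frame(x),
                             num.threads = 1)$predictions[, "1"]),
         ADA = predict_ada(model, x),
         GBM = predict(model, xgboost::xgb.DMatrix(x)))
}

# stratified assignment of 1..k fold ids, seeded
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Grid-search cross-validation with a held-out test split
#'
#' Splits the matrix into a stratified 75/25 train/test partition (seeded),
#' evaluates every grid row by stratified k-fold cross-validated AUROC on
#' the training part, selects the best mean CV AUROC (ties keep the first
#' grid row), refits that configuration on the full training part, and
#' scores the held-out test part.
#'
#' @param fm a `feature_matrix` (both classes required).
#' @param spec a [model_spec()].
#' @param k number of CV folds (default 10).
#' @param seed integer seed controlling the split, folds and learner RNG.
#' @param train_fraction held-in fraction (default 0.75).
#' @return a `model_run`: family, selected hyper-parameters, per-grid-point
#'   CV AUROCs, fitted model, internal test AUROC, test scores/labels,
#'   manifest and mode.
#' @export
grid_search_cv <- function(fm, spec, k = 10, seed = 1L,
                           train_fraction = 0.75) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(spec, "model_spec"),
            k >= 2)
  xy <- fm_xy(fm)
  if (length(unique(xy$y)) < 2L)
    stop("training data contain a single class", call. = FALSE)
  n <- length(xy$y)
  test_fold <- stratified_folds(xy$y, round(1 / (1 - train_fraction)),
                                sub_seed(seed, "split"))
  test_idx <- which(test_fold == 1L)
  tr_x <- xy$x[-test_idx, , drop = FALSE]; tr_y <- xy$y[-test_idx]
  te_x <- xy$x[test_idx, , drop = FALSE]; te_y <- xy$y[test_idx]

  folds <- stratified_folds(tr_y, k, sub_seed(seed, "folds"))
  grid <- spec$grid
  cv_auc <- matrix(NA_real_, nrow(grid), k)
  for (g in seq_len(nrow(grid))) {
    params <- grid[g, , drop = FALSE]
    for (f in seq_len(k)) {
      in_tr <- folds != f
      model <- fit_family(spec$family, tr_x[in_tr, , drop = FALSE],
                          tr_y[in_tr], params,
                          seed = sub_seed(seed, sprintf("fit_%d_%d", g, f)))
      sc <- predict_family(spec$family, model,
                           tr_x[!in_tr, , drop = FALSE])
      cv_auc[g, f] <- auroc(sc, tr_y[!in_tr])
    }
  }
  mean_cv <- rowMeans(cv_auc)
  best <- which.max(mean_cv)          # which.max keeps the first tie
  final <- fit_family(spec$family, tr_x, tr_y, grid[best, , drop = FALSE],
                      seed = sub_seed(seed, "final"))
  test_scores <- predict_family(spec$family, final, te_x)
  run <- list(family = spec$family,
              selected = grid[best, , drop = FALSE],
              cv_results = cbind(grid, mean_cv_auc = mean_cv),
              cv_auc_selected = mean_cv[best],
              model = final,
              test_auc = auroc(test_scores, te_y),
              test_scores = test_scores, test_labels = te_y,
              external_auc = NA_real_,
              external_scores = NULL, external_labels = NULL,
              seed = seed, manifest = fm$columns, mode = fm$mode)
  class(run) <- "model_run"
  run
}

#' @export
print.model_run <- function(x, ...) {
  cat(sprintf("<model_run> %s (%s): CV AUROC %.3f, test AUROC %.3f%s\n",
              x$family, x$mode, x$cv_auc_selected, x$test_auc,
              if (is.na(x$external_auc)) ""
              else sprintf(", external AUROC %.3f", x$external_auc)))
  invisible(x)
}

#' External-site validation of a frozen model
#'
#' Scores the fitted model, without any refitting, on an external feature
#' matrix that must already be conformed to the run's manifest.
#'
#' @param run a `model_run` from [grid_search_cv()].
#' @param external_fm a `feature_matrix` with columns identical to the
#'   run's manifest (use [conform_features()]).
#' @return the run with `external_auc`, scores and labels set.
#' @export
external_validate <- function(run, external_fm) {
  if (!identical(external_fm$columns, run$manifest))
    stop("external matrix is not conformed to the training manifest; call conform_features() first",
         call. = FALSE)
  xy <- fm_xy(external_fm)
  run$external_scores <- predict_family(run$family, run$model, xy$x)
  run$external_labels <- xy$y
  run$external_auc <- auroc(run$external_scores, xy$y)
  run
}

#' Per-covariate means by outcome
#'
#' For every feature column: overall mean, mean among events with the
#' outcome, and mean among events without, sorted by the absolute
#' with/without difference (most outcome-separating first).
#'
#' @param fm a `feature_matrix` with labels.
#' @return data frame `covariate`, `mean`, `mean_with_outcome`,
#'   `mean_without_outcome`, `abs_diff`.
#' @export
covariate_summary <- function(fm) {
  xy <- fm_xy(fm)
  pos <- xy$y == 1L
  out <- data.frame(
    covariate = fm$columns,
    mean = colMeans(xy$x),
    mean_with_outcome = if (any(pos)) colMeans(xy$x[pos, , drop = FALSE])
                        else NA_real_,
    mean_without_outcome = if (any(!pos)) colMeans(xy$x[!pos, , drop = FALSE])
                           else NA_real_,
    stringsAsFactors = FALSE)
  out$abs_diff <- abs(out$mean_with_outcome - out$mean_without_outcome)
  out <- out[order(-out$abs_diff, out$covariate), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the evaluation report
#'
#' Produces, deterministically: `table3.csv` — one row per (family, mode)
#' with internal and external AUROC and a best-per-column flag;
#' `roc_internal_<family>_<mode>.csv` / `roc_external_...` point files;
#' `covariate_summary.csv` (when summaries are supplied); and `runs.json`
#' with the selected hyper-parameters.
#'
#' @param runs list of `model_run`s.
#' @param out output directory.
#' @param covariate_summaries optional named list of [covariate_summary()]
#'   frames to write.
#' @return invisibly, the table-3 data frame.
#' @export
report <- function(runs, out, covariate_summaries = NULL) {
  stopifnot(length(runs) >= 1)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(
    family = vapply(runs, `[[`, "", "family"),
    mode = vapply(runs, `[[`, "", "mode"),
    internal_auc = round(vapply(runs, `[[`, 0, "test_auc"), 6),
    external_auc = round(vapply(runs, function(r)
      ifelse(is.na(r$external_auc), NA_real_, r$external_auc), 0), 6),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$family, tab$mode), , drop = FALSE]
  flag_best <- function(v) !is.na(v) & v == max(v, na.rm = TRUE)
  tab$best_internal <- stats::ave(tab$internal_auc, tab$mode,
                                  FUN = flag_best) == 1
  tab$best_external <- if (all(is.na(tab$external_auc))) FALSE
    else stats::ave(tab$external_auc, tab$mode, FUN = flag_best) == 1
  utils::write.csv(tab, file.path(out, "table3.csv"), row.names = FALSE,
                   quote = FALSE)
  for (r in runs) {
    key <- sprintf("%s_%s", tolower(r$family), r$mode)
    utils::write.csv(round(roc_points(r$test_scores, r$test_labels), 6),
                     file.path(out, sprintf("roc_internal_%s.csv", key)),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(r$external_scores))
      utils::write.csv(round(roc_points(r$external_scores,
                                        r$external_labels), 6),
                       file.path(out, sprintf("roc_external_%s.csv", key)),
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(covariate_summaries)) {
    cs <- do.call(rbind, lapply(names(covariate_summaries), function(nm) {
      df <- covariate_summaries[[nm]]
      df[, -1] <- round(df[, -1], 6)
      cbind(cohort = nm, df)
    }))
    utils::write.csv(cs, file.path(out, "covariate_summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  sel <- lapply(runs, function(r)
    list(family = r$family, mode = r$mode, selected = as.list(r$selected),
         cv_auc = round(r$cv_auc_selected, 6),
         internal_auc = round(r$test_auc, 6),
         external_auc = if (is.na(r$external_auc)) NULL
                        else round(r$external_auc, 6)))
  jsonlite::write_json(sel, file.path(out, "runs.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(tab)
}
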