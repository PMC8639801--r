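# A small seeded feature matrix with genuine signal, reused across tests.
make_fm <- function(n = 300, seed = 5, p_signal = 1.2, mode = "clinical") {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-1 + p_signal * x1 + 0.5 * x3))
  df <- data.frame(visit_id = sprintf("v%04d", seq_len(n)),
                   age = 70 + 5 * x1, length_of_stay = abs(x2),
                   charlson = x3, outcome = y)
  readmitw:::feature_matrix(df, mode)
}

test_that("auroc handles the canonical cases", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("auroc matches the pair-counting oracle, including ties", {
  set.seed(20260903)
  for (i in 1:1000) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))     # both classes guaranteed
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                 info = sprintf("instance %d", i))
  }
})

test_that("auroc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, plogis(scores))
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("roc points run from (0,0) to (1,1) and track the AUC", {
  set.seed(10)
  scores <- rnorm(80)
  labels <- c(0, 1, rbinom(78, 1, 0.5))
  pts <- roc_points(scores, labels)
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  # trapezoid area under the staircase equals the rank AUROC
  area <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                 utils::tail(pts$tpr, -1)) / 2)
  expect_equal(area, auroc(scores, labels), tolerance = 1e-12)
})

test_that("covariate summary computes exact group means on a 4-row fixture", {
  df <- data.frame(visit_id = c("a", "b", "c", "d"),
                   x = c(1, 2, 3, 4), ones = 1,
                   lab = c(1, 1, 0, 0), outcome = c(1, 1, 0, 0))
  fm <- readmitw:::feature_matrix(df, "clinical")
  cs <- covariate_summary(fm)
  x <- cs[cs$covariate == "x", ]
  expect_equal(x$mean, 2.5)
  expect_equal(x$mean_with_outcome, 1.5)
  expect_equal(x$mean_without_outcome, 3.5)
  ones <- cs[cs$covariate == "ones", ]
  expect_equal(unlist(ones[, 2:4]), c(1, 1, 1), ignore_attr = TRUE)
  lab <- cs[cs$covariate == "lab", ]
  expect_equal(lab$mean_without_outcome, 0)
  expect_equal(cs$covariate[1], "x")  # sorted by |with - without|
})

test_that("each model family trains, predicts and is seed-deterministic", {
  fm <- make_fm()
  small_grids <- list(
    DT = NULL,
    RF = data.frame(max_depth = 4, mtry = -1, num_trees = 50),
    ADA = NULL,
    GBM = data.frame(learning_rate = 0.1, max_depth = 3, n_trees = 50,
                     early_stop = 10, min_rows = 2))
  for (family in c("DT", "RF", "ADA", "GBM")) {
    spec <- model_spec(family, grid = small_grids[[family]])
    r1 <- grid_search_cv(fm, spec, k = 3, seed = 7)
    r2 <- grid_search_cv(fm, spec, k = 3, seed = 7)
    expect_equal(r1$test_auc, r2$test_auc, info = family)
    expect_equal(r1$selected, r2$selected, info = family)
    expect_gt(r1$test_auc, 0.6)  # genuine signal is learnable
    expect_true(all(r1$cv_results$mean_cv_auc >= 0 &
                      r1$cv_results$mean_cv_auc <= 1))
  }
})

test_that("the default DT grid explores both class weightings", {
  expect_setequal(model_spec("DT")$grid$class_weight, c("balance", "none"))
})

test_that("a single-point grid is selected without comparison and a dominant grid point wins", {
  fm <- make_fm()
  one <- model_spec("GBM", grid = data.frame(learning_rate = 0.1,
                                             max_depth = 3, n_trees = 40,
                                             early_stop = 10, min_rows = 2))
  run <- grid_search_cv(fm, one, k = 3, seed = 3)
  expect_equal(nrow(run$cv_results), 1L)
  expect_equal(run$selected$learning_rate, 0.1)

  # a learning rate far too small to learn in 20 trees is dominated
  two <- model_spec("GBM", grid = data.frame(learning_rate = c(1e-5, 0.1),
                                             max_depth = 3, n_trees = 20,
                                             early_stop = 20, min_rows = 2))
  run2 <- grid_search_cv(fm, two, k = 3, seed = 3)
  expect_equal(run2$selected$learning_rate, 0.1)
})

test_that("single-class training data are rejected", {
  fm <- make_fm()
  fm$features$outcome <- 0L
  expect_error(grid_search_cv(fm, model_spec("DT"), k = 3, seed = 1),
               "single class")
})

test_that("external validation scores the frozen model and enforces conformance", {
  fm <- make_fm(seed = 21)
  spec <- model_spec("GBM", grid = data.frame(learning_rate = 0.1,
                                              max_depth = 3, n_trees = 40,
                                              early_stop = 10, min_rows = 2))
  run <- grid_search_cv(fm, spec, k = 3, seed = 2)

  # identical external set reproduces internal behaviour deterministically
  run2 <- external_validate(run, fm)
  expect_true(run2$external_auc > 0.5)

  # permuted labels destroy the signal: AUROC within 0.5 +/- 0.05
  fm_null <- make_fm(n = 2000, seed = 22)
  set.seed(11)
  fm_null$features$outcome <- sample(fm_null$features$outcome)
  run3 <- external_validate(run, fm_null)
  expect_lt(abs(run3$external_auc - 0.5), 0.05)

  bad <- fm
  bad$columns <- rev(bad$columns)
  expect_error(external_validate(run, bad), "conform")
})

test_that("the report writes a deterministic table with correct best flags", {
  fm <- make_fm(seed = 31)
  spec_a <- model_spec("DT")
  spec_b <- model_spec("RF", grid = data.frame(max_depth = 4, mtry = -1,
                                               num_trees = 50))
  runs <- list(grid_search_cv(fm, spec_a, k = 3, seed = 5),
               grid_search_cv(fm, spec_b, k = 3, seed = 5))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  tab1 <- report(runs, d1, covariate_summaries = list(all = covariate_summary(fm)))
  report(runs, d2, covariate_summaries = list(all = covariate_summary(fm)))
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  expect_equal(sum(tab1$best_internal), 1L)
  expect_equal(tab1$best_internal[which.max(tab1$internal_auc)], TRUE)
  roc <- read.csv(file.path(d1, "roc_internal_dt_clinical.csv"))
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))

  one <- report(runs[1], withr::local_tempdir())
  expect_true(one$best_internal)
})
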