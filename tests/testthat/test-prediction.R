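co <- table1_cohort()
lab <- label_cohort(co)

test_that("feature matrices have the documented shape and encodings", {
  fm1 <- build_feature_matrix(co, 1)
  expect_equal(dim(fm1$x), c(20L, 6L))
  expect_setequal(colnames(fm1$x),
                  c("age", "chronicity", "sex", "ms_RR", "ms_PP", "ms_SP"))
  expect_true(all(rowSums(fm1$x[, c("ms_RR", "ms_PP", "ms_SP")]) == 1))
  fm6 <- build_feature_matrix(co, 6)
  expect_equal(dim(fm6$x), c(20L, 3L))
  fm16 <- build_feature_matrix(co, c(6, 1))
  expect_equal(ncol(fm16$x), 9L)
  # sets 3-5 are unavailable on the clinical table alone
  expect_error(build_feature_matrix(co, 3), "disability",
               class = "msrehab_feature_error")
  expect_error(build_feature_matrix(co, 4), class = "msrehab_feature_error")
  expect_error(build_feature_matrix(co, 5), class = "msrehab_feature_error")
  expect_error(build_feature_matrix(co, integer(0)),
               class = "msrehab_feature_error")
})

test_that("LOSO folds partition datasets by participant", {
  folds <- loso_folds(co$participant_id)
  expect_length(folds, 11L)
  sizes <- sort(vapply(folds, function(f) length(f$test), integer(1)))
  expect_equal(sizes, c(1L, 1L, rep(2L, 9L)))
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(all_test, 1:20)            # folds cover every dataset once
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_false(f$participant %in% co$participant_id[f$train])
  }
  expect_error(loso_folds(rep("a", 4)), class = "msrehab_cv_error")
  two <- loso_folds(c("a", "b"))
  expect_equal(vapply(two, function(f) length(f$test), integer(1)), c(1L, 1L))
})

test_that("model families separate a linearly separable cohort and fall back on single-class folds", {
  set.seed(1)
  x <- matrix(rnorm(60 * 2), ncol = 2)
  y <- x[, 1] > 0
  x[, 1] <- x[, 1] + ifelse(y, 2, -2)
  tr <- 1:40; te <- 41:60
  for (fam in c("linreg", "tree", "knn", "rf")) {
    pred <- fit_predict(fam, x[tr, ], y[tr], x[te, ], seed = 17)
    expect_equal(pred, y[te], ignore_attr = TRUE)
  }
  # single-class training fold: constant prediction of that class
  for (fam in c("linreg", "tree", "knn", "rf")) {
    expect_true(all(fit_predict(fam, x[tr, ], rep(TRUE, 40), x[te, ])))
    expect_false(any(fit_predict(fam, x[tr, ], rep(FALSE, 40), x[te, ])))
  }
  expect_error(fit_predict("linreg", x[0, , drop = FALSE], logical(0),
                           x[te, ]), class = "msrehab_cv_error")
})

test_that("rounded linear regression thresholds fitted values at 0.5", {
  # balanced two-point design: OLS fitted value equals the feature value,
  # so test points 0.49 / 0.51 straddle the rounding threshold exactly
  x_tr <- matrix(c(rep(0, 5), rep(1, 5)))
  y_tr <- x_tr[, 1] == 1
  pred <- fit_predict("linreg", x_tr, y_tr, matrix(c(0.49, 0.51)))
  expect_equal(pred, c(FALSE, TRUE))
})

test_that("evaluation agrees with a brute-force confusion counter", {
  perf <- evaluate_predictions(c(rep(TRUE, 6), rep(FALSE, 14)),
                               c(rep(TRUE, 6), rep(TRUE, 3), rep(FALSE, 11)))
  expect_equal(perf$sensitivity, 1)
  expect_equal(round(100 * perf$specificity, 1), 78.6)
  expect_equal(round(100 * perf$balanced_accuracy, 1), 89.3)
  expect_equal(round(100 * perf$precision, 1), 66.7)
  perfect <- evaluate_predictions(lab$arat_improved, lab$arat_improved)
  expect_equal(perfect$balanced_accuracy, 1)
  allneg <- evaluate_predictions(c(TRUE, TRUE, FALSE, FALSE),
                                 rep(FALSE, 4))
  expect_equal(allneg$balanced_accuracy, 0.5)
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    truth <- runif(n) < runif(1, 0.2, 0.8)
    if (!any(truth) || all(truth)) next
    pred <- runif(n) < 0.5
    got <- suppressWarnings(evaluate_predictions(truth, pred))
    want <- brute_confusion(truth, pred)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fn, want$fn)
    expect_equal(got$specificity, want$spec)
    if (!is.nan(want$ba)) expect_equal(got$balanced_accuracy, want$ba)
  }
  expect_warning(evaluate_predictions(rep(FALSE, 5), rep(FALSE, 5)),
                 class = "msrehab_degenerate_evaluation")
})

test_that("the prediction grid reproduces the published best models", {
  g <- run_grid(co, lab, feature_sets = list(1, c(1, 6)),
                models = c("linreg", "tree"),
                outcomes = c("arat", "bbt"))
  ba <- function(o, f, m) g$balanced_accuracy[g$outcome == o &
                                                g$feature_set == f &
                                                g$model == m]
  expect_equal(round(ba("arat", "1+6", "linreg")), 89)
  expect_equal(round(ba("bbt", "1", "tree")), 83)
  expect_equal(g$sensitivity[g$outcome == "arat" & g$feature_set == "1+6" &
                               g$model == "linreg"], 100)
  expect_equal(g$precision[g$outcome == "bbt" & g$feature_set == "1" &
                             g$model == "tree"], 100)
  # balanced-accuracy identity holds for every emitted summary
  ok <- g[g$status == "ok", ]
  expect_equal(ok$balanced_accuracy,
               (ok$sensitivity + ok$specificity) / 2)
  expect_equal(ok$tp + ok$fp + ok$tn + ok$fn, rep(20L, nrow(ok)))
  # repeated runs with the same seed are identical
  g2 <- run_grid(co, lab, feature_sets = list(1, c(1, 6)),
                 models = c("linreg", "tree"),
                 outcomes = c("arat", "bbt"))
  expect_identical(as.data.frame(g), as.data.frame(g2))
})

test_that("unavailable feature sets are recorded as skipped, not errors", {
  g <- run_grid(co, lab, feature_sets = list(1, 3, 5),
                models = "tree", outcomes = "arat")
  expect_equal(sum(g$status == "ok"), 1L)
  expect_equal(sum(g$status == "skipped: features unavailable"), 2L)
  expect_true(all(is.na(g$balanced_accuracy[g$status != "ok"])))
})

test_that("the non-responder check looks up per-configuration correctness", {
  g <- run_grid(co, lab, feature_sets = list(1), models = "tree")
  chk <- nonresponder_check(g, "02_right")
  expect_equal(nrow(chk), 3L)  # one per outcome
  expect_type(chk$correct, "logical")
  # agreement with the grid's own flag
  expect_equal(chk$correct[chk$outcome == "bbt"],
               g$nonresponder_correct[g$outcome == "bbt"])
  expect_error(nonresponder_check(g, "99_left"),
               class = "msrehab_lookup_error")
})

test_that("gain correlations reproduce the published coefficients", {
  ca <- correlate_gains(co, "chronicity", "arat")
  expect_equal(round(ca$r, 2), 0.58)
  expect_lt(ca$p, 0.05)
  cb <- correlate_gains(co, "age", "bbt")
  expect_equal(round(cb$r, 2), -0.52)
  # a covariate duplicated as the gain correlates perfectly
  fake <- as.data.frame(co)
  fake$bbt_pre <- 0
  fake$bbt_post <- fake$age
  expect_equal(correlate_gains(ms_cohort(fake), "age", "bbt")$r, 1)
  const <- as.data.frame(co)
  const$age <- 50
  expect_error(correlate_gains(ms_cohort(const), "age", "bbt"),
               class = "msrehab_validation_error")
})
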