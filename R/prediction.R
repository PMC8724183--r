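# Feature-set construction, grouped leave-one-subject-out cross-validation,
# the four model families, and the performance grid.

.feature_set_names <- c("1" = "patient master data",
                        "2" = "intervention group",
                        "3" = "disability",
                        "4" = "conventional body-function scales",
                        "5" = "digital health metrics",
                        "6" = "pre-intervention activity scales")

onehot <- function(x, levels, prefix) {
  m <- vapply(levels, function(l) as.numeric(x == l), numeric(length(x)))
  colnames(m) <- paste0(prefix, "_", levels)
  m
}

#' Build the numeric feature matrix for one or more feature sets
#'
#' Feature sets follow the study's nomenclature: (1) patient master data
#' (age, chronicity, sex, MS type), (2) intervention group, (3) disability
#' (EDSS and the disability group used for block randomization), (4)
#' conventional body-function scales (Motricity Index, Static Fatigue
#' Index, monofilament index, SDMT, Fahn tremor score), (5) the ten
#' normalized digital health metrics, (6) pre-intervention activity scores
#' (ARAT, BBT, NHPT). Encodings: sex as 0/1 (M = 1); MS type and
#' intervention group one-hot.
#'
#' Sets 3 and 4 need optional cohort columns and set 5 a metric table;
#' when a requested field is entirely absent a condition of class
#' `msrehab_feature_error` is signalled naming the set.
#'
#' @param cohort an `ms_cohort`.
#' @param sets integer vector, subset of 1:6.
#' @param metrics optional data.frame with `dataset_id` plus the ten
#'   normalized metric columns (as produced by [normalize_metrics()] /
#'   [write_metric_table()] conventions).
#' @return List with `x` (numeric matrix, one row per dataset in cohort
#'   order) and `dataset_id`.
#' @export
build_feature_matrix <- function(cohort, sets, metrics = NULL) {
  stopifnot(inherits(cohort, "ms_cohort"))
  sets <- sort(unique(as.integer(sets)))
  if (length(sets) == 0L || !all(sets %in% 1:6)) {
    msr_error("feature sets must be a non-empty subset of 1..6",
              "msrehab_feature_error")
  }
  need <- function(cols, set) {
    missing <- setdiff(cols, names(cohort))
    miss_val <- cols[cols %in% names(cohort) &
                       vapply(cols[cols %in% names(cohort)],
                              function(cc) all(is.na(cohort[[cc]])),
                              logical(1))]
    bad <- union(missing, miss_val)
    if (length(bad) > 0L) {
      msr_error(sprintf(
        "feature set %d (%s) unavailable: missing field(s) %s",
        set, .feature_set_names[[as.character(set)]],
        paste(bad, collapse = ", ")), "msrehab_feature_error")
    }
  }
  blocks <- lapply(sets, function(s) {
    switch(as.character(s),
      "1" = cbind(age = cohort$age, chronicity = cohort$chronicity,
                  sex = as.numeric(cohort$sex == "M"),
                  onehot(cohort$ms_type, c("RR", "PP", "SP"), "ms")),
      "2" = onehot(cohort$intervention_group, 1:3, "group"),
      "3" = {
        need(c("disability_group"), 3L)
        cbind(edss = cohort$edss,
              disability_group = as.numeric(cohort$disability_group))
      },
      "4" = {
        cols <- c("motricity", "static_fatigue_index",
                  "monofilament_index", "sdmt", "fahn_tremor")
        need(cols, 4L)
        as.matrix(cohort[, cols, drop = FALSE])
      },
      "5" = {
        if (is.null(metrics)) {
          msr_error("feature set 5 (digital health metrics) unavailable: no metric table supplied",
                    "msrehab_feature_error")
        }
        mcols <- intersect(vpit_metric_names(), names(metrics))
        if (length(mcols) < length(vpit_metric_names())) {
          msr_error(sprintf("feature set 5 unavailable: metric table lacks %s",
                            paste(setdiff(vpit_metric_names(), mcols),
                                  collapse = ", ")),
                    "msrehab_feature_error")
        }
        idx <- match(cohort$dataset_id, metrics$dataset_id)
        if (anyNA(idx)) {
          msr_error("feature set 5 unavailable: metric table misses datasets",
                    "msrehab_feature_error")
        }
        as.matrix(metrics[idx, vpit_metric_names(), drop = FALSE])
      },
      "6" = cbind(arat_pre = cohort$arat_pre, bbt_pre = cohort$bbt_pre,
                  nhpt_pre = cohort$nhpt_pre))
  })
  x <- do.call(cbind, blocks)
  rownames(x) <- cohort$dataset_id
  list(x = x, dataset_id = cohort$dataset_id)
}

#' Leave-one-subject-out folds grouped by participant
#'
#' One fold per participant; the test fold contains every dataset (both
#' body sides) of that participant, so no participant ever contributes to
#' both sides of a split.
#'
#' @param participant_id character vector, one entry per dataset.
#' @return List of folds, each `list(participant, train, test)` with
#'   integer row indices.
#' @export
loso_folds <- function(participant_id) {
  participant_id <- as.character(participant_id)
  ids <- unique(participant_id)
  if (length(ids) < 2L) {
    msr_error("leave-one-subject-out needs at least 2 participants",
              "msrehab_cv_error")
  }
  lapply(ids, function(p) {
    test <- which(participant_id == p)
    list(participant = p, train = setdiff(seq_along(participant_id), test),
         test = test)
  })
}

# z-score columns by training statistics; zero-variance columns are set
# to 0 in both splits so they carry no distance information.
zscore_fold <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2L, sd)
  zero <- !is.finite(sdv) | sdv == 0
  sdv[zero] <- 1
  tr <- sweep(sweep(x_train, 2L, mu), 2L, sdv, "/")
  te <- sweep(sweep(x_test, 2L, mu), 2L, sdv, "/")
  tr[, zero] <- 0
  te[, zero] <- 0
  list(train = tr, test = te)
}

#' Fit one model family on a training fold and predict the test fold
#'
#' Families use fixed standard settings: `linreg` is ordinary least
#' squares on the 0/1 labels with the fitted value thresholded at 0.5;
#' `tree` is CART (Gini, grown without depth limit, minimum leaf size 1);
#' `knn` is k-nearest neighbours on within-fold z-scored features with
#' k = 3 and distance ties broken by smallest training index; `rf` is a
#' random forest with 100 trees and sqrt(p) candidate features per split.
#' A single-class training fold yields a constant prediction of that
#' class for every family.
#'
#' @param family `"linreg"`, `"tree"`, `"knn"` or `"rf"`.
#' @param x_train,x_test numeric feature matrices.
#' @param y_train logical (TRUE = considerable improvement).
#' @param seed integer seed for the stochastic families (forest bootstrap).
#' @param k neighbours for `knn`.
#' @param ntree forest size for `rf`.
#' @return Logical predictions, one per test row.
#' @export
fit_predict <- function(family = c("linreg", "tree", "knn", "rf"),
                        x_train, y_train, x_test, seed = 17L,
                        k = 3L, ntree = 100L) {
  family <- match.arg(family)
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  y_train <- as.logical(y_train)
  if (nrow(x_train) == 0L) {
    msr_error("empty training set", "msrehab_cv_error")
  }
  if (length(unique(y_train)) == 1L) {
    return(rep(y_train[1L], nrow(x_test)))
  }
  switch(family,
    linreg = {
      z <- zscore_fold(x_train, x_test)
      beta <- qr.coef(qr(cbind(1, z$train)), as.numeric(y_train))
      beta[is.na(beta)] <- 0
      drop(cbind(1, z$test) %*% beta) >= 0.5
    },
    tree = {
      df <- data.frame(z = x_train)
      df$.y <- factor(y_train, levels = c(FALSE, TRUE))
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = "gini"),
                          control = rpart::rpart.control(
                            minsplit = 2L, minbucket = 1L, cp = 0,
                            xval = 0L, maxcompete = 0L, maxsurrogate = 0L))
      predict(fit, data.frame(z = x_test), type = "class") == "TRUE"
    },
    knn = {
      z <- zscore_fold(x_train, x_test)
      kk <- min(k, nrow(z$train))
      apply(z$test, 1L, function(q) {
        d <- sqrt(colSums((t(z$train) - q)^2))
        nb <- order(d)[seq_len(kk)]  # order() is stable: smallest index wins ties
        votes <- sum(y_train[nb])
        if (2 * votes == kk) y_train[nb[1L]] else votes > kk / 2
      })
    },
    rf = {
      set.seed(seed)
      fit <- randomForest::randomForest(
        x = x_train, y = factor(y_train, levels = c(FALSE, TRUE)),
        ntree = ntree, mtry = max(1L, floor(sqrt(ncol(x_train)))))
      predict(fit, x_test) == "TRUE"
    })
}

#' Confusion counts and performance rates of binary predictions
#'
#' Positive class is "considerable improvement". Computes TP/FP/TN/FN,
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP)
#' and balanced accuracy (sensitivity + specificity)/2, all as fractions.
#' When the truth contains no positives (or no negatives) the undefined
#' rate is `NA` with a warning and the balanced accuracy is computed from
#' the defined part only; precision is `NA` when nothing is predicted
#' positive.
#'
#' @param truth,predictions logical vectors of equal, nonzero length.
#' @return List of class `performance_summary`.
#' @export
evaluate_predictions <- function(truth, predictions) {
  truth <- as.logical(truth)
  predictions <- as.logical(predictions)
  if (length(truth) == 0L || length(truth) != length(predictions)) {
    msr_error("truth and predictions must be equal-length and non-empty",
              "msrehab_validation_error")
  }
  tp <- sum(predictions & truth)
  fp <- sum(predictions & !truth)
  tn <- sum(!predictions & !truth)
  fn <- sum(!predictions & truth)
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  if (is.na(sens) || is.na(spec)) {
    msr_warn("one class absent from truth; balanced accuracy uses the defined rate only",
             "msrehab_degenerate_evaluation")
  }
  ba <- mean(c(sens, spec), na.rm = TRUE)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 precision = prec, balanced_accuracy = ba),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("BA %.1f%%  sens %.1f%%  spec %.1f%%  prec %.1f%%  (TP %d FP %d TN %d FN %d)\n",
              100 * x$balanced_accuracy, 100 * x$sensitivity,
              100 * x$specificity, 100 * x$precision,
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

loso_predict <- function(x, y, participant_id, family, seed = 17L, ...) {
  folds <- loso_folds(participant_id)
  pred <- logical(length(y))
  for (f in folds) {
    pred[f$test] <- fit_predict(family, x[f$train, , drop = FALSE],
                                y[f$train], x[f$test, , drop = FALSE],
                                seed = seed, ...)
  }
  pred
}

#' Run the full feature-set-by-model prediction grid
#'
#' For every combination of outcome scale, feature set and model family:
#' build the features, obtain one leave-one-subject-out prediction per
#' dataset, and summarize performance plus whether the designated
#' unexpected non-responder dataset was predicted correctly.
#' Configurations whose features are unavailable (sets 3-5 without the
#' needed columns/tables) are recorded as skipped rather than failing the
#' run.
#'
#' @param cohort an `ms_cohort`.
#' @param labels `responder_labels` from [label_cohort()].
#' @param feature_sets list of integer vectors, e.g. `list(1, c(1, 6))`.
#' @param models character subset of `c("linreg","tree","knn","rf")`.
#' @param outcomes character subset of `c("arat","bbt","nhpt")`.
#' @param metrics optional normalized metric table (for set 5).
#' @param seed integer seed for stochastic families.
#' @param nonresponder `c(participant_id, side)` of the designated
#'   unexpected non-responder dataset.
#' @return A data.frame of class `grid_result`, one row per
#'   configuration, with percentage performance columns, confusion
#'   counts, `nonresponder_correct` and `status`; per-dataset predictions
#'   are attached as attribute `"predictions"`.
#' @export
run_grid <- function(cohort, labels,
                     feature_sets = list(1, 2, 6, c(1, 2), c(1, 6)),
                     models = c("linreg", "tree", "knn", "rf"),
                     outcomes = c("arat", "bbt", "nhpt"),
                     metrics = NULL, seed = 17L,
                     nonresponder = c("02", "right")) {
  stopifnot(inherits(cohort, "ms_cohort"),
            inherits(labels, "responder_labels"))
  models <- match.arg(models, several.ok = TRUE)
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  idx <- match(cohort$dataset_id, labels$dataset_id)
  if (anyNA(idx)) {
    msr_error("labels do not cover every dataset of the cohort",
              "msrehab_validation_error")
  }
  labels <- labels[idx, , drop = FALSE]
  nr_id <- paste(nonresponder[1L], nonresponder[2L], sep = "_")
  rows <- list()
  preds <- list()
  for (fs in feature_sets) {
    fs_tag <- paste(sort(unique(as.integer(fs))), collapse = "+")
    fm <- tryCatch(build_feature_matrix(cohort, fs, metrics),
                   msrehab_feature_error = function(e) e)
    for (outc in outcomes) {
      y <- labels[[paste0(outc, "_improved")]]
      for (mod in models) {
        if (inherits(fm, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            outcome = outc, feature_set = fs_tag, model = mod,
            balanced_accuracy = NA_real_, sensitivity = NA_real_,
            specificity = NA_real_, precision = NA_real_,
            tp = NA_integer_, fp = NA_integer_, tn = NA_integer_,
            fn = NA_integer_, nonresponder_correct = NA,
            status = "skipped: features unavailable",
            stringsAsFactors = FALSE)
          next
        }
        pred <- loso_predict(fm$x, y, cohort$participant_id, mod,
                             seed = seed)
        perf <- evaluate_predictions(y, pred)
        nr_ok <- if (nr_id %in% cohort$dataset_id) {
          i <- match(nr_id, cohort$dataset_id)
          pred[i] == y[i]
        } else NA
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = outc, feature_set = fs_tag, model = mod,
          balanced_accuracy = 100 * perf$balanced_accuracy,
          sensitivity = 100 * perf$sensitivity,
          specificity = 100 * perf$specificity,
          precision = 100 * perf$precision,
          tp = perf$tp, fp = perf$fp, tn = perf$tn, fn = perf$fn,
          nonresponder_correct = nr_ok, status = "ok",
          stringsAsFactors = FALSE)
        preds[[length(preds) + 1L]] <- data.frame(
          outcome = outc, feature_set = fs_tag, model = mod,
          dataset_id = cohort$dataset_id, truth = y, prediction = pred,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "predictions") <- do.call(rbind, preds)
  attr(out, "seed") <- seed
  attr(out, "nonresponder") <- nr_id
  attr(out, "hyperparameters") <-
    "linreg: OLS on 0/1 labels, threshold 0.5; tree: CART gini minsplit=2 minbucket=1 cp=0; knn: k=3 z-scored; rf: ntree=100 mtry=floor(sqrt(p))"
  class(out) <- c("grid_result", "data.frame")
  out
}

#' Was a given dataset predicted correctly in every grid configuration?
#'
#' Looks up the leave-one-subject-out prediction of one dataset (by
#' default the designated unexpected non-responder) in each evaluated
#' configuration of a grid result.
#'
#' @param grid a `grid_result` from [run_grid()].
#' @param dataset_id dataset identifier `participant_side`.
#' @return data.frame with one row per evaluated configuration and a
#'   logical `correct` column.
#' @export
nonresponder_check <- function(grid, dataset_id) {
  stopifnot(inherits(grid, "grid_result"))
  preds <- attr(grid, "predictions")
  if (!dataset_id %in% preds$dataset_id) {
    msr_error(sprintf("unknown dataset id: %s", dataset_id),
              "msrehab_lookup_error")
  }
  p <- preds[preds$dataset_id == dataset_id, , drop = FALSE]
  data.frame(outcome = p$outcome, feature_set = p$feature_set,
             model = p$model, correct = p$prediction == p$truth,
             stringsAsFactors = FALSE)
}

#' Correlate a pre-intervention covariate with the raw score gain
#'
#' Pearson correlation between a cohort covariate (e.g. chronicity or
#' age) and the raw signed change of a scale across the intervention:
#' post - pre for ARAT and BBT ("gains"), pre - post for NHPT (time
#' reduction).
#'
#' @param cohort an `ms_cohort` with at least 3 datasets.
#' @param covariate name of a numeric cohort column.
#' @param scale `"arat"`, `"bbt"` or `"nhpt"`.
#' @return List with `r`, `p`, `n`.
#' @export
correlate_gains <- function(cohort, covariate,
                            scale = c("arat", "bbt", "nhpt")) {
  scale <- match.arg(scale)
  stopifnot(inherits(cohort, "ms_cohort"))
  if (nrow(cohort) < 3L) {
    msr_error("need at least 3 datasets for a correlation",
              "msrehab_validation_error")
  }
  x <- cohort[[covariate]]
  if (is.null(x) || !is.numeric(x)) {
    msr_error(sprintf("unknown or non-numeric covariate: %s", covariate),
              "msrehab_validation_error")
  }
  gain <- improvement_change(cohort[[paste0(scale, "_pre")]],
                             cohort[[paste0(scale, "_post")]], scale)
  if (sd(x) == 0 || sd(gain) == 0) {
    msr_error("zero variance: correlation undefined",
              "msrehab_validation_error")
  }
  ct <- cor.test(x, gain, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(cohort))
}
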