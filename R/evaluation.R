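# Metrics, stratified cross-validation, and the five-method comparison.

#' Classification accuracy
#'
#' @param truth,predicted Equal-length label vectors.
#' @return Proportion of correct predictions.
#' @export
accuracy <- function(truth, predicted) {
  if (!length(truth)) stopf("cannot compute accuracy of zero predictions")
  if (length(truth) != length(predicted)) stopf("label vectors differ in length")
  mean(as.character(truth) == as.character(predicted))
}

#' 3x3 confusion matrix (rows = truth, columns = predicted)
#'
#' @param truth,predicted Label vectors over [stress_levels()].
#' @param classes Class order.
#' @return Integer matrix of counts.
#' @export
confusion_matrix <- function(truth, predicted, classes = stress_levels()) {
  t <- factor(as.character(truth), levels = classes)
  p <- factor(as.character(predicted), levels = classes)
  as.matrix(table(truth = t, predicted = p))
}

#' Per-class recall, precision and F1 from a confusion matrix
#'
#' `recall = TP / row sum`, `precision = TP / column sum`,
#' `F1 = 2 R P / (R + P)`. When a class has `R + P = 0` (or an undefined
#' recall/precision from an empty margin) its F1 is 0 by convention.
#'
#' @param confusion Square count matrix, rows = truth, columns = predicted.
#' @return Data frame with columns `class`, `support`, `recall`,
#'   `precision`, `f1`.
#' @export
f1_per_class <- function(confusion) {
  cm <- as.matrix(confusion)
  classes <- rownames(cm)
  tp <- diag(cm)
  recall <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  precision <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  f1 <- ifelse(recall + precision > 0,
               2 * recall * precision / (recall + precision), 0)
  data.frame(class = classes, support = as.integer(rowSums(cm)),
             recall = as.numeric(recall), precision = as.numeric(precision),
             f1 = as.numeric(f1), row.names = NULL)
}

#' @noRd
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(droplevels(y))) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the stress ensemble
#'
#' Folds are stratified by class and seeded. Within each fold, imputation
#' and all resampling happen on the training part only; out-of-fold
#' predictions are pooled and scored.
#'
#' @param x Feature matrix (may contain `NA`).
#' @param y Stress labels.
#' @param k Number of folds.
#' @param scheme Data-processing scheme (see [stress_ensemble()]).
#' @param config A [resampling_config()].
#' @param split_seed Seed of the fold split.
#' @return Object of class `stress_cv`: accuracy, per-class metrics,
#'   confusion matrix, fold assignment and pooled predictions.
#' @export
cross_validate <- function(x, y, k = 3, scheme = "over_under_bagging",
                           config = resampling_config(), split_seed = 0) {
  x <- as.matrix(x)
  y <- if (is.factor(y)) factor(as.character(y), levels = stress_levels())
       else factor(y, levels = stress_levels())
  counts <- table(droplevels(y))
  if (any(counts < k))
    stopf("need >= k rows per class (got %s)",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  fold <- stratified_folds(y, k, split_seed)
  for (f in seq_len(k)) {
    tr <- table(droplevels(y[fold != f]))
    if (any(tr == 0))
      stopf("class '%s' absent from the training part of fold %d; use a different split seed or more data",
            names(tr)[which(tr == 0)[1L]], f)
  }
  pred <- factor(rep(NA_character_, length(y)), levels = stress_levels())
  for (f in seq_len(k)) {
    fit <- stress_ensemble(x[fold != f, , drop = FALSE], y[fold != f],
                           scheme = scheme, config = config)
    pred[fold == f] <- predict(fit, x[fold == f, , drop = FALSE])
  }
  cm <- confusion_matrix(y, pred)
  out <- list(accuracy = accuracy(y, pred), per_class = f1_per_class(cm),
              confusion = cm, k = k, scheme = scheme, split_seed = split_seed,
              fold = fold, truth = y, predicted = pred)
  class(out) <- "stress_cv"
  out
}

#' @export
print.stress_cv <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV (%s): accuracy %.3f on %d rows\n",
              x$k, x$scheme, x$accuracy, length(x$truth)))
  print(x$per_class, digits = 3)
  invisible(x)
}

#' Majority-class rate of a label vector
#'
#' The accuracy of always predicting the most frequent class; the chance
#' reference for the classifiers.
#' @param y Label vector.
#' @return Proportion of the most frequent class.
#' @export
majority_class_rate <- function(y) {
  max(table(y)) / length(y)
}

#' Evaluate one method variant on one question
#'
#' Builds the variant's features for the cohort, maps the Likert answers of
#' the requested question to stress classes, and cross-validates.
#'
#' @param cohort A `stress_cohort`.
#' @param variant Method variant name.
#' @param question `"MQ"` or `"NQ"`.
#' @param features Optional precomputed `stress_features` for the
#'   `proposed2`/full profile; its manifest is subset to `variant` (used by
#'   [compare_methods()] to share one feature build).
#' @inheritParams cross_validate
#' @return A `stress_cv`.
#' @export
evaluate_question <- function(cohort, variant = "proposed2", question = "NQ",
                              k = 3, scheme = "over_under_bagging",
                              config = resampling_config(), split_seed = 0,
                              features = NULL) {
  if (is.null(features)) features <- build_dataset(cohort, variant)
  man <- attr(features, "manifest")
  wanted <- feature_manifest(variant, man$activities, man$profile)
  if (!all(wanted %in% man$features))
    stopf("precomputed features lack columns of variant '%s'", variant)
  sub <- features[features$question == question, , drop = FALSE]
  x <- as.matrix(sub[, wanted, drop = FALSE])
  y <- map_likert(sub$answer, sub$question)
  cross_validate(x, y, k = k, scheme = scheme, config = config,
                 split_seed = split_seed)
}

#' Compare the five method variants on a cohort
#'
#' Builds the richest feature set once, then cross-validates every variant
#' on both questions with identical fold splits (the split depends only on
#' the labels and the seed, which the variants share).
#'
#' @param cohort A `stress_cohort`.
#' @param variants Method variant names, in comparison order.
#' @param questions Questions to score.
#' @inheritParams cross_validate
#' @return Object of class `stress_comparison`: accuracy table (rows MQ, NQ,
#'   Mean; one column per variant) plus per-variant `stress_cv` details.
#' @export
compare_methods <- function(cohort,
                            variants = c("baseline1", "baseline2", "previous",
                                         "proposed1", "proposed2"),
                            questions = c("MQ", "NQ"), k = 3,
                            scheme = "over_under_bagging",
                            config = resampling_config(), split_seed = 0) {
  features <- build_dataset(cohort, "proposed2")
  acc <- matrix(NA_real_, length(questions) + 1L, length(variants),
                dimnames = list(c(questions, "Mean"), variants))
  details <- list()
  for (v in variants) {
    for (q in questions) {
      cv <- evaluate_question(cohort, v, q, k = k, scheme = scheme,
                              config = config, split_seed = split_seed,
                              features = features)
      acc[q, v] <- cv$accuracy
      details[[paste(v, q, sep = ".")]] <- cv
    }
    acc["Mean", v] <- mean(acc[questions, v])
  }
  out <- list(accuracy = acc, details = details, questions = questions,
              scheme = scheme, k = k, split_seed = split_seed)
  class(out) <- "stress_comparison"
  out
}

#' @export
print.stress_comparison <- function(x, ...) {
  cat(sprintf("Five-method comparison (%s, %d-fold CV)\n", x$scheme, x$k))
  rn <- rownames(x$accuracy)
  rn[rn == "MQ"] <- "MQ: Morning physical stress"
  rn[rn == "NQ"] <- "NQ: Nighttime physical stress"
  tab <- round(x$accuracy, 2)
  rownames(tab) <- rn
  print(tab)
  invisible(x)
}

#' Write a comparison report to CSV files
#'
#' Emits the accuracy table and, per variant and question, the per-class
#' metrics and confusion matrix.
#'
#' @param comparison A `stress_comparison`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(row = rownames(comparison$accuracy),
                              comparison$accuracy, check.names = FALSE),
                   file.path(dir, "accuracy.csv"), row.names = FALSE)
  for (nm in names(comparison$details)) {
    cv <- comparison$details[[nm]]
    utils::write.csv(cv$per_class, file.path(dir, paste0("metrics_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cv$confusion),
                     file.path(dir, paste0("confusion_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
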