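# Likert-to-class mapping and the imbalance-aware bagged random-forest
# ensemble. The fitting function follows the classic R modelling idiom:
# `stress_ensemble()` returns a classed object with print, summary and
# predict methods.

#' The three stress classes, in voting-priority order
#'
#' Ties in the ensemble majority vote resolve toward the earlier class:
#' `bad` over `neutral` over `good`. Early detection of deteriorating
#' physical condition is the clinical goal, so ties go to the costly class.
#' @return `c("bad", "neutral", "good")`.
#' @export
stress_levels <- function() c("bad", "neutral", "good")

#' Default Likert-answer mapping to the three stress classes
#'
#' The morning question asks whether the resident feels physically refreshed
#' (high answer = good); the night question asks whether physical stress is
#' felt (high answer = bad). Cut points: the two low answers, the midpoint,
#' and the two high answers.
#'
#' @return List with integer-indexed class vectors for `MQ` and `NQ`.
#' @export
likert_mapping <- function() {
  list(MQ = c("bad", "bad", "neutral", "good", "good"),
       NQ = c("good", "good", "neutral", "bad", "bad"))
}

#' Map 5-point Likert answers to stress classes
#'
#' @param answer Integer vector of answers in 1..5.
#' @param question Question id(s), `"MQ"` or `"NQ"` (recycled if scalar).
#' @param mapping A mapping as returned by [likert_mapping()].
#' @return Factor with levels [stress_levels()].
#' @export
map_likert <- function(answer, question, mapping = likert_mapping()) {
  if (any(!answer %in% 1:5)) stopf("answers must be integers in 1..5")
  question <- rep_len(as.character(question), length(answer))
  bad_q <- setdiff(unique(question), names(mapping))
  if (length(bad_q)) stopf("no mapping for question(s): %s", paste(bad_q, collapse = ", "))
  lab <- vapply(seq_along(answer), function(i) mapping[[question[i]]][answer[i]], "")
  factor(lab, levels = stress_levels())
}

#' Resampling configuration of the ensemble
#'
#' Defaults follow the published pipeline: SMOTE to per-class targets
#' bad 100, neutral 100, good 200 with `k = 3` neighbours under a fixed
#' random state 0; ten bagged members whose undersampler seeds run 1..10
#' with replacement.
#'
#' @param smote_targets Named post-oversampling counts per class.
#' @param smote_k SMOTE nearest-neighbour count.
#' @param smote_seed SMOTE random state.
#' @param under_seeds Integer seeds of the bagged undersample members; their
#'   number is the bag size.
#' @param under_replace Undersample with replacement.
#' @return List of class `resampling_config`.
#' @export
resampling_config <- function(smote_targets = c(bad = 100, neutral = 100, good = 200),
                              smote_k = 3, smote_seed = 0,
                              under_seeds = 1:10, under_replace = TRUE) {
  if (any(smote_targets <= 0)) stopf("smote_targets must be positive")
  structure(list(smote_targets = smote_targets, smote_k = smote_k,
                 smote_seed = smote_seed, under_seeds = under_seeds,
                 under_replace = under_replace),
            class = "resampling_config")
}

#' @noRd
impute_fit <- function(x) {
  med <- apply(x, 2L, function(col) {
    m <- stats::median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  })
  med
}

#' @noRd
impute_apply <- function(x, medians) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- medians[j]
  }
  x
}

#' Fit the imbalance-aware stress classification ensemble
#'
#' Five data-processing schemes are supported, composing SMOTE
#' oversampling, seeded random undersampling with replacement, and bagging
#' around random forests with library-default hyperparameters:
#' \describe{
#'   \item{`not_manipulated`}{a single forest on the training data as-is.}
#'   \item{`oversampler`}{SMOTE to the configured targets, single forest.}
#'   \item{`undersampler`}{balanced undersample (first seed), single forest.}
#'   \item{`under_bagging`}{one forest per undersampler seed, majority vote.}
#'   \item{`over_under_bagging`}{(default) SMOTE once under its fixed random
#'     state, then one forest per undersampler seed on a balanced
#'     with-replacement undersample of the oversampled data; per-row majority
#'     vote across the ten members.}
#' }
#' Missing feature values are imputed with per-column training medians,
#' stored in the model so prediction uses the same imputation. All
#' randomness is governed by the seeds in `config`; refitting with identical
#' inputs reproduces the model exactly.
#'
#' @param x Numeric feature matrix or data frame (may contain `NA`).
#' @param y Stress labels: factor with levels [stress_levels()] or a
#'   character vector of them.
#' @param scheme Data-processing scheme (see above).
#' @param config A [resampling_config()].
#' @return Object of class `stress_ensemble` with elements `members` (list
#'   of (seed, forest)), `scheme`, `config`, `classes`, `feature_names`,
#'   `medians`.
#' @export
stress_ensemble <- function(x, y,
                            scheme = c("over_under_bagging", "not_manipulated",
                                       "oversampler", "undersampler", "under_bagging"),
                            config = resampling_config()) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- if (is.factor(y)) factor(as.character(y), levels = stress_levels())
       else factor(y, levels = stress_levels())
  if (anyNA(y)) stopf("labels outside %s", paste(stress_levels(), collapse = "/"))
  if (nrow(x) != length(y)) stopf("x and y sizes differ")
  if (length(unique(y)) < 2L) stopf("training data contain a single class")
  medians <- impute_fit(x)
  xi <- impute_apply(x, medians)

  over <- function() with_seed(config$smote_seed,
                               smote(xi, y, config$smote_targets, config$smote_k))
  fit_rf <- function(xx, yy) randomForest::randomForest(xx, droplevels(yy))
  member <- function(seed, xx, yy, under) with_seed(seed, {
    if (under) {
      u <- random_undersample(xx, yy, replace = config$under_replace)
      xx <- u$x; yy <- u$y
    }
    list(seed = seed, forest = fit_rf(xx, yy))
  })

  members <- switch(
    scheme,
    not_manipulated = list(member(0L, xi, y, under = FALSE)),
    oversampler = { o <- over(); list(member(0L, o$x, o$y, under = FALSE)) },
    undersampler = list(member(config$under_seeds[1L], xi, y, under = TRUE)),
    under_bagging = lapply(config$under_seeds, member, xx = xi, yy = y, under = TRUE),
    over_under_bagging = {
      o <- over()
      lapply(config$under_seeds, member, xx = o$x, yy = o$y, under = TRUE)
    })

  out <- list(members = members, scheme = scheme, config = config,
              classes = stress_levels(), feature_names = colnames(x),
              medians = medians, n_train = nrow(x),
              class_counts = table(y))
  class(out) <- "stress_ensemble"
  out
}

#' Predict stress classes with a fitted ensemble
#'
#' Each member votes for the class its forest's trees favour; the plurality
#' class over members wins. Ties — both among a member's trees and among
#' members — resolve by the fixed priority bad > neutral > good, making
#' prediction fully deterministic.
#'
#' @param object A `stress_ensemble`.
#' @param newdata Feature matrix or data frame whose column names must match
#'   the training manifest exactly.
#' @param type `"class"` for labels, `"votes"` for the member vote-count
#'   matrix.
#' @param ... Unused.
#' @return Factor of predicted labels, or an integer vote matrix.
#' @export
predict.stress_ensemble <- function(object, newdata, type = c("class", "votes"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  missing_f <- setdiff(object$feature_names, colnames(x))
  extra_f <- setdiff(colnames(x), object$feature_names)
  if (length(missing_f) || length(extra_f))
    stopf("feature names do not match the model manifest (missing: %s; extra: %s)",
          paste(missing_f, collapse = ", ") %||% "", paste(extra_f, collapse = ", "))
  x <- impute_apply(x[, object$feature_names, drop = FALSE], object$medians)
  storage.mode(x) <- "double"
  votes <- matrix(0L, nrow(x), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (m in object$members) {
    p <- member_vote(m$forest, x, object$classes)
    for (cl in object$classes) votes[, cl] <- votes[, cl] + (p == cl)
  }
  if (type == "votes") return(votes)
  # max.col "first" implements the bad > neutral > good tie-break
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

#' A member's class vote: argmax of its forest's tree votes
#'
#' Deterministic alternative to the forest's own predict method, whose
#' tree-vote ties are broken at random; here ties resolve by the fixed
#' class-priority order.
#' @param forest A fitted member classifier.
#' @param x Imputed feature matrix.
#' @param classes Class order (priority order for ties).
#' @return Character vector of per-row class votes.
#' @export
member_vote <- function(forest, x, classes = stress_levels()) {
  if (inherits(forest, "randomForest")) {
    vf <- predict(forest, x, type = "vote")
    tv <- matrix(0, nrow(x), length(classes), dimnames = list(NULL, classes))
    tv[, colnames(vf)] <- vf
    classes[max.col(tv, ties.method = "first")]
  } else {
    as.character(predict(forest, x))
  }
}

#' @export
print.stress_ensemble <- function(x, ...) {
  cat(sprintf("Stress classification ensemble (%s)\n", x$scheme))
  cat(sprintf("  members: %d   features: %d   training rows: %d\n",
              length(x$members), length(x$feature_names), x$n_train))
  cat("  training class counts: ",
      paste(sprintf("%s=%d", names(x$class_counts), x$class_counts), collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.stress_ensemble <- function(object, ...) {
  print(object)
  cat("  member seeds:", paste(vapply(object$members, `[[`, 0, "seed"), collapse = ", "), "\n")
  cat("  SMOTE targets:",
      paste(sprintf("%s=%d", names(object$config$smote_targets),
                    object$config$smote_targets), collapse = "  "),
      sprintf("(k = %d, state = %d)\n", object$config$smote_k,
              as.integer(object$config$smote_seed)))
  invisible(object)
}
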