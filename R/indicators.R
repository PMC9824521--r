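# Gender-normalised activity, biometric and mixed indicators.
#
# For each subject s and activity a, the raw quantities are
#   Ar[s,a]: fraction of the last 24 h spent in activity a, and
#   Br[s,a]: Lorenz-plot ellipse area of the RRI pairs recorded during a
#            within the same 24 h.
# Housework time differs strongly by gender, so each quantity is divided by
# the mean over the subject's gender group:
#   Ai[s,a] = Ar[s,a] / mean_g(Ar[.,a]),  Bi[s,a] = Br[s,a] / mean_g(Br[.,a]),
#   Mixed[s,a] = Ai[s,a] * Bi[s,a].
# The group mean counts every group member, zeros included: a man who never
# cooks contributes Ar = 0 (and Br = 0, an undefined area being read as "no
# variability observed") to the male means.

#' Activity time ratios over a 24 h window
#'
#' @param durations Named numeric vector of seconds per activity (from
#'   [durations_by_activity()] on a `last_24h` window).
#' @return Named vector of ratios in `[0, 1]` (seconds / 86400).
#' @export
activity_ratio <- function(durations) {
  durations / 86400
}

#' Normalise per-subject values by their gender-group mean
#'
#' Divides each subject's value by the mean over the subject's group, where
#' the mean counts all group members (`NA`s coerced to 0 when
#' `na_as_zero = TRUE`, the indicator convention). A zero group mean leaves
#' the whole group undefined (`NA`) with a warning.
#'
#' @param values Numeric vector, one value per subject, for one activity.
#' @param groups Group id per subject (gender).
#' @param na_as_zero Treat `NA` values as 0 both in the mean and the
#'   numerator (default `TRUE`).
#' @return Numeric vector of normalised values; group mean of the result is 1
#'   for every group with a nonzero mean.
#' @export
normalize_over_subjects <- function(values, groups, na_as_zero = TRUE) {
  stopifnot(length(values) == length(groups))
  v <- as.numeric(values)
  if (na_as_zero) v[is.na(v)] <- 0
  out <- rep(NA_real_, length(v))
  for (g in unique(groups)) {
    sel <- groups == g
    gm <- mean(v[sel])
    if (is.na(gm)) next
    if (gm == 0) {
      warning(sprintf("group '%s' has zero mean; normalised values undefined", g),
              call. = FALSE)
      next
    }
    out[sel] <- v[sel] / gm
  }
  out
}

#' Mixed indicator
#'
#' Elementwise product of the activity and biometric indicators; `NA`
#' propagates.
#'
#' @param ai,bi Numeric vectors (activity and biometric indicators).
#' @return `ai * bi`.
#' @export
mixed_indicator <- function(ai, bi) {
  ai * bi
}

#' Build the per-subject indicator table
#'
#' Takes raw per-(subject, date, question, activity) quantities `Ar`
#' (24 h time ratio) and `Br` (24 h Lorenz area) and emits the normalised
#' indicators. Two normalisation scopes are supported:
#' \describe{
#'   \item{`per_day`}{(default) each subject's same-day value is divided by
#'     the same-day mean of the subject's gender group, separately per
#'     (date, question, activity) — indicators stay causally computable each
#'     day.}
#'   \item{`aggregate`}{each subject's study-period mean is normalised over
#'     the gender group, giving one indicator per (subject, activity) that is
#'     attached to every day.}
#' }
#'
#' @param raw Data frame with columns `subject_id`, `date`, `question`,
#'   `activity`, `Ar`, `Br` (`Br` may contain `NA` for activities without
#'   enough RRI pairs; treated as 0 in the group means and the subject's
#'   indicator).
#' @param subjects Subjects data frame (`subject_id`, `gender`).
#' @param scope `"per_day"` or `"aggregate"`.
#' @return `raw` with columns `gender`, `Ai`, `Bi`, `Mixed` appended.
#' @export
build_indicator_table <- function(raw, subjects, scope = c("per_day", "aggregate")) {
  scope <- match.arg(scope)
  need <- c("subject_id", "date", "question", "activity", "Ar", "Br")
  if (!all(need %in% names(raw)))
    stopf("raw indicator input must have columns: %s", paste(need, collapse = ", "))
  gmap <- stats::setNames(subjects$gender, subjects$subject_id)
  raw$gender <- unname(gmap[as.character(raw$subject_id)])
  if (anyNA(raw$gender))
    stopf("subjects missing from the subjects table: %s",
          paste(unique(raw$subject_id[is.na(raw$gender)]), collapse = ", "))
  raw$Ai <- NA_real_
  raw$Bi <- NA_real_

  if (scope == "per_day") {
    key <- interaction(raw$date, raw$question, raw$activity, drop = TRUE)
    for (k in levels(key)) {
      sel <- key == k
      raw$Ai[sel] <- normalize_over_subjects(raw$Ar[sel], raw$gender[sel])
      raw$Bi[sel] <- normalize_over_subjects(raw$Br[sel], raw$gender[sel])
    }
  } else {
    ar0 <- raw$Ar; ar0[is.na(ar0)] <- 0
    br0 <- raw$Br; br0[is.na(br0)] <- 0
    per_subj <- aggregate(cbind(Ar = ar0, Br = br0),
                          by = list(subject_id = raw$subject_id, activity = raw$activity),
                          FUN = mean)
    per_subj$gender <- unname(gmap[as.character(per_subj$subject_id)])
    per_subj$Ai <- NA_real_; per_subj$Bi <- NA_real_
    for (a in unique(per_subj$activity)) {
      sel <- per_subj$activity == a
      per_subj$Ai[sel] <- normalize_over_subjects(per_subj$Ar[sel], per_subj$gender[sel])
      per_subj$Bi[sel] <- normalize_over_subjects(per_subj$Br[sel], per_subj$gender[sel])
    }
    key_r <- paste(raw$subject_id, raw$activity)
    key_s <- paste(per_subj$subject_id, per_subj$activity)
    idx <- match(key_r, key_s)
    raw$Ai <- per_subj$Ai[idx]
    raw$Bi <- per_subj$Bi[idx]
  }
  raw$Mixed <- mixed_indicator(raw$Ai, raw$Bi)
  raw
}
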