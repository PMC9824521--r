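# Assembly of per-(subject, date, question) feature vectors for the five
# method variants. The variants nest: each adds feature families to the
# previous one.
#
#   baseline1  4 basic features (mean RRI and window-wide Lorenz area, for
#              the last 24 h and the 4 h after waking)
#   baseline2  + sleep duration (1)
#   previous   + Lorenz area per activity, both windows (2 x 6)
#   proposed1  + time per activity, both windows (2 x 6)
#   proposed2  + mixed-indicator products with the 24 h per-activity area and
#              time (2 x 6)
#
# yielding 41 features for proposed2 under the full profile. Missing values
# (no wake event, too few RRI pairs in a slice) are carried as NA and
# imputed with training-fold medians inside the classifier.

#' Feature-name manifest of a method variant
#'
#' @param variant One of `baseline1`, `baseline2`, `previous`, `proposed1`,
#'   `proposed2`.
#' @param activities Activity label set.
#' @param profile `"full"` keeps all six activities in the per-activity
#'   families (41 features for proposed2); `"compact"` drops the sleeping
#'   activity (its duration already enters as sleep duration) and keeps only
#'   the area-based mixed family, giving a 30-feature proposed2 roster.
#' @return Character vector of ordered feature names; attribute `families`
#'   maps each name to its family.
#' @export
feature_manifest <- function(variant = c("baseline1", "baseline2", "previous",
                                         "proposed1", "proposed2"),
                             activities = activity_levels(),
                             profile = c("full", "compact")) {
  variant <- match.arg(variant)
  profile <- match.arg(profile)
  acts <- if (profile == "compact") setdiff(activities, "sleeping") else activities
  fam <- list(
    basic = c("mean_rri_24h", "mean_rri_wake4h", "lp_area_24h", "lp_area_wake4h"),
    sleep = "sleep_hours",
    lp_per_activity = c(paste0("lp_area_24h_", acts), paste0("lp_area_wake4h_", acts)),
    time_per_activity = c(paste0("time_24h_", acts), paste0("time_wake4h_", acts)),
    mixed = if (profile == "compact") paste0("mixed_lp_area_24h_", acts)
            else c(paste0("mixed_lp_area_24h_", acts), paste0("mixed_time_24h_", acts)))
  upto <- switch(variant, baseline1 = 1L, baseline2 = 2L, previous = 3L,
                 proposed1 = 4L, proposed2 = 5L)
  keep <- fam[seq_len(upto)]
  nm <- unlist(keep, use.names = FALSE)
  attr(nm, "families") <- rep(names(keep), lengths(keep))
  nm
}

#' Basic biometric features of one questionnaire row
#'
#' @param rri RRI data frame (`timestamp`, `rri_ms`) for the subject.
#' @param w24 `last_24h` analysis window.
#' @param w4 `post_wake_4h` analysis window (may have an `NA` anchor, in
#'   which case the post-wake features are missing).
#' @param max_gap Lorenz pair gap rule in seconds.
#' @param rri_wake Optional pre-sliced RRI data for the post-wake window;
#'   when omitted both windows are sliced from `rri`.
#' @return Named numeric vector of the four basic features; window-wide
#'   Lorenz areas pool all pairs in the window regardless of activity.
#' @export
basic_features <- function(rri, w24, w4, max_gap = 30, rri_wake = NULL) {
  slice <- function(w) {
    if (is.na(w$start)) return(rri[0, , drop = FALSE])
    t <- as.numeric(as_instant(rri$timestamp))
    rri[t >= as.numeric(w$start) & t < as.numeric(w$end), , drop = FALSE]
  }
  r24 <- slice(w24)
  r4 <- if (is.null(rri_wake)) slice(w4) else {
    t <- as.numeric(as_instant(rri_wake$timestamp))
    if (is.na(w4$start)) rri_wake[0, , drop = FALSE]
    else rri_wake[t >= as.numeric(w4$start) & t < as.numeric(w4$end), , drop = FALSE]
  }
  c(mean_rri_24h = mean_rri(r24),
    mean_rri_wake4h = mean_rri(r4),
    lp_area_24h = lorenz_area(build_pairs(r24, max_gap = max_gap)),
    lp_area_wake4h = lorenz_area(build_pairs(r4, max_gap = max_gap)))
}

#' Sleep duration in hours from 24 h activity durations
#'
#' Identical by definition to the sleeping entry of the time-per-activity
#' family, expressed in hours.
#' @param durations Named seconds-per-activity vector from a `last_24h`
#'   window.
#' @return Hours of sleep.
#' @export
sleep_duration <- function(durations) {
  unname(durations["sleeping"]) / 3600
}

#' Per-activity Lorenz areas and durations in one window
#'
#' @param rri RRI data frame.
#' @param intervals Subject's activity intervals.
#' @param window An `analysis_window`.
#' @param suffix Name suffix identifying the window kind (`"24h"` or
#'   `"wake4h"`).
#' @param activities Label set.
#' @param max_gap Lorenz pair gap rule in seconds.
#' @return Named vector `lp_area_<suffix>_<activity>` (NA when fewer than
#'   two pairs) and `time_<suffix>_<activity>` (seconds; 0 when absent).
#' @export
per_activity_features <- function(rri, intervals, window, suffix = "24h",
                                  activities = activity_levels(), max_gap = 30) {
  if (is.na(window$start)) {
    out <- rep(NA_real_, 2L * length(activities))
    names(out) <- c(paste0("lp_area_", suffix, "_", activities),
                    paste0("time_", suffix, "_", activities))
    return(out)
  }
  prs <- pairs_by_activity(rri, intervals, window, max_gap = max_gap,
                           activities = activities)
  areas <- vapply(activities, function(a) lorenz_area(prs[[a]]), 0)
  durs <- durations_by_activity(intervals, window, activities)
  out <- c(areas, durs[activities])
  names(out) <- c(paste0("lp_area_", suffix, "_", activities),
                  paste0("time_", suffix, "_", activities))
  out
}

#' Mixed-indicator feature products
#'
#' Multiplies the per-activity mixed indicator with the 24 h per-activity
#' Lorenz area and duration. NA inputs propagate.
#'
#' @param mixed Named mixed-indicator vector (one entry per activity).
#' @param lp24 Named `lp_area_24h_<activity>` vector.
#' @param time24 Named `time_24h_<activity>` vector.
#' @param activities Label set.
#' @return Named vector `mixed_lp_area_24h_<a>`, `mixed_time_24h_<a>`.
#' @export
mixed_features <- function(mixed, lp24, time24, activities = activity_levels()) {
  out <- c(mixed[activities] * lp24[paste0("lp_area_24h_", activities)],
           mixed[activities] * time24[paste0("time_24h_", activities)])
  names(out) <- c(paste0("mixed_lp_area_24h_", activities),
                  paste0("mixed_time_24h_", activities))
  out
}

#' @noRd
night_bed_time <- function(intervals, date) {
  day0 <- as.numeric(as_instant(as_day(date)))
  starts <- as.numeric(as_instant(intervals$start))
  sel <- intervals$label == "sleeping" & starts >= day0 + 14 * 3600 &
    starts < day0 + 28 * 3600
  if (!any(sel)) return(as_instant(NA_real_))
  as_instant(min(starts[sel]))
}

#' @noRd
question_anchor <- function(question, date, answered_at, intervals) {
  if (!is.null(answered_at) && !is.na(answered_at)) return(as_instant(answered_at))
  if (question == "MQ") wake_time(intervals, date) else night_bed_time(intervals, date)
}

#' Build the feature dataset for a method variant
#'
#' One row per (subject, date, question) found in the cohort's answers. The
#' morning question of day *d* anchors its 24 h window at the answer time
#' (wake, by default) and takes its post-wake window from the *previous*
#' day's wake event — the 4 h after the current wake have not happened yet;
#' the night question anchors at the evening answer time and uses the same
#' day's wake. Both windows therefore end strictly before the questionnaire
#' anchor, so no feature can leak post-questionnaire data.
#'
#' @param cohort A `stress_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param variant Method variant name (see [feature_manifest()]).
#' @param scope Indicator normalisation scope, see [build_indicator_table()].
#' @param profile Feature profile, see [feature_manifest()].
#' @param max_gap Lorenz pair gap rule in seconds (default twice the nominal
#'   15 s cadence).
#' @return Data frame of class `stress_features`: id columns `subject_id`,
#'   `date`, `question`, `answer`, then the variant's features in manifest
#'   order; attribute `manifest` records the variant, feature names and
#'   configuration.
#' @export
build_dataset <- function(cohort, variant = "proposed2",
                          scope = c("per_day", "aggregate"),
                          profile = c("full", "compact"), max_gap = 30) {
  scope <- match.arg(scope)
  profile <- match.arg(profile)
  acts <- if (!is.null(cohort$config)) cohort$config$activities else activity_levels()
  manifest <- feature_manifest(variant, acts, profile)
  full <- feature_manifest("proposed2", acts, "full")

  ans <- cohort$answers
  dup <- duplicated(ans[, c("subject_id", "date", "question")])
  if (any(dup)) stopf("duplicate (subject, date, question) answer rows")
  has_at <- "answered_at" %in% names(ans)

  subj_rri <- list(); subj_int <- list(); subj_t <- list()
  for (sid in unique(ans$subject_id)) {
    hr <- cohort$heart_rate[cohort$heart_rate$subject_id == sid, , drop = FALSE]
    subj_rri[[sid]] <- series_to_rri(hr)
    subj_t[[sid]] <- as.numeric(subj_rri[[sid]]$timestamp)
    subj_int[[sid]] <- cohort$activities[cohort$activities$subject_id == sid, , drop = FALSE]
  }
  # pre-restrict the subject's series to the window by binary search; the
  # downstream operations then scan only the slice
  slice_window <- function(rri, t, w) {
    if (is.na(w$start)) return(rri[0, , drop = FALSE])
    # left.open counts strict inequalities, giving the exact half-open
    # [start, end) slice without epsilon tricks
    lo <- findInterval(as.numeric(w$start), t, left.open = TRUE) + 1L
    hi <- findInterval(as.numeric(w$end), t, left.open = TRUE)
    if (hi < lo) return(rri[0, , drop = FALSE])
    rri[lo:hi, , drop = FALSE]
  }

  rows <- vector("list", nrow(ans))
  for (i in seq_len(nrow(ans))) {
    sid <- ans$subject_id[i]; q <- ans$question[i]; date <- ans$date[i]
    rri <- subj_rri[[sid]]; ints <- subj_int[[sid]]; t <- subj_t[[sid]]
    anchor <- question_anchor(q, date, if (has_at) ans$answered_at[i] else NULL, ints)
    w24 <- make_window("last_24h", anchor)
    wake_anchor <- if (q == "MQ") wake_time(ints, as_day(date) - 1L)
                   else wake_time(ints, date)
    w4 <- make_window("post_wake_4h", wake_anchor)
    r24 <- slice_window(rri, t, w24)
    r4 <- slice_window(rri, t, w4)
    fb <- basic_features(r24, w24, w4, max_gap = max_gap, rri_wake = r4)
    d24 <- durations_by_activity(ints, w24, acts)
    pa24 <- per_activity_features(r24, ints, w24, "24h", acts, max_gap)
    pa4 <- per_activity_features(r4, ints, w4, "wake4h", acts, max_gap)
    rows[[i]] <- c(fb, sleep_hours = sleep_duration(d24), pa24, pa4)
  }
  feats <- do.call(rbind, rows)

  # mixed indicators need the whole cohort: Ar/Br per row, normalised over
  # subjects within gender group
  raw <- do.call(rbind, lapply(seq_len(nrow(ans)), function(i) {
    data.frame(subject_id = ans$subject_id[i], date = ans$date[i],
               question = ans$question[i], activity = acts,
               Ar = as.numeric(feats[i, paste0("time_24h_", acts)]) / 86400,
               Br = as.numeric(feats[i, paste0("lp_area_24h_", acts)]))
  }))
  ind <- build_indicator_table(raw, cohort$subjects, scope = scope)
  mixed_cols <- matrix(NA_real_, nrow(ans), 2L * length(acts),
                       dimnames = list(NULL, c(paste0("mixed_lp_area_24h_", acts),
                                               paste0("mixed_time_24h_", acts))))
  key_row <- paste(ans$subject_id, ans$date, ans$question)
  key_ind <- paste(ind$subject_id, ind$date, ind$question)
  for (i in seq_len(nrow(ans))) {
    sub <- ind[key_ind == key_row[i], , drop = FALSE]
    mx <- stats::setNames(sub$Mixed, sub$activity)
    mixed_cols[i, ] <- mixed_features(mx, feats[i, ], feats[i, ], acts)
  }
  feats <- cbind(feats, mixed_cols)[, full, drop = FALSE]

  out <- cbind(ans[, c("subject_id", "date", "question", "answer")],
               as.data.frame(feats[, manifest, drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "manifest") <- list(variant = variant, features = manifest,
                                activities = acts, scope = scope,
                                profile = profile, max_gap = max_gap)
  class(out) <- c("stress_features", class(out))
  out
}

#' Extract the feature matrix and labels from a feature dataset
#'
#' @param features A `stress_features` data frame.
#' @param mapping Likert mapping (see [map_likert()]).
#' @return List with numeric matrix `x` (manifest columns only) and factor
#'   `y` of stress labels.
#' @export
feature_matrix <- function(features, mapping = likert_mapping()) {
  man <- attr(features, "manifest")
  x <- as.matrix(features[, man$features, drop = FALSE])
  y <- map_likert(features$answer, features$question, mapping)
  list(x = x, y = y)
}
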