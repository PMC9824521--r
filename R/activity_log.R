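# Activity-interval logs, analysis windows, and slicing of RRI data by
# activity. Intervals are half-open [start, end) in timezone-naive local
# time; the six default labels follow the in-home activity-recognition
# annotation scheme.

#' Default set of daily-living activity labels
#'
#' @return Character vector: bathing, cooking, eating, going_out, sleeping,
#'   other.
#' @export
activity_levels <- function() {
  c("bathing", "cooking", "eating", "going_out", "sleeping", "other")
}

#' @noRd
validate_intervals <- function(df, activities) {
  df$start <- as_instant(df$start)
  df$end <- as_instant(df$end)
  bad <- which(!(as.numeric(df$end) > as.numeric(df$start)))
  if (length(bad))
    stopf("intervals with start >= end at rows: %s", paste(utils::head(bad, 10L), collapse = ", "))
  unknown <- setdiff(unique(as.character(df$label)), activities)
  if (length(unknown))
    stopf("unknown activity label(s): %s (expected one of: %s)",
          paste(unknown, collapse = ", "), paste(activities, collapse = ", "))
  df$label <- as.character(df$label)
  split_by <- if ("subject_id" %in% names(df)) df$subject_id else rep("", nrow(df))
  for (sid in unique(split_by)) {
    d <- df[split_by == sid, , drop = FALSE]
    o <- order(as.numeric(d$start))
    d <- d[o, , drop = FALSE]
    if (nrow(d) > 1L) {
      ov <- which(as.numeric(d$start[-1L]) < as.numeric(d$end[-nrow(d)]))
      if (length(ov))
        stopf("overlapping intervals%s: [%s, %s) '%s' overlaps [%s, %s) '%s'",
              if (nzchar(sid)) paste0(" for subject ", sid) else "",
              fmt_instant(d$start[ov[1L]]), fmt_instant(d$end[ov[1L]]), d$label[ov[1L]],
              fmt_instant(d$start[ov[1L] + 1L]), fmt_instant(d$end[ov[1L] + 1L]), d$label[ov[1L] + 1L])
    }
  }
  df[order(split_by, as.numeric(df$start)), , drop = FALSE]
}

#' Load and validate an activity-interval log
#'
#' Reads a CSV with columns `subject_id,start,end,label` (ISO-8601 local
#' timestamps). Intervals are validated: start < end, labels restricted to
#' the configured activity set, and no within-subject overlaps.
#'
#' @param path CSV file path, or a data frame already holding the columns.
#' @param activities Allowed label set (default [activity_levels()]).
#' @return Data frame of validated intervals sorted by subject and start.
#' @export
load_activity_log <- function(path, activities = activity_levels()) {
  df <- if (is.data.frame(path)) path
        else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start", "end", "label")
  if (!all(need %in% names(df)))
    stopf("activity log must have columns start, end, label (got: %s)",
          paste(names(df), collapse = ", "))
  if (!nrow(df)) {
    df$start <- as_instant(character(0)); df$end <- as_instant(character(0))
    return(df)
  }
  rownames(df) <- NULL
  validate_intervals(df, activities)
}

#' Wake time of a given date
#'
#' The wake event of day `date` is the end of the last sleeping interval that
#' ends between 00:00 and 14:00 local time on that date; this tolerates
#' interrupted nights (the final morning awakening wins) while excluding
#' afternoon naps.
#'
#' @param intervals Validated interval data frame for one subject.
#' @param date A `Date` (or string coercible to one).
#' @return POSIXct wake instant, or `NA` when no qualifying sleeping interval
#'   exists (the day's post-wake features are then missing).
#' @export
wake_time <- function(intervals, date) {
  date <- as_day(date)
  day0 <- as_instant(date)
  lo <- as.numeric(day0)
  hi <- lo + 14 * 3600
  ends <- as.numeric(as_instant(intervals$end))
  sel <- intervals$label == "sleeping" & ends > lo & ends <= hi
  if (!any(sel)) return(as_instant(NA_real_))
  as_instant(max(ends[sel]))
}

#' Construct an analysis window
#'
#' Two window kinds anchor the feature aggregation: `last_24h` covers the 24
#' hours up to (and excluding) the anchor — normally the questionnaire answer
#' time — and `post_wake_4h` covers the 4 hours from the wake anchor.
#'
#' @param kind `"last_24h"` or `"post_wake_4h"`.
#' @param anchor POSIXct anchor instant (answer time, or wake time for
#'   `post_wake_4h`).
#' @return List of class `analysis_window` with `kind`, `anchor`, `start`,
#'   `end` (half-open `[start, end)`).
#' @export
make_window <- function(kind = c("last_24h", "post_wake_4h"), anchor) {
  kind <- match.arg(kind)
  anchor <- as_instant(anchor)
  if (is.na(anchor)) {
    w <- list(kind = kind, anchor = anchor, start = anchor, end = anchor)
    class(w) <- "analysis_window"
    return(w)
  }
  if (kind == "last_24h") {
    start <- anchor - 86400; end <- anchor
  } else {
    start <- anchor; end <- anchor + 14400
  }
  w <- list(kind = kind, anchor = anchor, start = start, end = end)
  class(w) <- "analysis_window"
  w
}

#' Clip activity intervals to a window
#'
#' Intersects each interval with `[window$start, window$end)`; partial
#' overlaps are truncated, empty intersections dropped.
#'
#' @param intervals Interval data frame.
#' @param window An `analysis_window`.
#' @return Clipped interval data frame (possibly zero rows).
#' @export
clip_to_window <- function(intervals, window) {
  if (!nrow(intervals) || is.na(window$start)) return(intervals[0, , drop = FALSE])
  s <- pmax(as.numeric(as_instant(intervals$start)), as.numeric(window$start))
  e <- pmin(as.numeric(as_instant(intervals$end)), as.numeric(window$end))
  keep <- e > s
  out <- intervals[keep, , drop = FALSE]
  out$start <- as_instant(s[keep])
  out$end <- as_instant(e[keep])
  rownames(out) <- NULL
  out
}

#' Total time per activity within a window
#'
#' @param intervals Interval data frame (clipped or not; clipping is applied).
#' @param window An `analysis_window`.
#' @param activities Label set; absent labels get 0.
#' @return Named numeric vector of seconds per activity.
#' @export
durations_by_activity <- function(intervals, window, activities = activity_levels()) {
  clipped <- clip_to_window(intervals, window)
  secs <- stats::setNames(numeric(length(activities)), activities)
  if (nrow(clipped)) {
    len <- as.numeric(clipped$end) - as.numeric(clipped$start)
    agg <- tapply(len, factor(clipped$label, levels = activities), sum, default = 0)
    secs[names(agg)] <- as.numeric(agg)
  }
  secs
}

#' Assign RRI samples to activity intervals within a window
#'
#' Each RRI sample falling in the window is assigned to the interval that
#' contains its timestamp under the half-open convention `[start, end)`; a
#' sample sitting exactly on an interval's end instant belongs to the next
#' interval. Samples in log gaps stay unassigned (`NA` label). The returned
#' `segment` id distinguishes multiple occurrences of the same activity so
#' Lorenz pairs can be built per occurrence and pooled without bridging
#' segments.
#'
#' @param rri RRI data frame (`timestamp`, `rri_ms`), sorted by time.
#' @param intervals Interval data frame.
#' @param window An `analysis_window`.
#' @return Data frame `timestamp`, `rri_ms`, `label`, `segment` restricted to
#'   the window.
#' @export
rri_by_activity <- function(rri, intervals, window) {
  clipped <- clip_to_window(intervals, window)
  t <- as.numeric(as_instant(rri$timestamp))
  inw <- t >= as.numeric(window$start) & t < as.numeric(window$end)
  out <- data.frame(timestamp = as_instant(rri$timestamp)[inw],
                    rri_ms = as.numeric(rri$rri_ms)[inw],
                    label = NA_character_, segment = NA_integer_)
  if (!nrow(out) || !nrow(clipped)) return(out)
  ts <- as.numeric(out$timestamp)
  starts <- as.numeric(clipped$start)
  ends <- as.numeric(clipped$end)
  idx <- findInterval(ts, starts)            # candidate interval (last start <= t)
  hit <- idx >= 1L & ts < ends[pmax(idx, 1L)]
  out$label[hit] <- clipped$label[idx[hit]]
  out$segment[hit] <- idx[hit]
  out
}

#' Pool Lorenz pairs per activity within a window
#'
#' Builds pairs inside each activity occurrence (never across segment
#' boundaries) and pools them by label.
#'
#' @inheritParams rri_by_activity
#' @param max_gap Maximum pair spacing in seconds (see [build_pairs()]).
#' @param activities Label set.
#' @return Named list label -> two-column pair matrix.
#' @export
pairs_by_activity <- function(rri, intervals, window, max_gap = 30,
                              activities = activity_levels()) {
  assigned <- rri_by_activity(rri, intervals, window)
  out <- stats::setNames(vector("list", length(activities)), activities)
  empty <- matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("a", "b")))
  for (a in activities) out[[a]] <- empty
  keep <- !is.na(assigned$label)
  if (sum(keep) < 2L) return(out)
  assigned <- assigned[keep, , drop = FALSE]
  # a pair joins consecutive samples of the same occurrence within the gap
  t <- as.numeric(assigned$timestamp)
  v <- assigned$rri_ms
  n <- length(v)
  ok <- assigned$segment[-1L] == assigned$segment[-n] & diff(t) <= max_gap
  if (!any(ok)) return(out)
  lab <- assigned$label[-n][ok]
  p <- cbind(a = v[-n][ok], b = v[-1L][ok])
  for (a in intersect(activities, unique(lab)))
    out[[a]] <- p[lab == a, , drop = FALSE]
  out
}

# ---- CSV readers for the cohort file schemas -------------------------------

#' Load a heart-rate CSV (`subject_id,timestamp,bpm`)
#' @param path CSV path or data frame.
#' @return Data frame with parsed timestamps, sorted by subject and time.
#' @export
load_heart_rate <- function(path) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "timestamp", "bpm") %in% names(df)))
    stopf("heart-rate file must have columns subject_id, timestamp, bpm")
  df$timestamp <- as_instant(df$timestamp)
  df[order(df$subject_id, as.numeric(df$timestamp)), , drop = FALSE]
}

#' Load a questionnaire-answer CSV
#'
#' Columns `subject_id,date,question,answer` with optional `answered_at`.
#' Questions are `MQ` (morning) or `NQ` (night); answers are integers 1..5.
#' @param path CSV path or data frame.
#' @return Validated data frame.
#' @export
load_answers <- function(path) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "date", "question", "answer") %in% names(df)))
    stopf("answers file must have columns subject_id, date, question, answer")
  df$date <- as_day(df$date)
  bad <- setdiff(unique(df$question), c("MQ", "NQ"))
  if (length(bad)) stopf("unknown question id(s): %s", paste(bad, collapse = ", "))
  if (any(!df$answer %in% 1:5)) stopf("answers must be integers in 1..5")
  if ("answered_at" %in% names(df)) df$answered_at <- as_instant(df$answered_at)
  dup <- duplicated(df[, c("subject_id", "date", "question")])
  if (any(dup))
    stopf("duplicate (subject, date, question) rows, e.g. %s %s %s",
          df$subject_id[dup][1L], format(df$date[dup][1L]), df$question[dup][1L])
  df
}

#' Load a subjects CSV (`subject_id,gender,household_id`)
#' @param path CSV path or data frame.
#' @return Validated data frame; gender must be `M` or `F`.
#' @export
load_subjects <- function(path) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "gender") %in% names(df)))
    stopf("subjects file must have columns subject_id, gender")
  if (any(!df$gender %in% c("M", "F"))) stopf("gender must be 'M' or 'F'")
  df
}
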