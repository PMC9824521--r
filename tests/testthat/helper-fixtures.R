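# Shared fixture builders and independent oracles. The oracles deliberately
# use direct summation / per-second scans, independent of the package's
# vectorised implementations.

base_day <- as.POSIXct("2022-03-01", tz = "UTC")

# data frame of RRI samples at second offsets from base_day
make_rri <- function(offset_sec, rri_ms) {
  data.frame(timestamp = base_day + offset_sec, rri_ms = rri_ms)
}

# intervals from hour offsets relative to base_day
make_intervals <- function(start_h, end_h, label, subject_id = NULL) {
  df <- data.frame(start = base_day + start_h * 3600,
                   end = base_day + end_h * 3600,
                   label = label)
  if (!is.null(subject_id)) df <- cbind(subject_id = subject_id, df)
  df
}

# brute-force Lorenz projection oracle: explicit u/v formation, direct
# two-pass summation for the population sds
lorenz_oracle <- function(pairs) {
  p <- as.matrix(pairs)
  n <- nrow(p)
  u <- numeric(n); v <- numeric(n)
  for (i in seq_len(n)) {
    u[i] <- (p[i, 1] + p[i, 2]) / sqrt(2)
    v[i] <- (p[i, 1] - p[i, 2]) / sqrt(2)
  }
  mu <- sum(u) / n
  mv <- sum(v) / n
  su <- 0; sv <- 0
  for (i in seq_len(n)) {
    su <- su + (u[i] - mu)^2
    sv <- sv + (v[i] - mv)^2
  }
  dx <- sqrt(su / n); dnx <- sqrt(sv / n)
  list(m = mu, delta_x = dx, delta_neg_x = dnx, area = pi * dx * dnx)
}

# 1 s resolution membership-count oracle for clipped durations
clip_oracle_seconds <- function(intervals, window, activities) {
  secs <- seq(as.numeric(window$start), as.numeric(window$end) - 1)
  out <- stats::setNames(numeric(length(activities)), activities)
  s <- as.numeric(intervals$start); e <- as.numeric(intervals$end)
  for (i in seq_len(nrow(intervals))) {
    inside <- secs >= s[i] & secs < e[i]
    out[intervals$label[i]] <- out[intervals$label[i]] + sum(inside)
  }
  out
}

# per-sample linear-scan assignment oracle
assign_oracle <- function(rri, intervals, window) {
  t <- as.numeric(rri$timestamp)
  lab <- rep(NA_character_, length(t))
  s <- as.numeric(intervals$start); e <- as.numeric(intervals$end)
  for (i in seq_along(t)) {
    if (t[i] < as.numeric(window$start) || t[i] >= as.numeric(window$end)) next
    for (j in seq_len(nrow(intervals))) {
      if (t[i] >= max(s[j], as.numeric(window$start)) &&
          t[i] < min(e[j], as.numeric(window$end))) {
        lab[i] <- intervals$label[j]
        break
      }
    }
  }
  lab[t >= as.numeric(window$start) & t < as.numeric(window$end)]
}

# small fast cohort for unit tests (not the study conditions)
tiny_config <- function(seed = 1, n_days = 3L, ...) {
  cohort_config(n_households = 2L, n_days = n_days, hr_sample_period = 60,
                seed = seed, ...)
}

# mock forest whose predict() returns a constant class, for vote-rule tests
predict.mock_forest <- function(object, newdata, ...) {
  rep(object$out, nrow(newdata))
}
registerS3method("predict", "mock_forest", predict.mock_forest)
mock_ensemble <- function(member_outputs) {
  members <- lapply(seq_along(member_outputs), function(i)
    list(seed = i, forest = structure(list(out = member_outputs[i]),
                                      class = "mock_forest")))
  structure(list(members = members, scheme = "over_under_bagging",
                 config = resampling_config(), classes = stress_levels(),
                 feature_names = "f1", medians = c(f1 = 0), n_train = 0L,
                 class_counts = table(factor(character(), levels = stress_levels()))),
            class = "stress_ensemble")
}
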