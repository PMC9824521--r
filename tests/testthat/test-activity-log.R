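# The reference schedule used below is the classic annotated example day:
# overnight sleep to 07:00, cooking/eating in the morning, a long outing,
# evening cooking/eating/resting, a bath, and sleep from 23:00.
example_schedule <- function() {
  make_intervals(
    start_h = c(0, 7.5, 8, 8.5, 9, 18, 18.5, 19.5, 21, 21.5, 23),
    end_h   = c(7, 8, 8.5, 9, 18, 18.5, 19.5, 21, 21.5, 23, 24),
    label = c("sleeping", "cooking", "eating_meals", "resting", "going_out",
              "cooking", "eating_meals", "resting", "bathing", "resting",
              "sleeping"))
}
example_labels <- c("sleeping", "cooking", "eating_meals", "resting",
                    "going_out", "bathing")

test_that("activity log loading validates schema, labels and overlaps", {
  sched <- example_schedule()
  f <- tempfile(fileext = ".csv")
  write.csv(transform(sched, start = format(start, "%Y-%m-%dT%H:%M:%S"),
                      end = format(end, "%Y-%m-%dT%H:%M:%S")),
            f, row.names = FALSE)
  log <- load_activity_log(f, activities = example_labels)
  expect_equal(nrow(log), 11L)
  expect_equal(log$label, sched$label)

  empty <- tempfile(fileext = ".csv")
  writeLines("subject_id,start,end,label", empty)
  expect_equal(nrow(load_activity_log(empty)), 0L)

  expect_error(load_activity_log(make_intervals(0, 1, "surfing")), "surfing")

  overlapping <- make_intervals(c(0, 0.5), c(1, 2), c("sleeping", "cooking"))
  err <- tryCatch(load_activity_log(overlapping), error = conditionMessage)
  expect_match(err, "overlap")
  expect_match(err, "sleeping")
  expect_match(err, "cooking")
})

test_that("wake time is the last sleeping end in the morning half of the day", {
  sched <- example_schedule()
  expect_equal(wake_time(sched, as.Date(base_day)), base_day + 7 * 3600)

  interrupted <- make_intervals(c(0, 6.5), c(6, 7.5), c("sleeping", "sleeping"))
  expect_equal(wake_time(interrupted, as.Date(base_day)), base_day + 7.5 * 3600)

  none <- make_intervals(9, 10, "cooking")
  expect_true(is.na(wake_time(none, as.Date(base_day))))
})

test_that("analysis windows have the exact spans", {
  a <- as.POSIXct("2022-01-02 22:00:00", tz = "UTC")
  w <- make_window("last_24h", a)
  expect_equal(w$start, as.POSIXct("2022-01-01 22:00:00", tz = "UTC"))
  expect_equal(as.numeric(w$end) - as.numeric(w$start), 86400)

  wk <- as.POSIXct("2022-01-02 07:00:00", tz = "UTC")
  w4 <- make_window("post_wake_4h", wk)
  expect_equal(w4$end, as.POSIXct("2022-01-02 11:00:00", tz = "UTC"))
  expect_equal(as.numeric(w4$end) - as.numeric(w4$start), 14400)
})

test_that("clipping truncates, drops and is idempotent", {
  w <- make_window("post_wake_4h", base_day + 7 * 3600)  # 07:00-11:00
  iv <- make_intervals(c(6, 12), c(8, 13), c("cooking", "eating_meals"))
  cl <- clip_to_window(iv, w)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, base_day + 7 * 3600)
  expect_equal(cl$end, base_day + 8 * 3600)
  expect_equal(clip_to_window(cl, w), cl)
})

test_that("durations match the example schedule arithmetic and the 1 s oracle", {
  sched <- example_schedule()
  w <- make_window("last_24h", base_day + 86400)  # the full calendar day
  d <- durations_by_activity(sched, w, example_labels)
  # 00:00-07:00 plus 23:00-24:00
  expect_equal(unname(d["sleeping"]), 8 * 3600)
  expect_equal(unname(d["going_out"]), 9 * 3600)
  # the printed schedule leaves 07:00-07:30 unlogged
  expect_equal(sum(d), 86400 - 1800)

  expect_true(all(durations_by_activity(sched[0, ], w, example_labels) == 0))

  set.seed(51)
  for (rep in 1:15) {
    n <- sample(3:8, 1)
    starts <- sort(sample(0:86000, n))
    ends <- pmin(starts + sample(600:7200, n, replace = TRUE),
                 c(starts[-1], 86400))
    keep <- ends > starts
    iv <- data.frame(start = base_day + starts[keep], end = base_day + ends[keep],
                     label = sample(example_labels, sum(keep), replace = TRUE))
    w <- make_window("last_24h", base_day + sample(20000:86400, 1))
    got <- durations_by_activity(iv, w, example_labels)
    want <- clip_oracle_seconds(iv, w, example_labels)
    expect_equal(got, want)
    expect_lte(sum(got), 86400)
  }
})

test_that("RRI samples are assigned half-open, per occurrence, matching a scan oracle", {
  iv <- make_intervals(c(7, 8, 9), c(8, 9, 10),
                       c("cooking", "eating", "cooking"))
  w <- make_window("last_24h", base_day + 86400)
  # sample exactly at 08:00 belongs to 'eating', not the ending 'cooking'
  r <- make_rri(c(7.5, 8, 9) * 3600, c(900, 910, 920))
  a <- rri_by_activity(r, iv, w)
  expect_equal(a$label, c("cooking", "eating", "cooking"))

  # two cooking occurrences pool areas but never pair across segments
  n1 <- 10; n2 <- 7
  r <- make_rri(c(7 * 3600 + seq_len(n1) * 15, 9 * 3600 + seq_len(n2) * 15),
                rnorm(n1 + n2, 900, 30))
  prs <- pairs_by_activity(r, iv, w, activities = c("cooking", "eating"))
  expect_equal(nrow(prs$cooking), (n1 - 1) + (n2 - 1))

  set.seed(61)
  for (rep in 1:10) {
    iv <- make_intervals(c(0, 6, 9, 14), c(5, 9, 12, 20),
                         sample(activity_levels(), 4, replace = TRUE))
    r <- make_rri(sort(sample(0:(22 * 3600), 300)), rnorm(300, 900, 40))
    w <- make_window("last_24h", base_day + sample(3600 * 10:22, 1))
    got <- rri_by_activity(r, iv, w)
    expect_equal(got$label, assign_oracle(r, iv, w))
    # partition: in-window sample count is preserved
    t <- as.numeric(r$timestamp)
    expect_equal(nrow(got), sum(t >= as.numeric(w$start) & t < as.numeric(w$end)))
  }
})
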