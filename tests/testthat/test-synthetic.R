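test_that("cohort simulation is deterministic given the seed", {
  a <- simulate_cohort(tiny_config(seed = 7))
  b <- simulate_cohort(tiny_config(seed = 7))
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$heart_rate, b$heart_rate)
  expect_identical(a$activities, b$activities)
  expect_identical(a$answers, b$answers)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(tiny_config(seed = 8))
  expect_false(identical(a$heart_rate, c$heart_rate))
})

test_that("sampling cadence yields 86400/period samples per subject-day", {
  co <- simulate_cohort(cohort_config(n_households = 1L, singles_fraction = 1,
                                      n_days = 1L, missingness = 0, seed = 3))
  expect_equal(nrow(co$subjects), 1L)
  expect_equal(nrow(co$heart_rate), 5760L)
  # dropout removes samples
  co2 <- simulate_cohort(cohort_config(n_households = 1L, singles_fraction = 1,
                                       n_days = 1L, missingness = 0.1, seed = 3))
  expect_lt(nrow(co2$heart_rate), 5760L)
})

test_that("generated schedules tile the day and anchor sleep overnight", {
  co <- simulate_cohort(tiny_config(seed = 5))
  dates <- sort(unique(co$answers$date))
  for (sid in co$subjects$subject_id) {
    iv <- co$activities[co$activities$subject_id == sid, ]
    expect_true(all(iv$label %in% activity_levels()))
    o <- order(as.numeric(iv$start))
    iv <- iv[o, ]
    expect_true(all(as.numeric(iv$start[-1]) >= as.numeric(iv$end[-nrow(iv)])))
    for (d in seq_along(dates)) {
      w <- make_window("last_24h", as.POSIXct(dates[d], tz = "UTC") + 86400)
      expect_equal(sum(durations_by_activity(iv, w)), 86400)
      # a wake event exists every questionnaire morning
      expect_false(is.na(wake_time(iv, dates[d])))
    }
  }
  expect_true(all(co$answers$answer %in% 1:5))
})

test_that("the latent truth never enters the feature-facing files", {
  co <- simulate_cohort(tiny_config(seed = 9))
  dir <- tempfile()
  write_cohort(co, dir)
  for (f in c("subjects.csv", "heart_rate.csv", "activities.csv", "answers.csv")) {
    cols <- names(read.csv(file.path(dir, f), nrows = 1))
    expect_false(any(grepl("stress", cols)), info = f)
  }
  expect_true(file.exists(file.path(dir, "cohort_truth.csv")))
  back <- read_cohort(dir)
  expect_equal(nrow(back$heart_rate), nrow(co$heart_rate))
  expect_equal(back$answers$answer, co$answers$answer)
  expect_equal(back$truth$latent_stress, co$truth$latent_stress, tolerance = 1e-9)
})

test_that("within-activity RRI dispersion decreases strictly with stress", {
  cfg <- cohort_config(duration_stress_effect = 0)
  set.seed(42)
  lo <- simulate_day("2022-03-05", 0, "F", cfg)
  set.seed(42)
  hi <- simulate_day("2022-03-05", 1, "F", cfg)
  # identical schedules (duration link disabled), identical normal draws
  expect_equal(lo$intervals$label, hi$intervals$label)
  rri_lo <- 60000 / lo$hr$bpm
  rri_hi <- 60000 / hi$hr$bpm
  lab <- rri_by_activity(series_to_rri(lo$hr),
                         lo$intervals,
                         make_window("last_24h",
                                     as.POSIXct("2022-03-06", tz = "UTC")))$label
  for (a in unique(na.omit(lab))) {
    sel <- which(lab == a)
    if (length(sel) < 30) next
    expect_gt(sd(rri_lo[sel]), sd(rri_hi[sel]))
  }
  expect_equal(sort(unique(lo$intervals$label)), sort(activity_levels()))
})

test_that("sampled RRI dispersion converges to the configured link", {
  cfg <- cohort_config(hr_sample_period = 1, missingness = 0)
  set.seed(17)
  day <- simulate_day("2022-03-05", 0.5, "F", cfg)
  rri <- series_to_rri(day$hr)
  lab <- rri_by_activity(rri, day$intervals,
                         make_window("last_24h",
                                     as.POSIXct("2022-03-06", tz = "UTC")))$label
  sleep_rri <- rri$rri_ms[which(lab == "sleeping")]
  expect_gt(length(sleep_rri), 10000)
  want <- cfg$rri_dispersion[["sleeping"]] * (1 - cfg$dispersion_stress_effect * 0.5)
  expect_lt(abs(sd(sleep_rri) - want) / want, 0.05)
})

test_that("likert answers follow the threshold link and its bin probabilities", {
  th <- c(0.25, 0.40, 0.60, 0.75)
  set.seed(23)
  expect_equal(generate_answer("NQ", 0.1, th, noise_sd = 0), 1L)
  expect_equal(generate_answer("MQ", 0.1, th, noise_sd = 0), 5L)
  expect_equal(generate_answer("NQ", 0.9, th, noise_sd = 0), 5L)
  expect_equal(generate_answer("MQ", 0.9, th, noise_sd = 0), 1L)

  s <- 0.5; noise <- 0.1
  draws <- generate_answer("NQ", rep(s, 10000), th, noise_sd = noise)
  emp <- tabulate(draws, 5) / 10000
  want <- diff(c(0, pnorm(th, mean = s, sd = noise), 1))
  expect_lt(max(abs(emp - want)), 0.02)
})

test_that("night answers rise and morning answers fall with latent stress", {
  co <- simulate_cohort(cohort_config(n_households = 3L, n_days = 15L,
                                      hr_sample_period = 300, seed = 13))
  m <- merge(co$answers, co$truth, by = c("subject_id", "date"))
  nq <- m[m$question == "NQ", ]
  expect_gt(cor(nq$latent_stress, nq$answer, method = "spearman"), 0.5)
  # the morning answer reflects the previous day's state
  mq <- m[m$question == "MQ", ]
  prev <- co$truth
  prev$date <- prev$date + 1L
  mq2 <- merge(co$answers[co$answers$question == "MQ", ], prev,
               by = c("subject_id", "date"))
  expect_lt(cor(mq2$latent_stress, mq2$answer, method = "spearman"), -0.5)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(cohort_config(stress_persistence = 1), "stress_persistence")
  expect_error(cohort_config(likert_thresholds = c(0.5, 0.4, 0.6, 0.7)),
               "likert_thresholds")
  expect_error(cohort_config(missingness = 1.2), "missingness")
  expect_error(cohort_config(dispersion_stress_effect = 1.5),
               "dispersion_stress_effect")
  expect_error(simulate_day("2022-01-01", 1.4), "latent_stress")
})
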