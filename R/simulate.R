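# Synthetic-cohort generator.
#
# Emulates the structure of a one-month in-home sensing study of elderly
# households (a mix of couples and singles): a latent daily physical-stress
# state per subject drives (a) the dispersion of R-R intervals within each
# activity (higher stress -> lower heart-rate variability), (b) mild shifts
# in how the day is allocated across activities, and (c) the morning/night
# five-point Likert questionnaire answers. Gendered activity-duration
# profiles reproduce the housework asymmetry that motivates gender-wise
# indicator normalisation. The generator is a study-condition definition,
# not a physiological simulator: see the methods vignette for what it does
# and does not emulate.

#' Configuration of a synthetic cohort
#'
#' All defaults describe the emulated study: five households (four couples
#' and one single, nine subjects), one month of data, a 15 s heart-rate
#' cadence and six activity labels.
#'
#' @param n_households Number of households.
#' @param singles_fraction Fraction of households with a single resident
#'   (rounded to a count).
#' @param n_days Days of data per household.
#' @param hr_sample_period Heart-rate cadence in seconds.
#' @param activities Ordered activity label set.
#' @param gender_duration_profiles Per-gender named vectors of mean daily
#'   minutes for the five waking activities; within-day allocation is drawn
#'   from a Dirichlet with these means as concentrations.
#' @param cooking_participation Per-gender probability that a subject cooks
#'   at all (non-cooks spend those minutes elsewhere); reproduces the
#'   "some men never cook" pattern.
#' @param stress_mean,stress_persistence,stress_innovation_sd AR(1)
#'   parameters of the latent daily stress state, clipped to `[0, 1]`.
#' @param rri_mean Named vector, mean RRI in ms per activity.
#' @param rri_dispersion Named vector, baseline RRI dispersion (sd, ms) per
#'   activity at zero stress.
#' @param dispersion_stress_effect In `[0, 1)`: within-activity dispersion is
#'   `rri_dispersion * (1 - effect * stress)`, strictly decreasing in stress
#'   whenever the effect is positive. 0 disables the biometric stress signal.
#' @param duration_stress_loadings Named vector of log-scale tilts applied to
#'   the Dirichlet concentrations as `exp(loading * effect * (stress - 0.5))`.
#' @param duration_stress_effect Scale of the duration channel; 0 disables it.
#' @param likert_thresholds Four strictly increasing cutpoints on latent
#'   stress defining the five answer bins.
#' @param answer_noise_sd Gaussian noise added to latent stress before
#'   binning an answer.
#' @param missingness Fraction of heart-rate samples dropped at random.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   full configuration.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_households = 5L,
                          singles_fraction = 0.2,
                          n_days = 30L,
                          hr_sample_period = 15,
                          activities = activity_levels(),
                          gender_duration_profiles = list(
                            F = c(bathing = 35, cooking = 110, eating = 100,
                                  going_out = 170, other = 545),
                            M = c(bathing = 30, cooking = 30, eating = 100,
                                  going_out = 260, other = 540)),
                          cooking_participation = c(F = 1, M = 0.5),
                          stress_mean = 0.38,
                          stress_persistence = 0.6,
                          stress_innovation_sd = 0.18,
                          rri_mean = c(bathing = 850, cooking = 750, eating = 800,
                                       going_out = 700, sleeping = 1000, other = 820),
                          rri_dispersion = c(bathing = 50, cooking = 35, eating = 40,
                                             going_out = 30, sleeping = 60, other = 45),
                          dispersion_stress_effect = 0.5,
                          duration_stress_loadings = c(bathing = 0.3, cooking = 0,
                                                       eating = 0, going_out = -1,
                                                       other = 0.7),
                          duration_stress_effect = 0.8,
                          likert_thresholds = c(0.25, 0.40, 0.60, 0.75),
                          answer_noise_sd = 0.10,
                          missingness = 0.02,
                          seed = 1L) {
  cfg <- list(n_households = as.integer(n_households),
              singles_fraction = singles_fraction, n_days = as.integer(n_days),
              hr_sample_period = hr_sample_period, activities = activities,
              gender_duration_profiles = gender_duration_profiles,
              cooking_participation = cooking_participation,
              stress_mean = stress_mean, stress_persistence = stress_persistence,
              stress_innovation_sd = stress_innovation_sd,
              rri_mean = rri_mean, rri_dispersion = rri_dispersion,
              dispersion_stress_effect = dispersion_stress_effect,
              duration_stress_loadings = duration_stress_loadings,
              duration_stress_effect = duration_stress_effect,
              likert_thresholds = likert_thresholds,
              answer_noise_sd = answer_noise_sd,
              missingness = missingness, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' @noRd
validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, why) if (!ok) stopf("invalid cohort_config field '%s': %s", field, why)
  chk(cfg$n_households >= 1L, "n_households", "must be >= 1")
  chk(cfg$singles_fraction >= 0 && cfg$singles_fraction <= 1, "singles_fraction", "must be in [0, 1]")
  chk(cfg$n_days >= 1L, "n_days", "must be >= 1")
  chk(cfg$hr_sample_period > 0, "hr_sample_period", "must be > 0 seconds")
  chk(all(c("sleeping") %in% cfg$activities), "activities", "must include 'sleeping'")
  day_acts <- setdiff(cfg$activities, "sleeping")
  for (g in c("F", "M")) {
    prof <- cfg$gender_duration_profiles[[g]]
    chk(!is.null(prof) && all(day_acts %in% names(prof)),
        "gender_duration_profiles", sprintf("gender '%s' must cover all waking activities", g))
    chk(all(prof >= 0), "gender_duration_profiles", "minutes must be >= 0")
  }
  chk(cfg$stress_persistence >= 0 && cfg$stress_persistence < 1,
      "stress_persistence", "must be in [0, 1)")
  chk(cfg$stress_innovation_sd >= 0, "stress_innovation_sd", "must be >= 0")
  chk(all(cfg$activities %in% names(cfg$rri_mean)), "rri_mean", "must cover all activities")
  chk(all(cfg$activities %in% names(cfg$rri_dispersion)), "rri_dispersion", "must cover all activities")
  chk(all(cfg$rri_dispersion >= 0), "rri_dispersion", "must be >= 0")
  chk(cfg$dispersion_stress_effect >= 0 && cfg$dispersion_stress_effect < 1,
      "dispersion_stress_effect", "must be in [0, 1)")
  chk(length(cfg$likert_thresholds) == 4L && all(diff(cfg$likert_thresholds) > 0),
      "likert_thresholds", "must be 4 strictly increasing cutpoints")
  chk(cfg$answer_noise_sd >= 0, "answer_noise_sd", "must be >= 0")
  chk(cfg$missingness >= 0 && cfg$missingness < 1, "missingness", "must be in [0, 1)")
  cfg
}

#' @noRd
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' @noRd
clip01 <- function(x) pmin(1, pmax(0, x))

#' Generate one Likert questionnaire answer from latent stress
#'
#' Gaussian noise is added to the latent stress and the result binned by the
#' four ordered thresholds into 1..5. The night question (NQ, "any physical
#' stress?") reports the bin directly, so it increases with stress; the
#' morning question (MQ, "feeling refreshed?") is reverse-coded (`6 - bin`).
#'
#' @param question `"MQ"` or `"NQ"`.
#' @param latent_stress Latent stress in `[0, 1]` (vectorised).
#' @param thresholds Four strictly increasing cutpoints.
#' @param noise_sd Answer noise standard deviation.
#' @return Integer answer(s) in 1..5. Draws from the caller's RNG stream.
#' @export
generate_answer <- function(question = c("NQ", "MQ"), latent_stress,
                            thresholds = c(0.25, 0.40, 0.60, 0.75),
                            noise_sd = 0.10) {
  question <- match.arg(question)
  if (any(diff(thresholds) <= 0)) stopf("thresholds must be strictly increasing")
  z <- latent_stress + stats::rnorm(length(latent_stress), 0, noise_sd)
  bin <- findInterval(z, thresholds) + 1L
  if (question == "MQ") 6L - bin else bin
}

#' @noRd
day_schedule <- function(date, wake, bed, prev_bed, gender, stress, prev_stress, cfg,
                         cooks = TRUE) {
  day_acts <- setdiff(cfg$activities, "sleeping")
  alpha <- cfg$gender_duration_profiles[[gender]][day_acts]
  if (!cooks && "cooking" %in% day_acts) alpha["cooking"] <- 0
  loads <- cfg$duration_stress_loadings[day_acts]
  loads[is.na(loads)] <- 0
  alpha <- alpha * exp(loads * cfg$duration_stress_effect * (stress - 0.5))
  keep <- alpha > 0
  p <- numeric(length(alpha))
  p[keep] <- rdirichlet1(alpha[keep])
  daylen <- as.numeric(bed) - as.numeric(wake)
  mins <- stats::setNames(p * daylen, day_acts)
  # fixed within-day template: morning cooking/eating, outing, evening
  # cooking/eating, bath, filler "other" blocks
  template <- list(c("cooking", 0.4), c("eating", 0.4), c("other", 0.3),
                   c("going_out", 1.0), c("other", 0.3), c("cooking", 0.6),
                   c("eating", 0.6), c("bathing", 1.0), c("other", 0.4))
  segs_lab <- vapply(template, `[[`, "", 1L)
  segs_len <- mins[segs_lab] * as.numeric(vapply(template, `[[`, "", 2L))
  ends <- as.numeric(wake) + cumsum(segs_len)
  starts <- c(as.numeric(wake), ends[-length(ends)])
  ends[length(ends)] <- as.numeric(bed)  # absorb rounding into the last block
  keep <- ends - starts >= 1
  day <- data.frame(start = starts[keep], end = ends[keep],
                    label = segs_lab[keep], stress = stress)
  night <- data.frame(start = as.numeric(prev_bed), end = as.numeric(wake),
                      label = "sleeping", stress = prev_stress)
  rbind(night, day)
}

#' Simulate one subject-day of intervals and heart-rate samples
#'
#' Exposed mainly for testing the generative links in isolation: given a
#' latent stress level it produces a day's activity intervals (overnight
#' sleeping anchored to the previous bedtime, waking activities tiling wake
#' to bedtime) and heart-rate samples on the configured cadence whose
#' underlying RRI dispersion decreases with stress within each activity.
#' Draws from the caller's RNG stream; wrap in a seeded context for
#' reproducibility.
#'
#' @param date Day being simulated (`Date` or string).
#' @param latent_stress Stress level in `[0, 1]` for this day.
#' @param gender `"F"` or `"M"`.
#' @param config A [cohort_config()].
#' @param wake,bed Wake and bedtime instants of the day (defaults 07:00 and
#'   23:00).
#' @param prev_bed Previous night's bedtime (defaults 23:00 the day before).
#' @param prev_stress Stress of the previous day (defaults to
#'   `latent_stress`); the overnight sleeping interval carries it.
#' @return List with `intervals` (start, end, label) and `hr` (timestamp,
#'   bpm) data frames; samples cover the calendar day `[00:00, 24:00)`.
#' @export
simulate_day <- function(date, latent_stress, gender = "F", config = cohort_config(),
                         wake = NULL, bed = NULL, prev_bed = NULL,
                         prev_stress = latent_stress) {
  if (latent_stress < 0 || latent_stress > 1) stopf("latent_stress must be in [0, 1]")
  day0 <- as.numeric(as_instant(as_day(date)))
  wake <- if (is.null(wake)) day0 + 7 * 3600 else as.numeric(as_instant(wake))
  bed <- if (is.null(bed)) day0 + 23 * 3600 else as.numeric(as_instant(bed))
  prev_bed <- if (is.null(prev_bed)) day0 - 3600 else as.numeric(as_instant(prev_bed))
  sched <- day_schedule(date, wake, bed, prev_bed, gender,
                        latent_stress, prev_stress, config)
  # trailing sleep so the calendar day is fully covered
  sched <- rbind(sched, data.frame(start = bed, end = day0 + 86400 + 7 * 3600,
                                   label = "sleeping", stress = latent_stress))
  hr <- sample_heart_rate(sched, day0, day0 + 86400, config)
  list(intervals = data.frame(start = as_instant(sched$start),
                              end = as_instant(sched$end),
                              label = sched$label),
       hr = hr)
}

#' @noRd
sample_heart_rate <- function(sched, from, to, cfg) {
  ts <- seq(from, to - cfg$hr_sample_period, by = cfg$hr_sample_period)
  idx <- findInterval(ts, sched$start)
  inside <- idx >= 1L & ts < sched$end[pmax(idx, 1L)]
  lab <- rep(NA_character_, length(ts))
  str <- rep(NA_real_, length(ts))
  lab[inside] <- sched$label[idx[inside]]
  str[inside] <- sched$stress[idx[inside]]
  keep <- !is.na(lab)
  ts <- ts[keep]; lab <- lab[keep]; str <- str[keep]
  mu <- cfg$rri_mean[lab]
  sdv <- cfg$rri_dispersion[lab] * (1 - cfg$dispersion_stress_effect * str)
  rri <- stats::rnorm(length(ts), mean = mu, sd = sdv)
  rri <- pmin(2000, pmax(300, rri))
  data.frame(timestamp = as_instant(ts), bpm = round(60000 / rri, 2))
}

#' Simulate a synthetic cohort
#'
#' Generates subjects (couples share a household clock but have independent
#' physiology), one month of activity logs and heart-rate samples, the
#' morning/night questionnaire answers, and the latent stress ground truth
#' (kept separate; it must never enter the feature-facing files).
#'
#' The morning answer of day *d* is generated from the previous day's latent
#' stress (the morning question asks about the night just ended, whose data
#' the morning feature windows cover); the night answer of day *d* uses day
#' *d*'s stress.
#'
#' @param config A [cohort_config()].
#' @param seed Overrides `config$seed` when given.
#' @return Object of class `stress_cohort`: list with data frames
#'   `subjects`, `heart_rate`, `activities`, `answers`, `truth`, plus the
#'   `config`. Deterministic in (config, seed).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  cfg <- validate_cohort_config(config)
  with_seed(seed, {
    n_singles <- round(cfg$singles_fraction * cfg$n_households)
    subjects <- list(); hh <- character(0)
    sid <- 0L
    for (h in seq_len(cfg$n_households)) {
      hid <- sprintf("H%d", h)
      genders <- if (h <= n_singles) sample(c("F", "M"), 1L) else c("F", "M")
      for (g in genders) {
        sid <- sid + 1L
        subjects[[sid]] <- data.frame(subject_id = sprintf("S%02d", sid),
                                      gender = g, household_id = hid)
      }
    }
    subjects <- do.call(rbind, subjects)
    base_date <- as.Date("2022-01-01")
    dates <- base_date + seq_len(cfg$n_days) - 1L

    # shared household clock: wake/bed times per household-day
    clock <- list()
    for (h in unique(subjects$household_id)) {
      wk <- as.numeric(as_instant(dates)) + 7 * 3600 + round(stats::rnorm(cfg$n_days, 0, 1200))
      bd <- as.numeric(as_instant(dates)) + 23 * 3600 + round(stats::rnorm(cfg$n_days, 0, 1200))
      bd0 <- as.numeric(as_instant(base_date)) - 3600 + round(stats::rnorm(1, 0, 1200))
      clock[[h]] <- list(wake = wk, bed = bd, bed0 = bd0)
    }

    hr_all <- list(); act_all <- list(); ans_all <- list(); truth_all <- list()
    stat_sd <- cfg$stress_innovation_sd / sqrt(max(1e-12, 1 - cfg$stress_persistence^2))
    for (i in seq_len(nrow(subjects))) {
      sj <- subjects[i, ]
      ck <- clock[[sj$household_id]]
      cooks <- sj$gender == "F" || stats::runif(1) < cfg$cooking_participation[[sj$gender]]
      # latent AR(1) stress, day 0 from the stationary distribution
      s <- numeric(cfg$n_days + 1L)
      s[1L] <- clip01(stats::rnorm(1, cfg$stress_mean, stat_sd))
      for (d in seq_len(cfg$n_days))
        s[d + 1L] <- clip01(cfg$stress_mean +
                              cfg$stress_persistence * (s[d] - cfg$stress_mean) +
                              stats::rnorm(1, 0, cfg$stress_innovation_sd))
      sched_all <- list()
      for (d in seq_len(cfg$n_days)) {
        prev_bed <- if (d == 1L) ck$bed0 else ck$bed[d - 1L]
        sched_all[[d]] <- day_schedule(dates[d], ck$wake[d], ck$bed[d], prev_bed,
                                       sj$gender, s[d + 1L], s[d], cfg, cooks = cooks)
      }
      sched <- do.call(rbind, sched_all)
      # trailing sleep covering the final night
      sched <- rbind(sched,
                     data.frame(start = ck$bed[cfg$n_days],
                                end = as.numeric(as_instant(dates[cfg$n_days] + 1L)) + 7 * 3600,
                                label = "sleeping", stress = s[cfg$n_days + 1L]))
      from <- as.numeric(as_instant(dates[1L]))
      to <- as.numeric(as_instant(dates[cfg$n_days] + 1L))
      hr <- sample_heart_rate(sched, from, to, cfg)
      if (cfg$missingness > 0) {
        drop <- stats::runif(nrow(hr)) < cfg$missingness
        hr <- hr[!drop, , drop = FALSE]
      }
      hr_all[[i]] <- cbind(subject_id = sj$subject_id, hr)
      act_all[[i]] <- data.frame(subject_id = sj$subject_id,
                                 start = as_instant(sched$start),
                                 end = as_instant(sched$end),
                                 label = sched$label)
      mq <- vapply(seq_len(cfg$n_days), function(d)
        generate_answer("MQ", s[d], cfg$likert_thresholds, cfg$answer_noise_sd), 0L)
      nq <- vapply(seq_len(cfg$n_days), function(d)
        generate_answer("NQ", s[d + 1L], cfg$likert_thresholds, cfg$answer_noise_sd), 0L)
      ans_all[[i]] <- data.frame(
        subject_id = sj$subject_id,
        date = rep(dates, 2L),
        question = rep(c("MQ", "NQ"), each = cfg$n_days),
        answer = c(mq, nq),
        answered_at = as_instant(c(ck$wake, ck$bed)))
      truth_all[[i]] <- data.frame(subject_id = sj$subject_id, date = dates,
                                   latent_stress = s[-1L])
    }
    cohort <- list(subjects = subjects,
                   heart_rate = do.call(rbind, hr_all),
                   activities = do.call(rbind, act_all),
                   answers = do.call(rbind, ans_all),
                   truth = do.call(rbind, truth_all),
                   config = cfg)
    rownames(cohort$heart_rate) <- rownames(cohort$activities) <-
      rownames(cohort$answers) <- rownames(cohort$truth) <- NULL
    class(cohort) <- "stress_cohort"
    cohort
  })
}

#' @export
print.stress_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic stress cohort: %d subjects in %d households, %d days\n",
                     "  heart-rate samples: %d   activity intervals: %d   answers: %d\n"),
              nrow(x$subjects), length(unique(x$subjects$household_id)),
              x$config$n_days, nrow(x$heart_rate), nrow(x$activities), nrow(x$answers)))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Emits `subjects.csv`, `heart_rate.csv`, `activities.csv`, `answers.csv`
#' and — separately, for tests only — `cohort_truth.csv` with the latent
#' stress ground truth. The truth never enters the feature-facing files.
#'
#' @param cohort A `stress_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name, stamp_cols = character(0)) {
    for (cc in stamp_cols) df[[cc]] <- fmt_instant(df[[cc]])
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  w(cohort$subjects, "subjects.csv")
  w(cohort$heart_rate, "heart_rate.csv", "timestamp")
  w(cohort$activities, "activities.csv", c("start", "end"))
  ans <- cohort$answers; ans$date <- format(ans$date)
  w(ans, "answers.csv", "answered_at")
  tr <- cohort$truth; tr$date <- format(tr$date)
  w(tr, "cohort_truth.csv")
  invisible(dir)
}

#' Read a cohort from CSV files written by [write_cohort()]
#'
#' @param dir Directory with the cohort CSVs.
#' @return A `stress_cohort` (with `truth` only if `cohort_truth.csv` exists).
#' @export
read_cohort <- function(dir) {
  cohort <- list(
    subjects = load_subjects(file.path(dir, "subjects.csv")),
    heart_rate = load_heart_rate(file.path(dir, "heart_rate.csv")),
    activities = load_activity_log(file.path(dir, "activities.csv")),
    answers = load_answers(file.path(dir, "answers.csv")),
    truth = NULL, config = NULL)
  tp <- file.path(dir, "cohort_truth.csv")
  if (file.exists(tp)) {
    tr <- utils::read.csv(tp, stringsAsFactors = FALSE)
    tr$date <- as_day(tr$date)
    cohort$truth <- tr
  }
  class(cohort) <- "stress_cohort"
  cohort
}
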