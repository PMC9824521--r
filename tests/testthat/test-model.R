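test_that("likert answers map to stress classes with question polarity", {
  expect_equal(as.character(map_likert(5, "MQ")), "good")
  expect_equal(as.character(map_likert(1, "MQ")), "bad")
  expect_equal(as.character(map_likert(3, "MQ")), "neutral")
  expect_equal(as.character(map_likert(5, "NQ")), "bad")
  expect_equal(as.character(map_likert(1, "NQ")), "good")
  expect_equal(as.character(map_likert(c(1, 5), c("MQ", "NQ"))), c("bad", "bad"))
  expect_error(map_likert(0, "MQ"), "1..5")
  expect_error(map_likert(2, "XQ"), "XQ")
})

sim_xy <- function(n_bad = 30, n_neutral = 60, n_good = 210, sd = 1, seed = 5) {
  set.seed(seed)
  y <- factor(rep(c("bad", "neutral", "good"), c(n_bad, n_neutral, n_good)),
              levels = stress_levels())
  x <- cbind(f1 = as.numeric(y) + rnorm(length(y), 0, sd),
             f2 = rnorm(length(y)))
  list(x = x, y = y)
}

test_that("SMOTE tops classes up to their exact targets", {
  d <- sim_xy()
  set.seed(0)
  out <- smote(d$x, d$y, targets = c(bad = 100, neutral = 100, good = 200))
  tab <- table(out$y)
  expect_equal(unname(tab["bad"]), 100L)
  expect_equal(unname(tab["neutral"]), 100L)
  expect_equal(unname(tab["good"]), 210L)  # above target: untouched
  expect_message(smote(d$x, d$y, targets = c(good = 100)), "above its SMOTE target")
  # synthetic rows interpolate within the class: f1 stays inside the class range
  newb <- out$x[seq(nrow(d$x) + 1, length.out = 70), "f1"]
  rng <- range(d$x[d$y == "bad", "f1"])
  expect_true(all(newb >= rng[1] & newb <= rng[2]))
  # tiny class degrades to resampling with replacement
  d2 <- list(x = d$x[c(1:2, 31:100), ], y = droplevels(d$y[c(1:2, 31:100)]))
  expect_message(out2 <- smote(d2$x, d2$y, targets = c(bad = 10)), "degrading")
  expect_equal(sum(out2$y == "bad"), 10L)
})

test_that("undersampling balances classes at the minority count", {
  d <- sim_xy()
  set.seed(1)
  u <- random_undersample(d$x, d$y)
  expect_true(all(table(u$y) == 30))
})

test_that("ensemble fits are exactly reproducible and separable data are learned", {
  d <- sim_xy(sd = 0.01)
  m1 <- suppressMessages(stress_ensemble(d$x, d$y))
  m2 <- suppressMessages(stress_ensemble(d$x, d$y))
  expect_identical(predict(m1, d$x, type = "votes"),
                   predict(m2, d$x, type = "votes"))
  expect_equal(length(m1$members), 10L)
  expect_equal(vapply(m1$members, `[[`, 0, "seed"), 1:10)
  # near-noiseless class-coded feature: training accuracy 1
  expect_equal(accuracy(d$y, predict(m1, d$x)), 1)

  nm <- stress_ensemble(d$x, d$y, scheme = "not_manipulated")
  expect_length(nm$members, 1L)
  # balanced separable data: resampling changes nothing
  bal <- sim_xy(100, 100, 100, sd = 0.01)
  p1 <- predict(stress_ensemble(bal$x, bal$y, scheme = "not_manipulated"), bal$x)
  p2 <- predict(suppressMessages(stress_ensemble(bal$x, bal$y)), bal$x)
  expect_equal(p1, p2)

  expect_error(stress_ensemble(d$x, factor(rep("good", nrow(d$x)),
                                           levels = stress_levels())),
               "single class")
})

test_that("majority voting counts members and breaks ties toward bad", {
  x <- matrix(0, 3, 1, dimnames = list(NULL, "f1"))
  m <- mock_ensemble(rep(c("good", "bad"), c(6, 4)))
  expect_equal(as.character(predict(m, x)), rep("good", 3))
  v <- predict(m, x, type = "votes")
  expect_equal(unname(v[1, ]), c(4, 0, 6))
  # 5-5 tie resolves to the costlier class
  tie <- mock_ensemble(rep(c("bad", "good"), c(5, 5)))
  expect_equal(as.character(predict(tie, x)), rep("bad", 3))
  tie2 <- mock_ensemble(rep(c("neutral", "good"), c(5, 5)))
  expect_equal(as.character(predict(tie2, x)), rep("neutral", 3))
})

test_that("vote matrices equal an external member-harvesting oracle", {
  d <- sim_xy(40, 60, 100, sd = 0.6, seed = 9)
  m <- suppressMessages(stress_ensemble(d$x, d$y))
  votes <- predict(m, d$x, type = "votes")
  xi <- d$x
  for (j in seq_len(ncol(xi))) xi[is.na(xi[, j]), j] <- m$medians[j]
  oracle <- matrix(0L, nrow(d$x), 3, dimnames = list(NULL, stress_levels()))
  for (mem in m$members) {
    p <- member_vote(mem$forest, xi)
    for (i in seq_along(p)) oracle[i, p[i]] <- oracle[i, p[i]] + 1L
  }
  expect_equal(unname(votes), unname(oracle))
  # majority of the oracle votes equals predict()'s classes
  maj <- stress_levels()[max.col(oracle, ties.method = "first")]
  expect_equal(as.character(predict(m, d$x)), maj)
})

test_that("permuting member seeds permutes members but not the vote multiset", {
  d <- sim_xy(40, 60, 100, sd = 0.6, seed = 10)
  cfg1 <- resampling_config(under_seeds = 1:10)
  cfg2 <- resampling_config(under_seeds = 10:1)
  v1 <- predict(suppressMessages(stress_ensemble(d$x, d$y, config = cfg1)), d$x,
                type = "votes")
  v2 <- predict(suppressMessages(stress_ensemble(d$x, d$y, config = cfg2)), d$x,
                type = "votes")
  expect_equal(v1, v2)  # counts are order-free
})

test_that("prediction validates the feature manifest", {
  d <- sim_xy(sd = 0.5)
  m <- suppressMessages(stress_ensemble(d$x, d$y))
  bad <- d$x
  colnames(bad) <- c("f1", "other")
  expect_error(predict(m, bad), "other")
  expect_error(predict(m, d$x[, 1, drop = FALSE]), "f2")
})

test_that("missing features are imputed with training medians", {
  d <- sim_xy(sd = 0.2)
  d$x[c(3, 50, 200), "f2"] <- NA
  m <- suppressMessages(stress_ensemble(d$x, d$y))
  expect_equal(unname(m$medians["f2"]),
               median(d$x[, "f2"], na.rm = TRUE))
  expect_silent(p <- predict(m, d$x))
  expect_false(anyNA(p))
})
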