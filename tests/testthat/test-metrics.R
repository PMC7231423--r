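# Metric suite, rate inversion and model evaluation.

test_that("computeMetrics reproduces hand-evaluated cases", {
  perfect <- computeMetrics(confusionCounts(50, 50, 0, 0))
  expect_identical(c(perfect@accuracy, perfect@precision, perfect@recall,
                     perfect@mcor), c(1, 1, 1, 1))

  chance <- computeMetrics(confusionCounts(25, 25, 25, 25))
  expect_identical(chance@accuracy, 0.5)
  expect_identical(chance@mcor, 0)

  r <- computeMetrics(confusionCounts(40, 45, 5, 10))
  expect_equal(r@accuracy, 0.85)
  expect_equal(r@precision, 40 / 45)
  expect_equal(r@recall, 0.8)
  expect_equal(r@mcor, (40 * 45 - 5 * 10) / sqrt(45 * 50 * 50 * 55))
})

test_that("zero denominators report 0 with a note instead of failing", {
  expect_message(r <- computeMetrics(confusionCounts(0, 90, 0, 10)),
                 "precision")
  expect_identical(r@precision, 0)
  expect_identical(r@recall, 0)
  expect_identical(r@mcor, 0)
  expect_error(confusionCounts(-1, 10, 0, 0), "nonnegative")
})

test_that("computeMetrics agrees with an independent implementation on random counts", {
  withr::with_seed(17, {
    for (i in 1:1000) {
      cnt <- rmultinom(1, sample(10:500, 1), prob = runif(4, 0.05, 1))[, 1]
      got <- suppressMessages(
        computeMetrics(confusionCounts(cnt[1], cnt[2], cnt[3], cnt[4])))
      ref <- refMetrics(cnt[1], cnt[2], cnt[3], cnt[4])
      expect_lt(abs(got@accuracy - ref["accuracy"]), 1e-9)
      expect_lt(abs(got@precision - ref["precision"]), 1e-9)
      expect_lt(abs(got@recall - ref["recall"]), 1e-9)
      expect_lt(abs(got@mcor - ref["mcor"]), 1e-9)
      expect_gte(got@mcor, -1)
      expect_lte(got@mcor, 1)
    }
  })
})

test_that("mcor vanishes whenever TP*TN equals FP*FN", {
  expect_identical(computeMetrics(confusionCounts(6, 6, 4, 9))@mcor, 0)
  expect_identical(computeMetrics(confusionCounts(8, 3, 6, 4))@mcor, 0)
})

test_that("rate inversion recovers the original counts", {
  inv <- confusionFromRates(1, 1, 1, N = 100, prevalence = 0.5)
  expect_equal(c(inv$counts@tp, inv$counts@tn, inv$counts@fp,
                 inv$counts@fn), c(50, 50, 0, 0))
  expect_equal(inv$residual, 0)

  back <- confusionFromRates(0.85, 0.8, 40 / 45, N = 100,
                             prevalence = 0.5)
  expect_equal(c(back$counts@tp, back$counts@fp, back$counts@tn,
                 back$counts@fn), c(40, 5, 45, 10), tolerance = 1e-9)

  expect_error(confusionFromRates(0.1, 0.99, 0.99, 100, 0.5), "negative")
  expect_error(confusionFromRates(0, 0.5, 0.5, 100, 0.5), "\\(0, 1\\]")
})

test_that("metrics -> rates -> counts -> metrics round-trips to 1e-9", {
  withr::with_seed(19, {
    ok <- 0
    for (i in 1:500) {
      cnt <- rmultinom(1, sample(20:2000, 1), prob = runif(4, 0.1, 1))[, 1]
      if (any(cnt == 0)) next
      ok <- ok + 1
      n <- sum(cnt)
      m1 <- computeMetrics(confusionCounts(cnt[1], cnt[2], cnt[3], cnt[4]))
      inv <- confusionFromRates(m1@accuracy, m1@recall, m1@precision,
                                N = n, prevalence = (cnt[1] + cnt[4]) / n)
      m2 <- computeMetrics(inv$counts)
      expect_lt(abs(m1@mcor - m2@mcor), 1e-9)
      expect_lt(abs(m1@accuracy - m2@accuracy), 1e-9)
      expect_lt(inv$residual, 1e-6)
    }
    expect_gt(ok, 400)
  })
})

test_that("evaluation counts are integers conserving the test-set size", {
  ds <- fixtureSmallSet()
  sp <- splitDataset(ds, seed = 6)
  m <- buildModel(modelSpec("tiny_random", c(16, 16)), seed = 6)
  fit <- trainModel(m, ds, sp, resnetTrainConfig(maxEpochs = 3, seed = 6))
  ev <- suppressMessages(evaluateModel(fit$model, ds, testIdx(sp)))
  cnt <- c(ev$counts@tp, ev$counts@tn, ev$counts@fp, ev$counts@fn)
  expect_identical(cnt, round(cnt))
  expect_identical(sum(cnt), as.numeric(length(testIdx(sp))))
  expect_true(is.finite(ev$report@loss))
  expect_error(evaluateModel(fit$model, ds, integer()), "empty")
})

test_that("an all-negative predictor on a balanced set scores recall 0, accuracy 0.5", {
  r <- suppressMessages(computeMetrics(confusionCounts(0, 50, 0, 50)))
  expect_identical(r@recall, 0)
  expect_identical(r@accuracy, 0.5)
})

test_that("repeated runs return per-run reports plus their arithmetic mean", {
  ds <- fixtureSmallSet()
  out <- suppressMessages(
    evaluateRepeated(ds, modelSpec("tiny_random", c(16, 16)),
                     resnetTrainConfig(maxEpochs = 3, seed = 100), k = 2))
  expect_length(out$perRun, 2L)
  expect_equal(out$mean[["accuracy"]],
               mean(vapply(out$perRun, function(r) r@accuracy, 0)))
  expect_equal(out$mean[["mcor"]],
               mean(vapply(out$perRun, function(r) r@mcor, 0)))
})

test_that("metric writers emit readable JSON and table-shaped CSV", {
  rep <- computeMetrics(confusionCounts(40, 45, 5, 10), loss = 0.12)
  f <- withr::local_tempfile(fileext = ".json")
  writeMetricsJSON(rep, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$accuracy, 0.85)
  expect_equal(j$loss, 0.12)

  rows <- data.frame(model = "tiny_random", fc_size = "16x16",
                     loss = 0.1, accuracy = 0.9, recall = 0.9,
                     precision = 0.9, mcor = 0.8)
  g <- withr::local_tempfile(fileext = ".csv")
  writeMetricsTableCSV(rows, g)
  expect_identical(names(utils::read.csv(g)),
                   c("model", "fc_size", "loss", "accuracy", "recall",
                     "precision", "mcor"))
})
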