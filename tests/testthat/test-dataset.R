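# Dataset assembly and the shuffled 60/20/20 split.

test_that("dataset counts equal the sum of the segmentation closed forms", {
  rec <- fixtureRecord600()                 # 600 s, one 40 s seizure
  ds <- buildDataset(list(rec))
  nSlide <- as.integer(floor((600 - 180) / 126) + 1)    # 4
  nAug <- 38L
  expect_identical(length(ds), nSlide + nAug)
  expect_identical(sum(imageManifest(ds)$source == "sliding"), nSlide)
  expect_identical(sum(imageManifest(ds)$source == "augment"), nAug)
})

test_that("a seizure-free record yields all-negative sliding images only", {
  rec <- generateRecord(synthConfig(durationS = 500, seed = 21))
  ds <- buildDataset(list(rec))
  expect_true(all(imageLabels(ds) == 0L))
  expect_true(all(imageManifest(ds)$source == "sliding"))
  expect_identical(classBalance(ds), 0)
})

test_that("two identical records give exactly twice the single-record dataset", {
  rec <- generateRecord(synthConfig(durationS = 400,
                                    seizures = seizureTable(100, 110),
                                    seed = 22))
  one <- buildDataset(list(rec))
  two <- buildDataset(list(rec, rec))
  expect_identical(length(two), 2L * length(one))
  expect_identical(imageLabels(two), rep(imageLabels(one), 2L))
  expect_identical(two@images[[length(one) + 1L]], one@images[[1L]])
})

test_that("records missing a required channel are skipped with a warning", {
  good <- generateRecord(synthConfig(durationS = 200, seed = 23))
  bad <- EEGRecord(matrix(0, 256 * 200, 2), c("FP2-F8", "F8-T8"),
                   fs = 256, subjectId = "incomplete")
  expect_warning(ds <- buildDataset(list(good, bad)), "incomplete")
  expect_identical(ds@metadata$skippedRecords, "incomplete")
  expect_identical(unique(imageManifest(ds)$record_ref), "synth")
})

test_that("manifest labels can be recomputed independently from the intervals", {
  rec <- fixtureRecord600()
  ds <- buildDataset(list(rec))
  m <- imageManifest(ds)
  relabel <- vapply(seq_len(nrow(m)), function(i) {
    ov <- pmin(m$start_s[i] + m$length_s[i], seizureIntervals(rec)$t2) -
      pmax(m$start_s[i], seizureIntervals(rec)$t1)
    as.integer(any(ov > 0))
  }, 0L)
  expect_identical(imageLabels(ds), relabel)
})

test_that("splits have round(f*N) sizes, partition the indices and are seeded", {
  sp <- splitDataset(1000, seed = 1)
  expect_identical(lengths(list(trainIdx(sp), valIdx(sp), testIdx(sp))),
                   c(600L, 200L, 200L))
  sp10 <- splitDataset(10, seed = 4)
  expect_identical(lengths(list(trainIdx(sp10), valIdx(sp10),
                                testIdx(sp10))), c(6L, 2L, 2L))
  expect_setequal(c(trainIdx(sp10), valIdx(sp10), testIdx(sp10)), 1:10)

  expect_identical(trainIdx(splitDataset(1000, seed = 7)),
                   trainIdx(splitDataset(1000, seed = 7)))
  expect_false(identical(trainIdx(splitDataset(1000, seed = 7)),
                         trainIdx(splitDataset(1000, seed = 8))))
  expect_error(splitDataset(100, fractions = c(0.6, 0.3, 0.2)), "sum")
})

test_that("split indices partition 1..N for random sizes and seeds", {
  withr::with_seed(9, {
    for (i in 1:100) {
      n <- sample(3:5000, 1)
      seed <- sample.int(1e6, 1)
      sp <- splitDataset(n, seed = seed)
      idx <- c(trainIdx(sp), valIdx(sp), testIdx(sp))
      expect_identical(sort(idx), seq_len(n))
      expect_identical(length(trainIdx(sp)), as.integer(round(0.6 * n)))
      expect_identical(length(valIdx(sp)), as.integer(round(0.2 * n)))
    }
  })
})

test_that("shuffling leaves the class balance unchanged", {
  ds <- fixtureSmallSet()
  sp <- splitDataset(ds, seed = 2)
  labs <- imageLabels(ds)
  expect_identical(mean(labs[c(trainIdx(sp), valIdx(sp), testIdx(sp))]),
                   classBalance(ds))
})

test_that("split JSON and manifest CSV round-trip", {
  sp <- splitDataset(50, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  writeSplitJSON(sp, f)
  back <- readSplitJSON(f)
  expect_identical(trainIdx(back), trainIdx(sp))
  expect_identical(testIdx(back), testIdx(sp))

  ds <- fixtureSmallSet()
  g <- withr::local_tempfile(fileext = ".csv")
  writeManifestCSV(ds, g)
  m <- utils::read.csv(g)
  expect_identical(nrow(m), length(ds))
  expect_identical(as.integer(m$label), imageLabels(ds))
})

test_that("leave-subject-out split keeps whole subjects in the test set", {
  ds <- fixtureSmallSet()
  refs <- unique(imageManifest(ds)$record_ref)
  sp <- leaveSubjectOutSplit(ds, refs[1])
  expect_setequal(imageManifest(ds)$record_ref[testIdx(sp)], refs[1])
  expect_false(refs[1] %in%
                 imageManifest(ds)$record_ref[c(trainIdx(sp), valIdx(sp))])
  expect_setequal(c(trainIdx(sp), valIdx(sp), testIdx(sp)),
                  seq_len(length(ds)))
})
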