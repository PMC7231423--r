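# EDF read/write and CHB-MIT-style annotation parsing.

test_that("EDF round-trip preserves channels, rate and samples to 16-bit tolerance", {
  rec <- generateRecord(synthConfig(durationS = 60, seed = 2))
  f <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, f)
  back <- readEDF(f, c("FP2-F8", "F8-T8", "T8-P8"))

  expect_identical(channelLabels(back), c("FP2-F8", "F8-T8", "T8-P8"))
  expect_identical(samplingRate(back), 256)
  expect_identical(dim(signalMatrix(back)), c(15360L, 3L))

  quantStep <- apply(signalMatrix(rec), 2, function(x) diff(range(x))) / 65535
  err <- abs(signalMatrix(rec) - signalMatrix(back))
  for (j in 1:3) expect_lt(max(err[, j]), quantStep[j] * 1.01)
})

test_that("readEDF returns channels in the requested order and errors on absent labels", {
  rec <- generateRecord(synthConfig(durationS = 10, seed = 3))
  f <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, f)

  reordered <- readEDF(f, c("T8-P8", "FP2-F8"))
  expect_identical(channelLabels(reordered), c("T8-P8", "FP2-F8"))
  expect_equal(signalMatrix(reordered)[, 2], signalMatrix(rec)[, 1],
               tolerance = 1e-2)

  expect_error(readEDF(f, "XX-YY"), "XX-YY")
  expect_error(readEDF(tempfile(), "FP2-F8"), "not found")
})

test_that("readEDF decodes a hand-constructed EDF byte stream", {
  # Built with raw writeBin from the published format, independent of
  # writeEDF: 1 signal, 4 Hz, 2 one-second records, physical range
  # [-100, 100] over digital [-32768, 32767].
  f <- withr::local_tempfile(fileext = ".edf")
  con <- file(f, "wb")
  pad <- function(x, w) formatC(as.character(x), width = -w)
  writeChar(paste0(pad("0", 8), pad("subj", 80), pad("rec", 80),
                   pad("01.01.20", 8), pad("00.00.00", 8), pad(512, 8),
                   pad("", 44), pad(2, 8), pad(1, 8), pad(1, 4)),
            con, eos = NULL)
  writeChar(paste0(pad("FP2-F8", 16), pad("", 80), pad("uV", 8),
                   pad(-100, 8), pad(100, 8), pad(-32768, 8),
                   pad(32767, 8), pad("", 80), pad(4, 8), pad("", 32)),
            con, eos = NULL)
  dig <- as.integer(round((c(0, 50, -50, 100, -100, 25, -25, 0) + 100) /
                            200 * 65535) - 32768)
  writeBin(dig, con, size = 2L, endian = "little")
  close(con)

  rec <- readEDF(f, "FP2-F8")
  expect_identical(samplingRate(rec), 4)
  expect_equal(as.vector(signalMatrix(rec)),
               c(0, 50, -50, 100, -100, 25, -25, 0), tolerance = 0.01)
})

test_that("referential channels are subtracted when no stored bipolar channel exists", {
  sig <- cbind(sin(1:512 / 10) * 40, cos(1:512 / 15) * 30)
  rec <- EEGRecord(sig, c("FP2", "F8"), fs = 256, subjectId = "ref")
  f <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, f)
  der <- readEDF(f, "FP2-F8")
  expect_equal(as.vector(signalMatrix(der)), sig[, 1] - sig[, 2],
               tolerance = 0.01)
})

test_that("summary parser extracts sorted intervals and handles seizure-free records", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "Data Sampling Rate: 256 Hz",
    "",
    "File Name: chb05_06.edf   ",
    "Number of Seizures in File: 1",
    "Seizure Start Time: 1732 seconds  ",
    "Seizure End Time: 1772 seconds",
    "",
    "",
    "File Name: chb05_13.edf",
    "Number of Seizures in File: 0",
    "",
    "File Name: chb05_06.edf",
    "Number of Seizures in File: 1",
    "Seizure 1 Start Time: 417 seconds",
    "Seizure 1 End Time: 532 seconds"), f)

  two <- readChbmitAnnotations(f, "chb05_06.edf")
  expect_equal(two, seizureTable(c(417, 1732), c(532, 1772)))
  expect_identical(nrow(readChbmitAnnotations(f, "chb05_13.edf")), 0L)
  expect_error(readChbmitAnnotations(f, "chb99_01.edf"), "not found")
})

test_that("malformed annotation blocks fail with a line number", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("File Name: a.edf",
               "Seizure Start Time: 100 seconds",
               "Seizure End Time: 90 seconds"), f)
  expect_error(readChbmitAnnotations(f, "a.edf"), "line 3")

  writeLines(c("File Name: a.edf",
               "Seizure Start Time: 100 seconds"), f)
  expect_error(readChbmitAnnotations(f, "a.edf"), "without a matching end")
})

test_that("summary writer output round-trips through the parser", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeChbmitSummary(f, list("synth.edf" = seizureTable(c(100, 300),
                                                        c(140, 360))))
  expect_equal(readChbmitAnnotations(f, "synth.edf"),
               seizureTable(c(100, 300), c(140, 360)))
})
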