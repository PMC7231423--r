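# Pooling records into one shuffled image dataset and splitting it.

#' Build the pooled cross-subject image dataset
#'
#' For each record, emits the step-one sliding-window images (labeled by
#' seizure overlap) and the step-two augmentation images for every seizure
#' interval, all fused from the three bipolar channels FP2-F8, F8-T8,
#' T8-P8. Images from all records are pooled with no per-subject
#' partitioning; the manifest records provenance per image.
#'
#' @param records list of [EEGRecord-class] objects.
#' @param stft an [StftConfig-class].
#' @param lengthS,overlapFrac step-one window length and overlap.
#' @param stepS,minOverlapS step-two stride and minimum seizure overlap.
#' @param channels the three channel labels to fuse, in RGB order.
#' @return a [TFImageSet-class]. Records missing a required channel are
#'   skipped with a warning and listed in \code{metadata$skippedRecords}.
#' @examples
#' rec <- generateRecord(synthConfig(durationS = 600,
#'                                   seizures = seizureTable(100, 140)))
#' ds <- buildDataset(list(rec))
#' length(ds); classBalance(ds)
#' @export
buildDataset <- function(records, stft = stftConfig(), lengthS = 180,
                         overlapFrac = 0.30, stepS = 1, minOverlapS = 3,
                         channels = TF_CHANNEL_ORDER) {
  images <- list(); manifests <- list(); skipped <- character()
  for (rec in records) {
    if (!all(channels %in% channelLabels(rec))) {
      warning(sprintf(
        "record '%s' lacks channel(s) %s; skipped", subjectId(rec),
        paste(setdiff(channels, channelLabels(rec)), collapse = ", ")))
      skipped <- c(skipped, subjectId(rec))
      next
    }
    ci <- match(channels, channelLabels(rec))
    win <- segmentSliding(rec, lengthS, overlapFrac)
    sz <- seizureIntervals(rec)
    for (k in seq_len(nrow(sz)))
      win <- rbind(win, segmentSeizureAugment(rec, sz[k, ], lengthS,
                                              stepS, minOverlapS))
    if (!nrow(win)) next
    imgs <- lapply(seq_len(nrow(win)), function(i) {
      seg <- extractSegment(rec, win$start_s[i], lengthS)[, ci, drop = FALSE]
      toTFImage(seg, stft, label = win$label[i],
                provenance = list(record_ref = win$record_ref[i],
                                  start_s = win$start_s[i],
                                  source = win$source[i]))@pixels
    })
    images <- c(images, imgs)
    manifests[[length(manifests) + 1L]] <- win
  }
  manifest <- if (length(manifests)) do.call(rbind, manifests)
              else windowFrame(numeric(), lengthS, integer(), character(),
                               character())
  rownames(manifest) <- NULL
  new("TFImageSet", images = images, labels = as.integer(manifest$label),
      manifest = manifest, metadata = list(skippedRecords = skipped))
}

#' Concatenate image sets
#'
#' @param ... [TFImageSet-class] objects.
#' @return the pooled [TFImageSet-class].
#' @export
concatImageSets <- function(...) {
  sets <- list(...)
  manifest <- do.call(rbind, lapply(sets, imageManifest))
  rownames(manifest) <- NULL
  new("TFImageSet",
      images = do.call(c, lapply(sets, function(s) s@images)),
      labels = do.call(c, lapply(sets, imageLabels)),
      manifest = manifest,
      metadata = list(skippedRecords =
        do.call(c, lapply(sets, function(s) s@metadata$skippedRecords))))
}

#' Shuffled 60/20/20 split
#'
#' Draws a seeded uniform permutation of the image indices and cuts it at
#' the fraction boundaries: train takes \code{round(f1 * N)}, validation
#' \code{round(f2 * N)}, test the remainder. The split is deliberately
#' subject-agnostic (records are pooled before shuffling), mirroring the
#' cross-subject protocol; see [leaveSubjectOutSplit()] for the stricter
#' alternative.
#'
#' @param dataset a [TFImageSet-class], or an integer N.
#' @param fractions numeric triple summing to 1 (default 0.6/0.2/0.2).
#' @param seed integer seed; the same seed always yields the same split.
#' @return a [DatasetSplit-class] with 1-based index vectors.
#' @examples
#' sp <- splitDataset(1000, seed = 1)
#' lengths(list(trainIdx(sp), valIdx(sp), testIdx(sp)))  # 600 200 200
#' @export
splitDataset <- function(dataset, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  n <- if (is(dataset, "TFImageSet")) length(dataset)
       else asCount(dataset, "dataset size")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three values summing to 1")
  if (n < 3L) stop("need at least 3 images to split")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  nTrain <- as.integer(round(fractions[1] * n))
  nVal <- as.integer(round(fractions[2] * n))
  if (nTrain + nVal > n)
    stop("fractions leave no room for a test set")
  new("DatasetSplit",
      trainIdx = perm[seq_len(nTrain)],
      valIdx = perm[nTrain + seq_len(nVal)],
      testIdx = perm[nTrain + nVal + seq_len(n - nTrain - nVal)],
      fractions = as.numeric(fractions), seed = as.integer(seed))
}

#' Leave-subject-out split (extension, off the default path)
#'
#' Assigns whole subjects to the test partition: images whose
#' \code{record_ref} is in \code{testSubjects} form the test set and the
#' rest is split train/validation by the same seeded permutation rule.
#' Stricter than the pooled protocol for generalization claims.
#'
#' @param dataset a [TFImageSet-class].
#' @param testSubjects character vector of \code{record_ref} values.
#' @param valFraction fraction of the remaining images used for
#'   validation.
#' @param seed integer seed.
#' @return a [DatasetSplit-class].
#' @export
leaveSubjectOutSplit <- function(dataset, testSubjects, valFraction = 0.25,
                                 seed = 1) {
  stopifnot(is(dataset, "TFImageSet"))
  refs <- imageManifest(dataset)$record_ref
  testI <- which(refs %in% testSubjects)
  restI <- which(!refs %in% testSubjects)
  if (!length(testI)) stop("no images belong to the requested subjects")
  if (length(restI) < 2L) stop("too few images left for train/validation")
  perm <- restI[withr::with_seed(as.integer(seed),
                                 sample.int(length(restI)))]
  nVal <- round(valFraction * length(restI))
  new("DatasetSplit",
      trainIdx = perm[seq_len(length(restI) - nVal)],
      valIdx = if (nVal) perm[(length(restI) - nVal + 1L):length(restI)]
               else integer(),
      testIdx = as.integer(testI),
      fractions = c((1 - valFraction) * length(restI),
                    valFraction * length(restI),
                    length(testI)) / length(dataset),
      seed = as.integer(seed))
}

#' Write / read split files and manifests
#'
#' The split JSON stores the seed, fractions and 1-based index lists so a
#' partition can be reproduced exactly; the manifest CSV serializes window
#' provenance.
#'
#' @param split a [DatasetSplit-class].
#' @param path output path.
#' @return \code{path} (writers, invisibly) or the reconstructed object.
#' @export
writeSplitJSON <- function(split, path) {
  jsonlite::write_json(
    list(seed = split@seed, fractions = split@fractions,
         train_idx = split@trainIdx, val_idx = split@valIdx,
         test_idx = split@testIdx),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSplitJSON
#' @export
readSplitJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DatasetSplit", trainIdx = as.integer(j$train_idx),
      valIdx = as.integer(j$val_idx), testIdx = as.integer(j$test_idx),
      fractions = as.numeric(j$fractions), seed = as.integer(j$seed))
}

#' @rdname writeSplitJSON
#' @param dataset a [TFImageSet-class].
#' @export
writeManifestCSV <- function(dataset, path) {
  utils::write.csv(imageManifest(dataset), path, row.names = FALSE)
  invisible(path)
}
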