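# Two-step windowing of a record into labeled 180 s segments.
#
# Step one slides a 180 s window with 30% overlap (stride 126 s) from time
# zero and labels each window by seizure overlap. Step two augments the
# positive class: windows start at the seizure onset t1 and advance one
# second per step, kept while they overlap [t1, t2] by at least 3 s.
# Windows are half-open [start, start + length); overlap is computed on
# the half-open intersection, so a window that merely touches a seizure
# boundary has zero overlap. Windows that would run past the record end
# are dropped, never truncated: every image must span exactly one window.

windowFrame <- function(startS, lengthS, label, source, recordRef) {
  data.frame(record_ref = rep(recordRef, length(startS)),
             start_s = startS,
             length_s = rep(lengthS, length(startS)),
             label = as.integer(label),
             source = rep(source, length(startS)),
             stringsAsFactors = FALSE)
}

#' Label a window by seizure overlap
#'
#' A window is positive iff its half-open extent \code{[start, start +
#' length)} overlaps any seizure interval by a strictly positive length.
#'
#' @param startS,lengthS window position and length in seconds.
#' @param seizures \code{data.frame(t1, t2)} of seizure intervals.
#' @return integer 0 or 1.
#' @examples
#' labelWindow(0, 180, seizureTable(179, 240))  # 1 s overlap -> positive
#' labelWindow(0, 180, seizureTable(180, 240))  # touch only -> negative
#' @export
labelWindow <- function(startS, lengthS, seizures) {
  if (nrow(seizures) == 0) return(0L)
  ov <- halfOpenOverlap(startS, startS + lengthS, seizures$t1, seizures$t2)
  as.integer(any(ov > 0))
}

#' Step-one sliding segmentation
#'
#' Moves a window of \code{lengthS} seconds from time 0 with the given
#' fractional overlap (stride \code{lengthS * (1 - overlapFrac)}, 126 s at
#' the defaults) and labels each window with [labelWindow()]. Windows are
#' emitted while they fit inside the record.
#'
#' @param record an [EEGRecord-class].
#' @param lengthS window length in seconds (default 180).
#' @param overlapFrac fractional overlap between consecutive windows,
#'   in [0, 1) (default 0.30).
#' @return \code{data.frame} with columns \code{record_ref},
#'   \code{start_s}, \code{length_s}, \code{label}, \code{source}
#'   (\code{"sliding"}); zero rows (with a warning) when the record is
#'   shorter than one window.
#' @examples
#' rec <- generateRecord(synthConfig(durationS = 600,
#'                                   seizures = seizureTable(100, 140)))
#' nrow(segmentSliding(rec))
#' @export
segmentSliding <- function(record, lengthS = 180, overlapFrac = 0.30) {
  stopifnot(is(record, "EEGRecord"), overlapFrac >= 0, overlapFrac < 1,
            lengthS > 0)
  dur <- durationS(record)
  if (dur < lengthS - 1e-9) {
    warning(sprintf(
      "record '%s' (%.1f s) is shorter than one %g s window; no segments",
      subjectId(record), dur, lengthS))
    return(windowFrame(numeric(), lengthS, integer(), character(),
                       character()))
  }
  stride <- lengthS * (1 - overlapFrac)
  nWin <- floor((dur - lengthS) / stride + 1e-9) + 1
  starts <- stride * (seq_len(nWin) - 1)
  labels <- vapply(starts, labelWindow, 0L, lengthS = lengthS,
                   seizures = seizureIntervals(record))
  windowFrame(starts, lengthS, labels, "sliding", subjectId(record))
}

#' Step-two seizure-interval augmentation
#'
#' Starting at the seizure onset \code{t1}, windows advance \code{stepS}
#' seconds per step and are kept while (a) they overlap \code{[t1, t2]} by
#' at least \code{minOverlapS} seconds and (b) they fit inside the record.
#' All emitted windows are positive with source \code{"augment"}. A
#' seizure shorter than \code{minOverlapS} yields no windows.
#'
#' @param record an [EEGRecord-class].
#' @param interval one-row \code{data.frame(t1, t2)} (or a list with
#'   \code{t1}, \code{t2}).
#' @param lengthS window length in seconds (default 180).
#' @param stepS step between window starts in seconds (default 1).
#' @param minOverlapS minimum overlap with the seizure interval (default 3).
#' @return \code{data.frame} in the same shape as [segmentSliding()];
#'   possibly zero rows.
#' @examples
#' rec <- generateRecord(synthConfig(durationS = 900,
#'                                   seizures = seizureTable(300, 340)))
#' nrow(segmentSeizureAugment(rec, seizureIntervals(rec)[1, ]))  # 38
#' @export
segmentSeizureAugment <- function(record, interval, lengthS = 180,
                                  stepS = 1, minOverlapS = 3) {
  stopifnot(is(record, "EEGRecord"), stepS > 0, minOverlapS > 0)
  t1 <- interval$t1; t2 <- interval$t2
  stopifnot(length(t1) == 1L, length(t2) == 1L, t2 > t1)
  dur <- durationS(record)
  kMax <- max(0, ceiling((t2 - t1) / stepS)) + 1L
  starts <- t1 + stepS * (0:kMax)
  ov <- halfOpenOverlap(starts, starts + lengthS, t1, t2)
  keep <- ov >= minOverlapS - 1e-9 & starts + lengthS <= dur + 1e-9
  windowFrame(starts[keep], lengthS, rep(1L, sum(keep)), "augment",
              subjectId(record))
}

#' Extract the sample block of one window
#'
#' @param record an [EEGRecord-class].
#' @param startS window start in seconds.
#' @param lengthS window length in seconds.
#' @return numeric matrix, \code{round(lengthS * fs)} samples x channels.
#' @export
extractSegment <- function(record, startS, lengthS = 180) {
  fs <- samplingRate(record)
  n <- as.integer(round(lengthS * fs))
  from <- as.integer(round(startS * fs)) + 1L
  if (from < 1L || from + n - 1L > nrow(signalMatrix(record)))
    stop("window extends past the record")
  signalMatrix(record)[from:(from + n - 1L), , drop = FALSE]
}
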