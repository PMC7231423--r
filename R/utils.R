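# Small internal helpers shared across modules.

# Overlap length of the half-open interval [a1, a2) with [b1, b2).
halfOpenOverlap <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}

# Build a validated seizure-interval data.frame.
#' Construct a seizure interval table
#'
#' @param t1,t2 numeric vectors of start/end times in seconds (t2 > t1).
#' @return \code{data.frame} with columns \code{t1}, \code{t2}, sorted by
#'   \code{t1}.
#' @examples
#' seizureTable(c(100, 300), c(140, 360))
#' @export
seizureTable <- function(t1 = numeric(), t2 = numeric()) {
  if (length(t1) != length(t2))
    stop("t1 and t2 must have the same length")
  if (any(t2 <= t1))
    stop("every seizure interval needs t2 > t1")
  o <- order(t1)
  data.frame(t1 = as.numeric(t1[o]), t2 = as.numeric(t2[o]))
}

#' Construct an EEGRecord
#'
#' @param signals numeric matrix, samples x channels (microvolts).
#' @param channelLabels channel names, one per column.
#' @param fs sampling rate in Hz.
#' @param seizures \code{data.frame(t1, t2)} of seizure intervals in
#'   seconds, e.g. from [seizureTable()].
#' @param subjectId identifier string.
#' @return validated [EEGRecord-class] object.
#' @examples
#' rec <- EEGRecord(matrix(rnorm(512 * 3), ncol = 3),
#'                  c("FP2-F8", "F8-T8", "T8-P8"), fs = 256)
#' durationS(rec)
#' @export
EEGRecord <- function(signals, channelLabels, fs,
                      seizures = seizureTable(), subjectId = "record") {
  new("EEGRecord", signals = as.matrix(signals),
      channelLabels = as.character(channelLabels), fs = as.numeric(fs),
      seizures = seizures, subjectId = as.character(subjectId))
}

# Integer coercion that rejects fractional input.
asCount <- function(x, name) {
  if (any(abs(x - round(x)) > 1e-9))
    stop(sprintf("%s must be integer-valued", name))
  as.integer(round(x))
}
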