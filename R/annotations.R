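# CHB-MIT summary-file dialect: plain-text per-record blocks like
#
#   File Name: chb05_06.edf
#   Number of Seizures in File: 1
#   Seizure Start Time: 417 seconds
#   Seizure End Time: 532 seconds
#
# Some subjects number their seizures ("Seizure 1 Start Time: ..."); both
# spellings are accepted. Parsing is insensitive to trailing whitespace and
# blank lines between blocks.

#' Read seizure annotations for one record from a CHB-MIT-style summary
#'
#' @param path summary text file (\code{chbXX-summary.txt} dialect).
#' @param recordName the record's file name as it appears after
#'   \code{"File Name:"} (e.g. \code{"chb05_06.edf"}).
#' @return \code{data.frame(t1, t2)} of seizure intervals in seconds,
#'   sorted by start time; zero rows when the record has no seizures.
#' @seealso [writeChbmitSummary()]
#' @export
readChbmitAnnotations <- function(path, recordName) {
  if (!file.exists(path))
    stop(sprintf("summary file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE), which = "right")

  fileLines <- grep("^\\s*File Name:", lines)
  if (!length(fileLines))
    stop("no 'File Name:' blocks found in summary file")
  names_in_file <- trimws(sub("^\\s*File Name:", "", lines[fileLines]))
  hits <- fileLines[names_in_file == recordName]
  if (!length(hits))
    stop(sprintf("record '%s' not found in summary file", recordName))

  t1 <- numeric(); t2 <- numeric()
  for (h in hits) {
    nxt <- fileLines[fileLines > h]
    blockEnd <- if (length(nxt)) min(nxt) - 1L else length(lines)
    pendingStart <- NA_real_
    pendingLine <- NA_integer_
    for (i in seq(h, blockEnd)) {
      ln <- lines[i]
      if (grepl("^\\s*Seizure( [0-9]+)? Start Time:", ln)) {
        if (!is.na(pendingStart))
          stop(sprintf(
            "line %d: seizure start without a matching end (start at line %d)",
            i, pendingLine))
        pendingStart <- as.numeric(gsub("[^0-9.]", "",
          sub("^\\s*Seizure( [0-9]+)? Start Time:", "", ln)))
        pendingLine <- i
      } else if (grepl("^\\s*Seizure( [0-9]+)? End Time:", ln)) {
        if (is.na(pendingStart))
          stop(sprintf("line %d: seizure end without a preceding start", i))
        end <- as.numeric(gsub("[^0-9.]", "",
          sub("^\\s*Seizure( [0-9]+)? End Time:", "", ln)))
        if (!is.finite(end) || end <= pendingStart)
          stop(sprintf("line %d: seizure end (%s) not after start (%s)",
                       i, format(end), format(pendingStart)))
        t1 <- c(t1, pendingStart); t2 <- c(t2, end)
        pendingStart <- NA_real_
      }
    }
    if (!is.na(pendingStart))
      stop(sprintf("line %d: seizure start without a matching end",
                   pendingLine))
  }
  seizureTable(t1, t2)
}

#' Write a CHB-MIT-dialect summary file for one or more records
#'
#' Used by the synthetic path (and the \code{simulate} CLI subcommand) so
#' generated fixtures exercise the same readers as real data. Times are
#' written as integer seconds, the CHB-MIT convention.
#'
#' @param path output text file.
#' @param records named list: record file name -> \code{data.frame(t1, t2)}.
#' @param fs sampling rate noted in the file header line.
#' @return \code{path}, invisibly.
#' @export
writeChbmitSummary <- function(path, records, fs = 256) {
  out <- c(sprintf("Data Sampling Rate: %g Hz", fs), "")
  for (nm in names(records)) {
    sz <- records[[nm]]
    out <- c(out,
             sprintf("File Name: %s", nm),
             sprintf("Number of Seizures in File: %d", nrow(sz)))
    for (k in seq_len(nrow(sz))) {
      out <- c(out,
               sprintf("Seizure %d Start Time: %d seconds", k,
                       as.integer(round(sz$t1[k]))),
               sprintf("Seizure %d End Time: %d seconds", k,
                       as.integer(round(sz$t2[k]))))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
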