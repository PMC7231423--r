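# Fusing three channel spectrograms into one 224 x 224 x 3 image.
#
# Per channel: magnitude spectrogram -> optional log10(mag + eps) ->
# min-max normalization to [0, 1] per image-channel -> bilinear resize of
# the frequency axis 207 -> 224 -> stacked in the fixed order FP2-F8
# (red), F8-T8 (green), T8-P8 (blue). Rows are flipped so the lowest
# frequency sits on the bottom row of the image.

TF_CHANNEL_ORDER <- c("FP2-F8", "F8-T8", "T8-P8")

minMaxScale <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 0) return(matrix(0, nrow(m), ncol(m)))
  (m - lo) / (hi - lo)
}

#' Convert one 3-channel segment to a fused time-frequency image
#'
#' @param segment numeric matrix, samples x 3 channels (the order is taken
#'   as FP2-F8, F8-T8, T8-P8 -> red, green, blue).
#' @param config an [StftConfig-class]; \code{logScale} and \code{eps}
#'   control the log compression.
#' @param label binary window label.
#' @param provenance optional list describing the source window.
#' @return a [TFImage-class], 224 x 224 x 3 with values in [0, 1];
#'   deterministic in its input.
#' @examples
#' rec <- generateRecord(synthConfig(durationS = 200, seed = 3))
#' img <- toTFImage(extractSegment(rec, 0), stftConfig(), label = 0)
#' dim(img@pixels)
#' @export
toTFImage <- function(segment, config = stftConfig(), label = 0L,
                      provenance = list()) {
  segment <- as.matrix(segment)
  if (ncol(segment) != 3L)
    stop(sprintf("segment must have exactly 3 channels, got %d",
                 ncol(segment)))
  planes <- lapply(seq_len(3L), function(j) {
    mag <- stftMagnitude(segment[, j], config)
    if (config@logScale) mag <- log10(mag + config@eps)
    scaled <- minMaxScale(mag)
    res <- EBImage::resize(scaled, w = 224L, h = 224L, filter = "bilinear")
    pmin(pmax(res, 0), 1)[224:1, , drop = FALSE]   # low freq at bottom
  })
  px <- array(0, c(224L, 224L, 3L))
  for (j in 1:3) px[, , j] <- planes[[j]]
  new("TFImage", pixels = px, label = as.integer(label),
      channelOrder = TF_CHANNEL_ORDER, provenance = provenance)
}

#' Export a time-frequency image as an 8-bit RGB PNG
#'
#' @param image a [TFImage-class] or a 224 x 224 x 3 array in [0, 1].
#' @param path output file; [tfImageFilename()] builds the conventional
#'   name \code{<record>_<start>s_<label>.png}.
#' @return \code{path}, invisibly.
#' @export
writeTFImagePNG <- function(image, path) {
  px <- if (is(image, "TFImage")) image@pixels else image
  png::writePNG(px, target = path)
  invisible(path)
}

#' @rdname writeTFImagePNG
#' @param recordRef,startS,label filename components encoding provenance.
#' @export
tfImageFilename <- function(recordRef, startS, label) {
  sprintf("%s_%08.1fs_%d.png", gsub("[^A-Za-z0-9_.-]", "_", recordRef),
          startS, as.integer(label))
}
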