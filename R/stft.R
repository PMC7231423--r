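# Short-time Fourier transform of one channel.
#
# The magnitude spectrogram of a 180 s segment at 256 Hz (46080 samples)
# with the default 413-sample Hann taper and 204-sample hop is 207 x 224:
# floor(413/2) + 1 one-sided bins by floor((46080 - 413)/204) + 1 frames.
# The hop of 204 samples (overlap 209, about 50.6%) is the largest hop
# that gives exactly 224 full frames with no padding; it is the package's
# documented frame-advance convention and can be overridden.

#' Construct an STFT configuration
#'
#' @param winSamples taper length in samples (default 413).
#' @param hopSamples frame advance in samples (default 204; see
#'   [StftConfig-class] for the convention).
#' @param windowFn \code{"hann"} (default), \code{"hamming"} or
#'   \code{"rect"}.
#' @param fs sampling rate in Hz (default 256).
#' @param logScale log10-compress magnitudes when imaging (default TRUE).
#' @param eps additive floor before the log (default 1e-12).
#' @return a validated [StftConfig-class].
#' @export
stftConfig <- function(winSamples = 413, hopSamples = 204,
                       windowFn = "hann", fs = 256, logScale = TRUE,
                       eps = 1e-12) {
  new("StftConfig", winSamples = asCount(winSamples, "winSamples"),
      hopSamples = asCount(hopSamples, "hopSamples"), windowFn = windowFn,
      fs = fs, logScale = logScale, eps = eps)
}

# Periodic taper of length n.
taperWindow <- function(fn, n) {
  k <- 0:(n - 1)
  switch(fn,
         hann = 0.5 * (1 - cos(2 * pi * k / n)),
         hamming = 0.54 - 0.46 * cos(2 * pi * k / n),
         rect = rep(1, n),
         stop("unknown window function: ", fn))
}

#' One-sided STFT magnitude of a signal
#'
#' Frames of \code{winSamples} samples are taken every \code{hopSamples}
#' samples (no padding, no mean removal), multiplied by the taper and
#' Fourier transformed; the one-sided magnitude is returned.
#'
#' @param signal numeric vector, length at least \code{winSamples}.
#' @param config an [StftConfig-class].
#' @return nonnegative matrix of \code{floor(winSamples/2) + 1} frequency
#'   bins (rows, bin b = frequency \code{b * fs / winSamples} for b =
#'   0, 1, ...) by \code{floor((length - winSamples)/hopSamples) + 1}
#'   frames (columns).
#' @examples
#' x <- sin(2 * pi * 5 * (0:46079) / 256)
#' dim(stftMagnitude(x, stftConfig()))   # 207 x 224
#' @export
stftMagnitude <- function(signal, config = stftConfig()) {
  stopifnot(is(config, "StftConfig"))
  win <- config@winSamples
  hop <- config@hopSamples
  n <- length(signal)
  if (n < win)
    stop(sprintf("signal (%d samples) shorter than the STFT window (%d)",
                 n, win))
  nFrames <- (n - win) %/% hop + 1L
  starts <- (seq_len(nFrames) - 1L) * hop
  frames <- matrix(signal[outer(seq_len(win), starts, `+`)], nrow = win)
  frames <- frames * taperWindow(config@windowFn, win)
  spec <- stats::mvfft(frames)
  Mod(spec[seq_len(win %/% 2L + 1L), , drop = FALSE])
}

#' Frequency-bin geometry helpers
#'
#' \code{stftBinForFreq} maps a frequency in Hz to the (0-based)
#' one-sided STFT bin; \code{imageRowsForBand} maps a frequency band to
#' the rows of the final 224 x 224 image (rows run high frequency at the
#' top to low frequency at the bottom), accounting for the 207 -> 224
#' bilinear resize.
#'
#' @param freqHz frequency in Hz.
#' @param config an [StftConfig-class].
#' @return \code{stftBinForFreq}: 0-based bin index (numeric).
#' @export
stftBinForFreq <- function(freqHz, config = stftConfig()) {
  freqHz * config@winSamples / config@fs
}

#' @rdname stftBinForFreq
#' @param fminHz,fmaxHz band edges in Hz.
#' @param nRowsOut,nRowsIn image rows and spectrogram bins.
#' @return \code{imageRowsForBand}: integer vector of image rows covering
#'   the band.
#' @export
imageRowsForBand <- function(fminHz, fmaxHz, config = stftConfig(),
                             nRowsOut = 224L, nRowsIn = NULL) {
  if (is.null(nRowsIn)) nRowsIn <- config@winSamples %/% 2L + 1L
  # pixel-center mapping of the resize, then flip (low freq at bottom)
  toOut <- function(bin0) (bin0 + 0.5) * nRowsOut / nRowsIn + 0.5
  lo <- toOut(stftBinForFreq(fminHz, config))
  hi <- toOut(stftBinForFreq(fmaxHz, config))
  rows <- (nRowsOut + 1L) - seq(floor(lo), ceiling(hi))
  sort(rows[rows >= 1L & rows <= nRowsOut])
}
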