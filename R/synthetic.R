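# Synthetic multichannel EEG with labeled seizure intervals.
#
# Background: 1/f^beta colored noise (spectrum-shaped white noise, zero
# mean by construction) plus a dominant alpha-band sinusoid. Seizures: an
# added rhythmic burst at a 3-7 Hz frequency, amplitude = background
# amplitude x gain, with half-second raised-cosine on/off ramps. Channels
# draw independent noise and phases but share seizure timing.

#' Construct a synthetic-EEG configuration
#'
#' @param fs sampling rate in Hz (default 256, the CHB-MIT rate).
#' @param durationS record length in seconds.
#' @param nChannels number of channels (default 3, matching the three
#'   bipolar derivations the pipeline fuses).
#' @param backgroundAlphaHz dominant background rhythm frequency (Hz).
#' @param backgroundAmpUv background rhythm amplitude (microvolts).
#' @param noiseAmpUv broadband-noise standard deviation (microvolts).
#' @param noiseExponent spectral slope beta of the 1/f^beta noise.
#' @param seizures \code{data.frame(t1, t2)} of seizure intervals, e.g.
#'   from [seizureTable()].
#' @param seizureFreqHz burst rhythm frequency in Hz (3-7 band).
#' @param seizureAmpGain burst amplitude as a multiple of
#'   \code{backgroundAmpUv}; must be > 1.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a validated [SynthConfig-class].
#' @examples
#' cfg <- synthConfig(durationS = 600, seizures = seizureTable(100, 140))
#' @export
synthConfig <- function(fs = 256, durationS = 600, nChannels = 3,
                        backgroundAlphaHz = 10, backgroundAmpUv = 20,
                        noiseAmpUv = 10, noiseExponent = 1,
                        seizures = seizureTable(), seizureFreqHz = 5,
                        seizureAmpGain = 5, seed = 1) {
  new("SynthConfig", fs = fs, durationS = durationS,
      nChannels = as.integer(nChannels),
      backgroundAlphaHz = backgroundAlphaHz,
      backgroundAmpUv = backgroundAmpUv, noiseAmpUv = noiseAmpUv,
      noiseExponent = noiseExponent, seizureIntervals = seizures,
      seizureFreqHz = seizureFreqHz, seizureAmpGain = seizureAmpGain,
      seed = as.integer(seed))
}

# 1/f^beta noise: shape white Gaussian spectrum by f^(-beta/2), zero DC.
coloredNoise <- function(n, beta, sdTarget) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)                       # two-sided frequency index
  shape <- ifelse(f == 0, 0, f^(-beta / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x * (sdTarget / stats::sd(x))
}

# Raised-cosine on/off envelope for one interval, on the sample time grid.
burstEnvelope <- function(t, t1, t2, rampS = 0.5) {
  env <- numeric(length(t))
  inside <- t >= t1 & t < t2
  env[inside] <- 1
  rampS <- min(rampS, (t2 - t1) / 2)
  if (rampS > 0) {
    up <- inside & t < t1 + rampS
    dn <- inside & t >= t2 - rampS
    env[up] <- 0.5 * (1 - cos(pi * (t[up] - t1) / rampS))
    env[dn] <- 0.5 * (1 - cos(pi * (t2 - t[dn]) / rampS))
  }
  env
}

#' Generate a labeled synthetic EEG record
#'
#' @param config a [SynthConfig-class] from [synthConfig()].
#' @param subjectId identifier stored on the record.
#' @return an [EEGRecord-class] whose \code{seizures} table equals
#'   \code{config}'s intervals. Identical configurations (including seed)
#'   produce bitwise-identical signals.
#' @examples
#' rec <- generateRecord(synthConfig(durationS = 10, seed = 42))
#' samplingRate(rec)
#' @export
generateRecord <- function(config, subjectId = "synth") {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  n <- as.integer(round(config@fs * config@durationS))
  t <- (seq_len(n) - 1) / config@fs
  sz <- config@seizureIntervals

  burstAmp <- config@backgroundAmpUv * config@seizureAmpGain
  envTotal <- numeric(n)
  for (k in seq_len(nrow(sz)))
    envTotal <- envTotal + burstEnvelope(t, sz$t1[k], sz$t2[k])

  sig <- withr::with_seed(config@seed, {
    vapply(seq_len(config@nChannels), function(ch) {
      noise <- coloredNoise(n, config@noiseExponent, config@noiseAmpUv)
      phiA <- stats::runif(1, 0, 2 * pi)
      phiS <- stats::runif(1, 0, 2 * pi)
      noise +
        config@backgroundAmpUv * sin(2 * pi * config@backgroundAlphaHz * t + phiA) +
        burstAmp * envTotal * sin(2 * pi * config@seizureFreqHz * t + phiS)
    }, numeric(n))
  })

  labs <- c("FP2-F8", "F8-T8", "T8-P8",
            sprintf("CH%d", seq_len(max(0, config@nChannels - 3L)) + 3L))
  EEGRecord(sig, labs[seq_len(config@nChannels)], fs = config@fs,
            seizures = sz, subjectId = subjectId)
}

#' Build a balanced synthetic image set
#'
#' Convenience wrapper used by the examples, tests and the acceptance
#' workflow: generates a seizure-free record segmented with a dense
#' sliding stride (negatives) and a record with one long seizure segmented
#' by one-second-step augmentation (positives), then converts every window
#' to a fused time-frequency image.
#'
#' @param nPerClass approximate number of images per class.
#' @param seed RNG seed controlling both records.
#' @param stft an [StftConfig-class]; defaults to the pipeline geometry.
#' @return a [TFImageSet-class] with roughly balanced classes.
#' @export
syntheticImageSet <- function(nPerClass = 200, seed = 1,
                              stft = stftConfig()) {
  lengthS <- 180
  # negatives: dense sliding over a seizure-free record
  strideS <- 9
  negDur <- lengthS + strideS * (nPerClass - 1)
  negRec <- generateRecord(synthConfig(durationS = negDur, seed = seed),
                           subjectId = "synthA")
  # positives: one long seizure, one-second-step augmentation
  szDur <- nPerClass + 2
  posDur <- 300 + szDur + lengthS + 60
  posRec <- generateRecord(
    synthConfig(durationS = posDur,
                seizures = seizureTable(300, 300 + szDur),
                seed = seed + 1000L),
    subjectId = "synthB")
  negSet <- buildDataset(list(negRec), stft = stft,
                         overlapFrac = 1 - strideS / lengthS)
  posSet <- buildDataset(list(posRec), stft = stft)
  concatImageSets(negSet, posSet)
}
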