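# Independent oracles and shared fixtures. Every oracle here is written
# from the defining formulas, not from the package's implementation.

# Naive one-sided DFT-per-frame spectrogram magnitude.
naiveSpectrogram <- function(x, win, hop, taper) {
  nFrames <- floor((length(x) - win) / hop) + 1
  nBins <- floor(win / 2) + 1
  out <- matrix(0, nBins, nFrames)
  for (f in seq_len(nFrames)) {
    seg <- x[((f - 1) * hop + 1):((f - 1) * hop + win)] * taper
    for (k in seq_len(nBins)) {
      w <- exp(-2i * pi * (k - 1) * (0:(win - 1)) / win)
      out[k, f] <- Mod(sum(seg * w))
    }
  }
  out
}

# Brute-force sliding-window enumeration: count starts k*stride with
# start + len <= duration.
bruteSlidingCount <- function(duration, len, stride) {
  n <- 0L; k <- 0
  repeat {
    if (k * stride + len > duration + 1e-9) break
    n <- n + 1L; k <- k + 1
  }
  n
}

# Brute-force augmentation enumeration.
bruteAugmentStarts <- function(t1, t2, duration, len, step, minOv) {
  starts <- c(); s <- t1
  while (s + len <= duration + 1e-9) {
    ov <- min(s + len, t2) - max(s, t1)
    if (ov >= minOv - 1e-9) starts <- c(starts, s)
    if (min(s + len, t2) - s < minOv - 1e-9) break
    s <- s + step
  }
  starts
}

# Independent metric formulas (plain transcription).
refMetrics <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  n <- tp + tn + fp + fn
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  c(accuracy = (tp + tn) / n, precision = prec, recall = rec, mcor = mcc)
}

# Raw periodogram band power (independent of the package's STFT).
bandPower <- function(x, fs, fmin, fmax) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sum(p[f >= fmin & f <= fmax & f <= fs / 2])
}

# Shared fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

fixtureRecord600 <- function() {
  if (is.null(.fixtures$rec600))
    .fixtures$rec600 <- generateRecord(
      synthConfig(durationS = 600, seizures = seizureTable(100, 140),
                  seed = 11))
  .fixtures$rec600
}

fixtureSmallSet <- function() {
  if (is.null(.fixtures$smallSet))
    .fixtures$smallSet <- syntheticImageSet(nPerClass = 30, seed = 5)
  .fixtures$smallSet
}
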