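#' @import methods
NULL

#' Multichannel EEG recording with labeled seizure intervals
#'
#' The raw input of the detection pipeline: a fixed-rate multichannel scalp
#' EEG signal (microvolts) together with expert-style seizure interval
#' annotations. Channels are stored column-wise; seizure intervals are a
#' two-column \code{data.frame} with columns \code{t1} and \code{t2}
#' (seconds, \code{t1 < t2}), sorted and non-overlapping.
#'
#' @slot signals numeric matrix, samples x channels, in microvolts.
#' @slot channelLabels character vector naming the columns of
#'   \code{signals}; bipolar-montage labels such as \code{"FP2-F8"}.
#' @slot fs sampling rate in Hz.
#' @slot seizures \code{data.frame} with numeric columns \code{t1},
#'   \code{t2} in seconds from record start.
#' @slot subjectId subject/record identifier string.
#'
#' @seealso [EEGRecord()], [readEDF()], [generateRecord()]
#' @export
setClass("EEGRecord",
  representation(
    signals = "matrix",
    channelLabels = "character",
    fs = "numeric",
    seizures = "data.frame",
    subjectId = "character"
  )
)

setValidity("EEGRecord", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (ncol(object@signals) != length(object@channelLabels))
    msg <- c(msg, "channelLabels length must equal number of signal columns")
  if (!is.numeric(object@signals))
    msg <- c(msg, "signals must be numeric")
  sz <- object@seizures
  if (!all(c("t1", "t2") %in% names(sz)))
    msg <- c(msg, "seizures must have columns t1 and t2")
  else if (nrow(sz) > 0) {
    dur <- nrow(object@signals) / object@fs
    if (any(sz$t1 < 0) || any(sz$t2 > dur + 1e-9))
      msg <- c(msg, "seizure intervals must lie within [0, duration]")
    if (any(sz$t2 <= sz$t1))
      msg <- c(msg, "every seizure interval needs t2 > t1")
    if (is.unsorted(sz$t1, strictly = FALSE))
      msg <- c(msg, "seizure intervals must be sorted by t1")
    if (nrow(sz) > 1 && any(sz$t1[-1] < sz$t2[-nrow(sz)] - 1e-12))
      msg <- c(msg, "seizure intervals must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic EEG generator
#'
#' Describes the statistical structure of generated records: 1/f-like
#' broadband background noise plus a dominant rhythm (alpha band by
#' default), with seizures rendered as higher-amplitude rhythmic bursts in
#' the 3-7 Hz band over configured intervals.
#'
#' @slot fs sampling rate, Hz.
#' @slot durationS record length, seconds.
#' @slot nChannels number of channels.
#' @slot backgroundAlphaHz frequency of the dominant background rhythm, Hz.
#' @slot backgroundAmpUv amplitude of the background rhythm, microvolts.
#' @slot noiseAmpUv standard deviation of the broadband noise, microvolts.
#' @slot noiseExponent spectral slope beta of the 1/f^beta noise.
#' @slot seizureIntervals \code{data.frame(t1, t2)} of seizure intervals.
#' @slot seizureFreqHz seizure burst rhythm frequency, Hz (3-7 band).
#' @slot seizureAmpGain amplitude multiplier of the burst relative to the
#'   background rhythm; must exceed 1 so that seizure epochs are spectrally
#'   separable.
#' @slot seed integer RNG seed; generation is deterministic given the seed.
#'
#' @seealso [synthConfig()], [generateRecord()]
#' @export
setClass("SynthConfig",
  representation(
    fs = "numeric",
    durationS = "numeric",
    nChannels = "integer",
    backgroundAlphaHz = "numeric",
    backgroundAmpUv = "numeric",
    noiseAmpUv = "numeric",
    noiseExponent = "numeric",
    seizureIntervals = "data.frame",
    seizureFreqHz = "numeric",
    seizureAmpGain = "numeric",
    seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (object@durationS <= 0) msg <- c(msg, "durationS must be > 0")
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (object@backgroundAmpUv <= 0 || object@noiseAmpUv <= 0)
    msg <- c(msg, "amplitudes must be > 0")
  if (object@seizureAmpGain <= 1)
    msg <- c(msg, "seizureAmpGain must be > 1 for spectral separability")
  sz <- object@seizureIntervals
  if (nrow(sz) > 0) {
    if (any(sz$t2 <= sz$t1)) msg <- c(msg, "seizure intervals need t2 > t1")
    if (any(sz$t1 < 0) || any(sz$t2 > object@durationS))
      msg <- c(msg, "seizure intervals must lie within [0, durationS]")
    o <- order(sz$t1)
    if (nrow(sz) > 1 && any(sz$t1[o][-1] < sz$t2[o][-nrow(sz)]))
      msg <- c(msg, "seizure intervals must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Short-time Fourier transform configuration
#'
#' Defaults reproduce the pipeline's spectrogram geometry: a 413-sample
#' taper advanced by 204 samples over a 180 s segment at 256 Hz yields a
#' 207 x 224 magnitude spectrogram (one-sided bins x frames).
#'
#' @slot winSamples taper length in samples.
#' @slot hopSamples frame advance in samples. The default 204 is the
#'   largest hop that yields exactly 224 frames from a 46080-sample
#'   segment with a 413-sample window (overlap 209 samples, about 50.6%).
#' @slot windowFn taper identifier: \code{"hann"}, \code{"hamming"} or
#'   \code{"rect"}.
#' @slot fs sampling rate of the analyzed signal, Hz.
#' @slot logScale if \code{TRUE}, images use \code{log10(mag + eps)}.
#' @slot eps floor added to the magnitude before the log.
#'
#' @seealso [stftConfig()], [stftMagnitude()], [toTFImage()]
#' @export
setClass("StftConfig",
  representation(
    winSamples = "integer",
    hopSamples = "integer",
    windowFn = "character",
    fs = "numeric",
    logScale = "logical",
    eps = "numeric"
  )
)

setValidity("StftConfig", function(object) {
  msg <- character()
  if (object@hopSamples < 1L || object@hopSamples > object@winSamples)
    msg <- c(msg, "need 0 < hopSamples <= winSamples")
  if (!object@windowFn %in% c("hann", "hamming", "rect"))
    msg <- c(msg, "windowFn must be one of 'hann', 'hamming', 'rect'")
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (object@eps <= 0) msg <- c(msg, "eps must be > 0")
  if (length(msg)) msg else TRUE
})

#' Fused time-frequency image of one EEG segment
#'
#' A 224 x 224 x 3 array in [0, 1]: one spectrogram plane per bipolar
#' channel, fused in the fixed RGB order FP2-F8 (red), F8-T8 (green),
#' T8-P8 (blue). Rows run from high frequency (top) to low frequency
#' (bottom row).
#'
#' @slot pixels numeric array, 224 x 224 x 3, values in [0, 1].
#' @slot label integer 0 (nonseizure) or 1 (seizure).
#' @slot channelOrder channel label per color plane.
#' @slot provenance list describing the source window (record id,
#'   start second, window source).
#'
#' @seealso [toTFImage()], [writeTFImagePNG()]
#' @export
setClass("TFImage",
  representation(
    pixels = "array",
    label = "integer",
    channelOrder = "character",
    provenance = "list"
  )
)

setValidity("TFImage", function(object) {
  msg <- character()
  if (!identical(dim(object@pixels), c(224L, 224L, 3L)))
    msg <- c(msg, "pixels must be a 224 x 224 x 3 array")
  if (!all(is.finite(object@pixels)))
    msg <- c(msg, "pixels must be finite")
  if (min(object@pixels) < -1e-9 || max(object@pixels) > 1 + 1e-9)
    msg <- c(msg, "pixels must lie in [0, 1]")
  if (!object@label %in% c(0L, 1L))
    msg <- c(msg, "label must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Collection of labeled time-frequency images
#'
#' The pooled cross-subject dataset fed to the classifiers: an ordered list
#' of [TFImage] pixel arrays, a parallel binary label vector and a
#' per-image provenance manifest (record id, window start, window length,
#' label, source).
#'
#' @slot images list of 224 x 224 x 3 pixel arrays.
#' @slot labels integer vector of 0/1 labels, parallel to \code{images}.
#' @slot manifest \code{data.frame} with columns \code{record_ref},
#'   \code{start_s}, \code{length_s}, \code{label}, \code{source}.
#' @slot metadata list of build-time notes (e.g. skipped records).
#'
#' @seealso [buildDataset()], [splitDataset()]
#' @export
setClass("TFImageSet",
  representation(
    images = "list",
    labels = "integer",
    manifest = "data.frame",
    metadata = "list"
  )
)

setValidity("TFImageSet", function(object) {
  msg <- character()
  if (length(object@images) != length(object@labels))
    msg <- c(msg, "images and labels must have the same length")
  if (nrow(object@manifest) != length(object@images))
    msg <- c(msg, "manifest must have one row per image")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0/1")
  if (length(msg)) msg else TRUE
})

#' Shuffled train/validation/test partition
#'
#' Index sets from a seeded uniform permutation cut at the fraction
#' boundaries (default 60/20/20). Indices are 1-based. The split is
#' subject-agnostic: images from one subject may land in several
#' partitions, mirroring the pooled cross-subject protocol.
#'
#' @slot trainIdx,valIdx,testIdx disjoint integer index vectors whose
#'   union is \code{seq_len(N)}.
#' @slot fractions numeric triple summing to 1.
#' @slot seed integer seed of the permutation.
#'
#' @seealso [splitDataset()]
#' @export
setClass("DatasetSplit",
  representation(
    trainIdx = "integer",
    valIdx = "integer",
    testIdx = "integer",
    fractions = "numeric",
    seed = "integer"
  )
)

setValidity("DatasetSplit", function(object) {
  msg <- character()
  all_idx <- c(object@trainIdx, object@valIdx, object@testIdx)
  if (anyDuplicated(all_idx))
    msg <- c(msg, "split index sets must be disjoint")
  if (!setequal(all_idx, seq_along(all_idx)))
    msg <- c(msg, "split indices must partition 1..N")
  if (length(object@fractions) != 3L ||
      abs(sum(object@fractions) - 1) > 1e-9)
    msg <- c(msg, "fractions must be a triple summing to 1")
  if (length(msg)) msg else TRUE
})

#' Transfer-classifier architecture description
#'
#' Identifies the convolutional backbone, the pooling between backbone and
#' head, and the sizes of the two trainable fully connected layers that
#' precede the 2-neuron softmax output.
#'
#' @slot backbone one of \code{"vgg16"}, \code{"vgg19"}, \code{"resnet50"},
#'   \code{"tiny_random"}.
#' @slot pretrained logical; only meaningful for the ImageNet backbones.
#' @slot freezeBackbone logical; frozen backbones receive no updates.
#' @slot pooling \code{"flatten"} (VGG-style) or \code{"global_average"}
#'   (ResNet-style).
#' @slot fcSizes integer pair: neurons in the two fully connected layers.
#' @slot nClasses number of output classes (2: seizure / nonseizure).
#'
#' @seealso [modelSpec()], [buildModel()], [nTrainableParams()]
#' @export
setClass("ModelSpec",
  representation(
    backbone = "character",
    pretrained = "logical",
    freezeBackbone = "logical",
    pooling = "character",
    fcSizes = "integer",
    nClasses = "integer"
  )
)

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@backbone %in% c("vgg16", "vgg19", "resnet50", "tiny_random"))
    msg <- c(msg, "unknown backbone")
  if (object@pretrained && object@backbone == "tiny_random")
    msg <- c(msg, "pretrained weights exist only for vgg16/vgg19/resnet50")
  if (!object@pooling %in% c("flatten", "global_average"))
    msg <- c(msg, "pooling must be 'flatten' or 'global_average'")
  if (length(object@fcSizes) != 2L || any(object@fcSizes < 1L))
    msg <- c(msg, "fcSizes must be two positive integers")
  if (object@nClasses != 2L)
    msg <- c(msg, "only binary (2-class) heads are supported")
  if (length(msg)) msg else TRUE
})

#' Training recipe
#'
#' Optimizer and stopping rules for head training. The defaults follow the
#' VGG-path recipe (SGD, learning rate 0.001, per-update decay 1e-5, batch
#' 64); [resnetTrainConfig()] gives the Adam/plateau recipe (batch 16,
#' learning rate reduced by factor 0.8 after 5 non-improving epochs).
#' Training always stops once the validation loss has not descended for
#' \code{earlyStopPatience} epochs, and the weights at the best validation
#' loss are restored.
#'
#' @slot optimizer \code{"sgd"} or \code{"adam"}.
#' @slot lr initial learning rate.
#' @slot sgdDecay per-update multiplicative decay d: the learning rate at
#'   update t is lr / (1 + d * t).
#' @slot adamBeta1,adamBeta2 Adam moment decay rates.
#' @slot batchSize minibatch size.
#' @slot maxEpochs epoch cap.
#' @slot earlyStopPatience epochs of non-descending validation loss
#'   tolerated before stopping.
#' @slot lrSchedule \code{"none"} or \code{"plateau"}.
#' @slot plateauFactor,plateauPatience reduce-on-plateau parameters, used
#'   when \code{lrSchedule == "plateau"}.
#' @slot seed RNG seed for weight initialization and batch shuffling.
#'
#' @seealso [trainConfig()], [trainModel()]
#' @export
setClass("TrainConfig",
  representation(
    optimizer = "character",
    lr = "numeric",
    sgdDecay = "numeric",
    adamBeta1 = "numeric",
    adamBeta2 = "numeric",
    batchSize = "integer",
    maxEpochs = "integer",
    earlyStopPatience = "integer",
    lrSchedule = "character",
    plateauFactor = "numeric",
    plateauPatience = "integer",
    seed = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (!object@optimizer %in% c("sgd", "adam"))
    msg <- c(msg, "optimizer must be 'sgd' or 'adam'")
  if (object@lr <= 0) msg <- c(msg, "lr must be > 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@earlyStopPatience < 1L || object@plateauPatience < 1L)
    msg <- c(msg, "patience values must be >= 1")
  if (!object@lrSchedule %in% c("none", "plateau"))
    msg <- c(msg, "lrSchedule must be 'none' or 'plateau'")
  if (object@plateauFactor <= 0 || object@plateauFactor >= 1)
    msg <- c(msg, "plateauFactor must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' A built (frozen backbone + trainable head) classifier
#'
#' Holds the frozen convolutional backbone weights and the trainable head
#' (FC1 -> ReLU -> FC2 -> ReLU -> softmax(2)) as plain matrices.
#'
#' @slot spec the [ModelSpec-class] that produced the model.
#' @slot backboneWeights list of convolution kernels and biases; never
#'   updated while \code{freezeBackbone} is \code{TRUE}.
#' @slot head list with \code{W1, b1, W2, b2, W3, b3}.
#' @slot featureNorm empty list, or \code{list(center, scale)} with the
#'   training-set feature statistics applied before the head. A random
#'   frozen backbone, unlike a pretrained one, carries no normalization
#'   statistics of its own, so they are estimated once from the training
#'   features and frozen into the model.
#' @slot seed seed used for weight initialization.
#'
#' @seealso [buildModel()], [trainModel()], [predictModel()]
#' @export
setClass("SeizureModel",
  representation(
    spec = "ModelSpec",
    backboneWeights = "list",
    head = "list",
    featureNorm = "list",
    seed = "integer"
  )
)

#' Binary confusion counts
#'
#' TP/TN/FP/FN with N = TP + TN + FP + FN. Counts are integers for real
#' evaluations; real values are allowed so that counts reconstructed from
#' printed rates (see [confusionFromRates()]) can be audited.
#'
#' @slot tp,tn,fp,fn nonnegative counts.
#'
#' @seealso [computeMetrics()], [confusionFromRates()]
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", tn = "numeric", fp = "numeric",
                 fn = "numeric")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (length(v) != 4L || any(!is.finite(v)))
    return("tp, tn, fp, fn must be single finite numbers")
  if (any(v < 0)) return("counts must be nonnegative")
  if (sum(v) <= 0) return("total count N must be > 0")
  TRUE
})

#' Classification metric suite
#'
#' Accuracy, precision, recall and the Matthews correlation coefficient
#' (mcor), plus the mean softmax cross-entropy over the evaluation set
#' (\code{NA} when metrics come from counts alone).
#'
#' @slot accuracy,precision,recall values in [0, 1].
#' @slot mcor Matthews correlation coefficient in [-1, 1].
#' @slot loss mean cross-entropy loss, or \code{NA}.
#'
#' @seealso [computeMetrics()], [evaluateModel()]
#' @export
setClass("MetricsReport",
  representation(accuracy = "numeric", precision = "numeric",
                 recall = "numeric", mcor = "numeric", loss = "numeric")
)

setValidity("MetricsReport", function(object) {
  msg <- character()
  r <- c(object@accuracy, object@precision, object@recall)
  if (any(r < -1e-9 | r > 1 + 1e-9))
    msg <- c(msg, "accuracy, precision, recall must lie in [0, 1]")
  if (object@mcor < -1 - 1e-9 || object@mcor > 1 + 1e-9)
    msg <- c(msg, "mcor must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})
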