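# Accessor generics and show methods for the core classes.

#' @rdname EEGRecord-class
#' @param object,x an \code{EEGRecord}
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname EEGRecord-class
#' @export
setMethod("signalMatrix", "EEGRecord", function(x) x@signals)

#' @rdname EEGRecord-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname EEGRecord-class
#' @export
setMethod("channelLabels", "EEGRecord", function(x) x@channelLabels)

#' @rdname EEGRecord-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname EEGRecord-class
#' @export
setMethod("samplingRate", "EEGRecord", function(x) x@fs)

#' @rdname EEGRecord-class
#' @export
setGeneric("durationS", function(x) standardGeneric("durationS"))
#' @rdname EEGRecord-class
#' @export
setMethod("durationS", "EEGRecord", function(x) nrow(x@signals) / x@fs)

#' @rdname EEGRecord-class
#' @export
setGeneric("seizureIntervals", function(x) standardGeneric("seizureIntervals"))
#' @rdname EEGRecord-class
#' @export
setMethod("seizureIntervals", "EEGRecord", function(x) x@seizures)

#' @rdname EEGRecord-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname EEGRecord-class
#' @export
setMethod("subjectId", "EEGRecord", function(x) x@subjectId)

setMethod("show", "EEGRecord", function(object) {
  cat(sprintf(
    "EEGRecord '%s': %d channel(s) x %d samples @ %g Hz (%.1f s), %d seizure(s)\n",
    object@subjectId, ncol(object@signals), nrow(object@signals),
    object@fs, durationS(object), nrow(object@seizures)))
  cat("  channels:", paste(object@channelLabels, collapse = ", "), "\n")
  if (nrow(object@seizures))
    cat("  seizures:", paste(sprintf("[%g, %g]", object@seizures$t1,
                                     object@seizures$t2), collapse = " "), "\n")
})

#' @rdname TFImageSet-class
#' @param x,object a \code{TFImageSet}
#' @export
setGeneric("imageLabels", function(x) standardGeneric("imageLabels"))
#' @rdname TFImageSet-class
#' @export
setMethod("imageLabels", "TFImageSet", function(x) x@labels)

#' @rdname TFImageSet-class
#' @export
setGeneric("imageManifest", function(x) standardGeneric("imageManifest"))
#' @rdname TFImageSet-class
#' @export
setMethod("imageManifest", "TFImageSet", function(x) x@manifest)

#' @rdname TFImageSet-class
#' @export
setGeneric("classBalance", function(x) standardGeneric("classBalance"))
#' @rdname TFImageSet-class
#' @export
setMethod("classBalance", "TFImageSet", function(x) mean(x@labels))

#' @rdname TFImageSet-class
#' @export
setGeneric("imagePixels", function(x, i) standardGeneric("imagePixels"))
#' @rdname TFImageSet-class
#' @param i image index
#' @export
setMethod("imagePixels", "TFImageSet", function(x, i) x@images[[i]])

#' @rdname TFImageSet-class
#' @export
setMethod("length", "TFImageSet", function(x) length(x@images))

setMethod("show", "TFImageSet", function(object) {
  cat(sprintf("TFImageSet: %d images (224 x 224 x 3), %.1f%% positive\n",
              length(object@images), 100 * mean(object@labels)))
  src <- table(object@manifest$source)
  if (length(src))
    cat("  sources:", paste(sprintf("%s=%d", names(src), src),
                            collapse = ", "), "\n")
})

#' @rdname DatasetSplit-class
#' @param x,object a \code{DatasetSplit}
#' @export
setGeneric("trainIdx", function(x) standardGeneric("trainIdx"))
#' @rdname DatasetSplit-class
#' @export
setMethod("trainIdx", "DatasetSplit", function(x) x@trainIdx)

#' @rdname DatasetSplit-class
#' @export
setGeneric("valIdx", function(x) standardGeneric("valIdx"))
#' @rdname DatasetSplit-class
#' @export
setMethod("valIdx", "DatasetSplit", function(x) x@valIdx)

#' @rdname DatasetSplit-class
#' @export
setGeneric("testIdx", function(x) standardGeneric("testIdx"))
#' @rdname DatasetSplit-class
#' @export
setMethod("testIdx", "DatasetSplit", function(x) x@testIdx)

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit (seed %d): train %d / val %d / test %d\n",
              object@seed, length(object@trainIdx), length(object@valIdx),
              length(object@testIdx)))
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf(
    "ModelSpec: backbone %s%s, pooling %s, FC %d x %d -> softmax(%d)\n",
    object@backbone, if (object@pretrained) " (pretrained)" else "",
    object@pooling, object@fcSizes[1], object@fcSizes[2], object@nClasses))
})

setMethod("show", "SeizureModel", function(object) {
  show(object@spec)
  cat(sprintf("  trainable head parameters: %d (backbone %s)\n",
              headParamCount(object@spec),
              if (object@spec@freezeBackbone) "frozen" else "trainable"))
})

#' @rdname ConfusionCounts-class
#' @param x,object a \code{ConfusionCounts}
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))
#' @rdname ConfusionCounts-class
#' @export
setMethod("totalCount", "ConfusionCounts",
          function(x) x@tp + x@tn + x@fp + x@fn)

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%g TN=%g FP=%g FN=%g (N=%g)\n",
              object@tp, object@tn, object@fp, object@fn,
              totalCount(object)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport: accuracy=%.4f recall=%.4f precision=%.4f mcor=%.4f%s\n",
    object@accuracy, object@recall, object@precision, object@mcor,
    if (is.na(object@loss)) "" else sprintf(" loss=%.4f", object@loss)))
})
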