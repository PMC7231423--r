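# Transfer architectures: frozen convolutional backbone + trainable
# two-layer fully connected head + 2-way softmax.
#
# The ImageNet backbones (vgg16/vgg19/resnet50) are described for
# architecture and parameter accounting; building them requires pretrained
# weights, which must be available locally. The `tiny_random` backbone
# (three conv blocks with frozen random weights) is first-class: it needs
# no weight files, so the complete pipeline runs offline, and it plays the
# same role as the pretrained feature extractors - a fixed nonlinear
# embedding on top of which only the head is trained.

BACKBONE_FEATURES <- list(
  vgg16 = list(grid = c(7L, 7L), channels = 512L, convParams = 14714688L),
  vgg19 = list(grid = c(7L, 7L), channels = 512L, convParams = 20024384L),
  resnet50 = list(grid = c(7L, 7L), channels = 2048L,
                  convParams = 23587712L),
  tiny_random = list(grid = c(7L, 7L), channels = 16L,
                     convParams = 3L * 3L * 3L * 8L + 8L +
                                  3L * 3L * 8L * 16L + 16L +
                                  3L * 3L * 16L * 16L + 16L)
)

#' Describe a transfer architecture
#'
#' @param backbone \code{"vgg16"}, \code{"vgg19"}, \code{"resnet50"} or
#'   \code{"tiny_random"}.
#' @param fcSizes integer pair: the two fully connected layer sizes
#'   (e.g. \code{c(4096, 4096)} for the VGG models, \code{c(2048, 2048)}
#'   for ResNet50).
#' @param pretrained use ImageNet weights (only meaningful for the three
#'   large backbones).
#' @param freezeBackbone keep backbone weights fixed during training
#'   (default TRUE).
#' @param pooling \code{"flatten"} or \code{"global_average"}; \code{NULL}
#'   selects the backbone's convention (flatten for VGG-style backbones,
#'   global average pooling for ResNet50).
#' @return a validated [ModelSpec-class].
#' @examples
#' modelSpec("vgg16", fcSizes = c(4096, 4096), pretrained = TRUE)
#' modelSpec("tiny_random", fcSizes = c(64, 64))
#' @export
modelSpec <- function(backbone = "tiny_random", fcSizes = c(64L, 64L),
                      pretrained = FALSE, freezeBackbone = TRUE,
                      pooling = NULL) {
  if (is.null(pooling))
    pooling <- if (backbone == "resnet50") "global_average" else "flatten"
  new("ModelSpec", backbone = backbone, pretrained = pretrained,
      freezeBackbone = freezeBackbone, pooling = pooling,
      fcSizes = asCount(fcSizes, "fcSizes"), nClasses = 2L)
}

#' Dimension of the pooled backbone output
#'
#' @param spec a [ModelSpec-class].
#' @return integer feature dimension seen by the first FC layer.
#' @export
pooledDim <- function(spec) {
  b <- BACKBONE_FEATURES[[spec@backbone]]
  if (spec@pooling == "flatten") prod(b$grid) * b$channels else b$channels
}

headParamCount <- function(spec) {
  d <- pooledDim(spec); f <- spec@fcSizes
  d * f[1] + f[1] + f[1] * f[2] + f[2] + f[2] * spec@nClasses + spec@nClasses
}

#' Count trainable parameters of an architecture
#'
#' With a frozen backbone only the head counts: \code{d*f1 + f1 + f1*f2 +
#' f2 + f2*2 + 2} where d is the pooled feature dimension.
#'
#' @param spec a [ModelSpec-class].
#' @return integer-valued count (numeric to avoid 32-bit overflow on the
#'   large heads).
#' @examples
#' nTrainableParams(modelSpec("vgg16", c(4096, 4096), pretrained = TRUE))
#' @export
nTrainableParams <- function(spec) {
  d <- as.numeric(pooledDim(spec)); f <- as.numeric(spec@fcSizes)
  head <- d * f[1] + f[1] + f[1] * f[2] + f[2] + f[2] * 2 + 2
  if (spec@freezeBackbone) head
  else head + as.numeric(BACKBONE_FEATURES[[spec@backbone]]$convParams)
}

glorotUniform <- function(nIn, nOut) {
  lim <- sqrt(6 / (nIn + nOut))
  matrix(stats::runif(nIn * nOut, -lim, lim), nIn, nOut)
}

glorotConv <- function(kh, kw, cin, cout) {
  lim <- sqrt(6 / (kh * kw * cin + kh * kw * cout))
  array(stats::runif(kh * kw * cin * cout, -lim, lim), c(kh, kw, cin, cout))
}

#' Build a classifier from its architecture description
#'
#' Backbone weights are generated (tiny_random) or would be loaded
#' (pretrained backbones); head weights are Glorot-uniform under the seed
#' with zero biases. Pretrained ImageNet weights are not bundled, so
#' requesting them raises an error pointing at \code{tiny_random}, the
#' self-contained offline backbone.
#'
#' @param spec a [ModelSpec-class].
#' @param seed integer seed for weight initialization.
#' @return a [SeizureModel-class].
#' @examples
#' m <- buildModel(modelSpec("tiny_random", c(32, 32)), seed = 7)
#' @export
buildModel <- function(spec, seed = 1) {
  stopifnot(is(spec, "ModelSpec"))
  validObject(spec)
  if (spec@backbone != "tiny_random")
    stop(sprintf(paste0(
      "pretrained weights for backbone '%s' are not available in this ",
      "installation; use backbone 'tiny_random' for offline use"),
      spec@backbone))
  seed <- as.integer(seed)
  w <- withr::with_seed(seed, {
    bw <- list(W1 = glorotConv(3, 3, 3, 8), b1 = numeric(8),
               W2 = glorotConv(3, 3, 8, 16), b2 = numeric(16),
               W3 = glorotConv(3, 3, 16, 16), b3 = numeric(16))
    d <- pooledDim(spec); f <- spec@fcSizes
    hd <- list(W1 = glorotUniform(d, f[1]), b1 = numeric(f[1]),
               W2 = glorotUniform(f[1], f[2]), b2 = numeric(f[2]),
               W3 = glorotUniform(f[2], spec@nClasses),
               b3 = numeric(spec@nClasses))
    list(bw = bw, hd = hd)
  })
  new("SeizureModel", spec = spec, backboneWeights = w$bw, head = w$hd,
      featureNorm = list(), seed = seed)
}

# Apply the model's frozen feature standardization (identity pre-training).
applyFeatureNorm <- function(model, X) {
  if (!length(model@featureNorm)) return(X)
  sweep(sweep(X, 2, model@featureNorm$center), 2, model@featureNorm$scale,
        `/`)
}

# -- tiny_random backbone forward pass ---------------------------------

# 3x3 "same" convolution via shift-and-accumulate; x is H x W x Cin.
conv3x3 <- function(x, W, b) {
  h <- dim(x)[1]; wd <- dim(x)[2]; cin <- dim(x)[3]; cout <- dim(W)[4]
  xp <- array(0, c(h + 2L, wd + 2L, cin))
  xp[2:(h + 1L), 2:(wd + 1L), ] <- x
  out <- array(0, c(h, wd, cout))
  ri <- seq_len(h); ci <- seq_len(wd)
  for (f in seq_len(cout)) {
    acc <- matrix(b[f], h, wd)
    for (di in 0:2) for (dj in 0:2) for (cc in seq_len(cin)) {
      wv <- W[di + 1L, dj + 1L, cc, f]
      if (wv != 0) acc <- acc + wv * xp[ri + di, ci + dj, cc]
    }
    out[, , f] <- acc
  }
  out
}

# Non-overlapping k x k max pooling (H, W divisible by k).
maxPool <- function(x, k) {
  h <- dim(x)[1] %/% k; wd <- dim(x)[2] %/% k
  out <- array(-Inf, c(h, wd, dim(x)[3]))
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    sub <- x[seq(di, by = k, length.out = h),
             seq(dj, by = k, length.out = wd), , drop = FALSE]
    out <- pmax(out, sub)
  }
  out
}

relu <- function(x) pmax(x, 0)

# Full backbone: 224x224x3 -> conv/pool(4) -> conv/pool(4) -> conv/pool(2)
# -> 7x7x16, then flatten or global average pooling.
tinyBackboneForward <- function(pixels, bw, pooling) {
  x <- relu(conv3x3(pixels, bw$W1, bw$b1)); x <- maxPool(x, 4L)
  x <- relu(conv3x3(x, bw$W2, bw$b2));      x <- maxPool(x, 4L)
  x <- relu(conv3x3(x, bw$W3, bw$b3));      x <- maxPool(x, 2L)
  if (pooling == "flatten") as.vector(x)
  else apply(x, 3, mean)
}

#' Extract frozen-backbone features
#'
#' @param model a [SeizureModel-class].
#' @param images list of 224 x 224 x 3 arrays, or a [TFImageSet-class].
#' @param idx optional indices into the image set.
#' @return numeric matrix, images x pooled feature dimension.
#' @export
backboneFeatures <- function(model, images, idx = NULL) {
  if (is(images, "TFImageSet")) {
    if (is.null(idx)) idx <- seq_len(length(images))
    images <- images@images[idx]
  }
  t(vapply(images, tinyBackboneForward, numeric(pooledDim(model@spec)),
           bw = model@backboneWeights, pooling = model@spec@pooling))
}
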