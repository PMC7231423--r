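# Head training: minibatch SGD/Adam on the softmax cross-entropy, early
# stopping on validation loss, optional reduce-on-plateau schedule, best
# weights restored. The frozen backbone is applied once per image to cache
# features, after which only the fully connected head is updated - the
# transfer-learning regime: the backbone is a fixed feature extractor.

#' Construct a training recipe
#'
#' The default arguments follow the VGG-path recipe (SGD, lr 0.001, decay
#' 1e-5, batch 64); [resnetTrainConfig()] returns the Adam recipe (lr
#' 0.001, beta1 0.9, beta2 0.999, batch 16, reduce-on-plateau factor 0.8
#' after 5 stalled epochs). Both cap at 500 epochs and stop early after 20
#' epochs without validation-loss improvement.
#'
#' @param optimizer \code{"sgd"} or \code{"adam"}.
#' @param lr initial learning rate.
#' @param sgdDecay per-update decay d: lr_t = lr / (1 + d * t).
#' @param adamBeta1,adamBeta2 Adam moment decays.
#' @param batchSize minibatch size.
#' @param maxEpochs epoch cap.
#' @param earlyStopPatience epochs of non-descending validation loss
#'   before stopping.
#' @param lrSchedule \code{"none"} or \code{"plateau"}.
#' @param plateauFactor,plateauPatience plateau-schedule parameters.
#' @param seed RNG seed for initialization order and batch shuffling.
#' @return a validated [TrainConfig-class].
#' @export
trainConfig <- function(optimizer = "sgd", lr = 0.001, sgdDecay = 1e-5,
                        adamBeta1 = 0.9, adamBeta2 = 0.999,
                        batchSize = 64, maxEpochs = 500,
                        earlyStopPatience = 20, lrSchedule = "none",
                        plateauFactor = 0.8, plateauPatience = 5,
                        seed = 1) {
  new("TrainConfig", optimizer = optimizer, lr = lr, sgdDecay = sgdDecay,
      adamBeta1 = adamBeta1, adamBeta2 = adamBeta2,
      batchSize = asCount(batchSize, "batchSize"),
      maxEpochs = asCount(maxEpochs, "maxEpochs"),
      earlyStopPatience = asCount(earlyStopPatience, "earlyStopPatience"),
      lrSchedule = lrSchedule, plateauFactor = plateauFactor,
      plateauPatience = asCount(plateauPatience, "plateauPatience"),
      seed = as.integer(seed))
}

#' @rdname trainConfig
#' @param ... overrides passed on to [trainConfig()].
#' @export
resnetTrainConfig <- function(...) {
  args <- list(optimizer = "adam", batchSize = 16, lrSchedule = "plateau")
  args[names(list(...))] <- list(...)
  do.call(trainConfig, args)
}

#' Softmax cross-entropy between two probability vectors
#'
#' \code{H(r, p) = -sum_i r_i log p_i} with the natural log; predicted
#' probabilities are clipped to \code{[eps, 1]} before the log.
#'
#' @param trueProbs,predProbs length-2 probability vectors, each summing
#'   to 1 within \code{tol}.
#' @param eps clipping floor.
#' @param tol normalization tolerance.
#' @return nonnegative scalar.
#' @examples
#' softmaxCrossEntropy(c(1, 0), c(0.5, 0.5))  # log(2)
#' @export
softmaxCrossEntropy <- function(trueProbs, predProbs, eps = 1e-12,
                                tol = 1e-6) {
  for (v in list(trueProbs, predProbs)) {
    if (length(v) != 2L || any(v < -tol) || any(v > 1 + tol) ||
        abs(sum(v) - 1) > tol)
      stop("inputs must be length-2 probability vectors summing to 1")
  }
  -sum(trueProbs * log(pmin(pmax(predProbs, eps), 1)))
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

headForward <- function(hd, X) {
  A1 <- relu(sweep(X %*% hd$W1, 2, hd$b1, `+`))
  A2 <- relu(sweep(A1 %*% hd$W2, 2, hd$b2, `+`))
  P <- softmaxRows(sweep(A2 %*% hd$W3, 2, hd$b3, `+`))
  list(A1 = A1, A2 = A2, P = P)
}

meanCrossEntropy <- function(P, y, eps = 1e-12) {
  -mean(log(pmin(pmax(P[cbind(seq_along(y), y + 1L)], eps), 1)))
}

headGradients <- function(hd, X, fwd, y) {
  n <- nrow(X)
  dZ3 <- fwd$P
  dZ3[cbind(seq_len(n), y + 1L)] <- dZ3[cbind(seq_len(n), y + 1L)] - 1
  dZ3 <- dZ3 / n
  dW3 <- crossprod(fwd$A2, dZ3); db3 <- colSums(dZ3)
  dA2 <- dZ3 %*% t(hd$W3); dZ2 <- dA2 * (fwd$A2 > 0)
  dW2 <- crossprod(fwd$A1, dZ2); db2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(hd$W2); dZ1 <- dA1 * (fwd$A1 > 0)
  dW1 <- crossprod(X, dZ1); db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

#' Train the fully connected head
#'
#' Runs minibatch optimization of the head on cached frozen-backbone
#' features, tracking per-epoch train/validation loss and accuracy. Stops
#' at \code{maxEpochs} or once the validation loss has not improved for
#' \code{earlyStopPatience} consecutive epochs; the head weights at the
#' best validation loss are restored. With \code{lrSchedule = "plateau"}
#' the learning rate is multiplied by \code{plateauFactor} after
#' \code{plateauPatience} stalled epochs.
#'
#' @param model a [SeizureModel-class] from [buildModel()].
#' @param dataset a [TFImageSet-class].
#' @param split a [DatasetSplit-class] over \code{dataset}.
#' @param config a [TrainConfig-class].
#' @param quiet suppress the per-epoch progress line.
#' @return list with \code{model} (trained), \code{history} (data.frame:
#'   epoch, lr, train_loss, train_acc, val_loss, val_acc),
#'   \code{bestEpoch} and \code{stoppedEarly}.
#' @export
trainModel <- function(model, dataset, split, config = trainConfig(),
                       quiet = TRUE) {
  stopifnot(is(model, "SeizureModel"), is(dataset, "TFImageSet"),
            is(split, "DatasetSplit"), is(config, "TrainConfig"))
  validObject(config)
  if (!length(split@trainIdx)) stop("empty training split")
  if (!model@spec@freezeBackbone)
    stop("backbone fine-tuning is not supported; freezeBackbone must be TRUE")

  Xtr <- backboneFeatures(model, dataset, split@trainIdx)
  ytr <- imageLabels(dataset)[split@trainIdx]
  Xva <- backboneFeatures(model, dataset, split@valIdx)
  yva <- imageLabels(dataset)[split@valIdx]

  # Freeze training-set feature statistics into the model (the random
  # backbone's stand-in for a pretrained backbone's normalization).
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2, stats::sd)
  scl[scl < 1e-8] <- 1
  model@featureNorm <- list(center = ctr, scale = scl)
  Xtr <- applyFeatureNorm(model, Xtr)
  Xva <- applyFeatureNorm(model, Xva)

  hd <- model@head
  lr0 <- config@lr; lrCur <- lr0
  adamM <- lapply(hd, function(w) w * 0)
  adamV <- lapply(hd, function(w) w * 0)
  tAdam <- 0L; tSgd <- 0L
  best <- list(loss = Inf, hd = hd, epoch = 0L)
  sinceBest <- 0L; sincePlateau <- 0L
  hist <- vector("list", config@maxEpochs)
  stoppedEarly <- FALSE

  withr::with_seed(config@seed, {
    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample.int(nrow(Xtr))
      for (b in split(ord, ceiling(seq_along(ord) / config@batchSize))) {
        Xb <- Xtr[b, , drop = FALSE]; yb <- ytr[b]
        fwd <- headForward(hd, Xb)
        g <- headGradients(hd, Xb, fwd, yb)
        if (config@optimizer == "sgd") {
          tSgd <- tSgd + 1L
          step <- lrCur / (1 + config@sgdDecay * tSgd)
          for (nm in names(hd)) hd[[nm]] <- hd[[nm]] - step * g[[nm]]
        } else {
          tAdam <- tAdam + 1L
          for (nm in names(hd)) {
            adamM[[nm]] <- config@adamBeta1 * adamM[[nm]] +
              (1 - config@adamBeta1) * g[[nm]]
            adamV[[nm]] <- config@adamBeta2 * adamV[[nm]] +
              (1 - config@adamBeta2) * g[[nm]]^2
            mHat <- adamM[[nm]] / (1 - config@adamBeta1^tAdam)
            vHat <- adamV[[nm]] / (1 - config@adamBeta2^tAdam)
            hd[[nm]] <- hd[[nm]] - lrCur * mHat / (sqrt(vHat) + 1e-8)
          }
        }
      }

      Ptr <- headForward(hd, Xtr)$P
      trLoss <- meanCrossEntropy(Ptr, ytr)
      trAcc <- mean(max.col(Ptr) - 1L == ytr)
      if (length(yva)) {
        Pva <- headForward(hd, Xva)$P
        vaLoss <- meanCrossEntropy(Pva, yva)
        vaAcc <- mean(max.col(Pva) - 1L == yva)
      } else {
        vaLoss <- trLoss; vaAcc <- trAcc
      }
      hist[[epoch]] <- data.frame(epoch = epoch, lr = lrCur,
                                  train_loss = trLoss, train_acc = trAcc,
                                  val_loss = vaLoss, val_acc = vaAcc)
      if (!quiet)
        message(sprintf(
          "epoch %3d: loss %.4f acc %.3f | val loss %.4f acc %.3f",
          epoch, trLoss, trAcc, vaLoss, vaAcc))

      if (vaLoss < best$loss - 1e-12) {
        best <- list(loss = vaLoss, hd = hd, epoch = epoch)
        sinceBest <- 0L; sincePlateau <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        sincePlateau <- sincePlateau + 1L
        if (config@lrSchedule == "plateau" &&
            sincePlateau >= config@plateauPatience) {
          lrCur <- lrCur * config@plateauFactor
          sincePlateau <- 0L
        }
        if (sinceBest >= config@earlyStopPatience) {
          stoppedEarly <- TRUE
          break
        }
      }
    }
  })

  model@head <- best$hd
  list(model = model, history = do.call(rbind, hist[!vapply(hist, is.null,
                                                            TRUE)]),
       bestEpoch = best$epoch, stoppedEarly = stoppedEarly)
}

#' Predict class probabilities
#'
#' @param model a [SeizureModel-class].
#' @param images a [TFImageSet-class], list of pixel arrays, or a cached
#'   feature matrix from [backboneFeatures()].
#' @param idx optional indices into the image set.
#' @return numeric matrix, one row per image, columns
#'   (P(nonseizure), P(seizure)); rows sum to 1.
#' @export
predictModel <- function(model, images, idx = NULL) {
  X <- if (is.matrix(images) && ncol(images) == pooledDim(model@spec))
    images
  else backboneFeatures(model, images, idx)
  P <- headForward(model@head, applyFeatureNorm(model, X))$P
  colnames(P) <- c("nonseizure", "seizure")
  P
}

#' Write a training history CSV
#'
#' @param history the \code{history} data.frame from [trainModel()].
#' @param path output path.
#' @export
writeHistoryCSV <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
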