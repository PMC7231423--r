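# Transfer architectures, the cross-entropy loss and head training.

test_that("softmax cross-entropy reproduces analytic values and validates input", {
  expect_identical(softmaxCrossEntropy(c(1, 0), c(1, 0)), 0)
  expect_equal(softmaxCrossEntropy(c(1, 0), c(0.5, 0.5)), log(2))
  expect_equal(softmaxCrossEntropy(c(0.3, 0.7), c(0.6, 0.4)),
               -(0.3 * log(0.6) + 0.7 * log(0.4)))   # 0.7946512
  expect_error(softmaxCrossEntropy(c(0.5, 0.6), c(0.5, 0.5)), "summing")
  expect_error(softmaxCrossEntropy(c(1, 0, 0), c(1, 0, 0)), "length-2")
})

test_that("the loss agrees with an independent scalar implementation on random pairs", {
  withr::with_seed(13, {
    for (i in 1:1000) {
      r <- runif(1); p <- runif(1, 1e-6, 1 - 1e-6)
      got <- softmaxCrossEntropy(c(r, 1 - r), c(p, 1 - p))
      ref <- -(r * log(p) + (1 - r) * log(1 - p))
      expect_lt(abs(got - ref), 1e-9)
    }
  })
})

test_that("trainable-parameter counts match the closed form and the built weights", {
  spec <- modelSpec("vgg16", fcSizes = c(4096, 4096), pretrained = TRUE)
  d <- 7 * 7 * 512
  expect_identical(nTrainableParams(spec),
                   d * 4096 + 4096 + 4096 * 4096 + 4096 + 4096 * 2 + 2)
  expect_identical(pooledDim(modelSpec("resnet50", c(2048, 2048))), 2048L)

  tiny <- modelSpec("tiny_random", c(32, 16))
  m <- buildModel(tiny, seed = 1)
  expect_identical(nTrainableParams(tiny),
                   sum(vapply(m@head, length, 0L)) + 0)
})

test_that("pretrained backbones error offline with a pointer to tiny_random", {
  expect_error(buildModel(modelSpec("vgg16", c(64, 64), pretrained = TRUE)),
               "tiny_random")
  expect_error(buildModel(modelSpec("resnet50", c(64, 64))), "tiny_random")
  expect_error(modelSpec("alexnet"), "backbone")
})

test_that("softmax outputs are row-normalized, shaped and deterministic", {
  ds <- fixtureSmallSet()
  m <- buildModel(modelSpec("tiny_random", c(16, 16)), seed = 2)
  P <- predictModel(m, ds, idx = 1:5)
  expect_identical(dim(P), c(5L, 2L))
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-6)
  expect_identical(P, predictModel(m, ds, idx = 1:5))
})

test_that("identical seeds build identical models; global average pooling shrinks features", {
  a <- buildModel(modelSpec("tiny_random", c(16, 16)), seed = 5)
  b <- buildModel(modelSpec("tiny_random", c(16, 16)), seed = 5)
  expect_identical(a@head, b@head)
  expect_identical(a@backboneWeights, b@backboneWeights)

  gap <- modelSpec("tiny_random", c(8, 8), pooling = "global_average")
  expect_identical(pooledDim(gap), 16L)
  mg <- buildModel(gap, seed = 1)
  ds <- fixtureSmallSet()
  expect_identical(dim(backboneFeatures(mg, ds, 1:3)), c(3L, 16L))
})

test_that("backbone weights are bitwise unchanged by a full training run", {
  ds <- fixtureSmallSet()
  sp <- splitDataset(ds, seed = 1)
  m <- buildModel(modelSpec("tiny_random", c(16, 16)), seed = 3)
  fit <- trainModel(m, ds, sp, trainConfig(maxEpochs = 3, batchSize = 8,
                                           seed = 3))
  expect_identical(fit$model@backboneWeights, m@backboneWeights)
  expect_false(identical(fit$model@head, m@head))
})

test_that("training histories are finite, bounded by maxEpochs and improve on separable data", {
  ds <- fixtureSmallSet()
  sp <- splitDataset(ds, seed = 2)
  m <- buildModel(modelSpec("tiny_random", c(32, 32)), seed = 2)
  fit <- trainModel(m, ds, sp, resnetTrainConfig(maxEpochs = 5, seed = 2))
  expect_lte(nrow(fit$history), 5L)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_gt(fit$history$train_acc[nrow(fit$history)],
            fit$history$train_acc[1] - 1e-9)
  expect_lt(fit$history$train_loss[nrow(fit$history)],
            fit$history$train_loss[1])
})

test_that("early stopping fires once validation loss stalls for the patience window", {
  ds <- fixtureSmallSet()
  sp <- splitDataset(ds, seed = 3)
  m <- buildModel(modelSpec("tiny_random", c(16, 16)), seed = 4)
  # an infinitesimal learning rate freezes the head, so the validation
  # loss can never descend and stopping must fire at patience + 1 epochs
  cfg <- trainConfig(lr = 1e-30, maxEpochs = 100, earlyStopPatience = 5,
                     seed = 4)
  fit <- trainModel(m, ds, sp, cfg)
  expect_true(fit$stoppedEarly)
  expect_identical(nrow(fit$history), 6L)
  expect_identical(fit$bestEpoch, 1L)
})

test_that("the plateau schedule multiplies the learning rate by its factor", {
  ds <- fixtureSmallSet()
  sp <- splitDataset(ds, seed = 3)
  m <- buildModel(modelSpec("tiny_random", c(16, 16)), seed = 4)
  cfg <- resnetTrainConfig(lr = 1e-30, maxEpochs = 30,
                           earlyStopPatience = 12, plateauPatience = 5,
                           seed = 4)
  fit <- trainModel(m, ds, sp, cfg)
  expect_equal(fit$history$lr[7], 1e-30 * 0.8)    # reduced after 5 stalls
  expect_true(fit$stoppedEarly)
})

test_that("training requires a nonempty train split and a frozen backbone", {
  ds <- fixtureSmallSet()
  sp <- splitDataset(ds, seed = 1)
  m <- buildModel(modelSpec("tiny_random", c(8, 8)), seed = 1)
  empty <- sp
  expect_error({
    empty@trainIdx <- integer()
    trainModel(m, ds, empty, trainConfig(maxEpochs = 1))
  })
  hot <- modelSpec("tiny_random", c(8, 8), freezeBackbone = FALSE)
  expect_error(trainModel(buildModel(hot, 1), ds, sp,
                          trainConfig(maxEpochs = 1)), "freezeBackbone")
})
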