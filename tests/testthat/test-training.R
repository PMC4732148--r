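# Optimisation components: loss, RMSProp, init, dropout, gradients and
# the training loop contract.

test_that("cross-entropy matches hand-evaluated values", {
  onehot <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(crossEntropyLoss(onehot, c(0, 1)), 0)
  unif <- matrix(1 / 5, 3, 5)
  expect_equal(crossEntropyLoss(unif, c(0, 2, 4)), log(5))
  p <- matrix(c(0.5, 0.5, 0.25, 0.75), 2, byrow = TRUE)
  expect_equal(crossEntropyLoss(p, c(0, 0)), (log(2) + log(4)) / 2)
})

test_that("rmsprop follows its update formula and decays an idle cache", {
  cfg <- trainingConfig(learningRate = 1e-3, rho = 0.9, epsilon = 1e-6)
  layers <- list(list(W = matrix(2, 1, 1)))
  state <- rmspropInit(layers)
  # one unit gradient from a cold cache
  up <- rmspropStep(layers, list(list(W = matrix(1, 1, 1))), state, cfg)
  expect_equal(up$state[[1]]$W[1], 0.1)
  expect_equal(up$layers[[1]]$W[1] - 2, -1e-3 / sqrt(0.1 + 1e-6),
               tolerance = 1e-12)
  expect_equal(up$layers[[1]]$W[1] - 2, -3.1623e-3, tolerance = 1e-4)
  # zero gradient: parameters frozen, cache decays by rho
  up2 <- rmspropStep(up$layers, list(list(W = matrix(0, 1, 1))),
                     up$state, cfg)
  expect_equal(up2$layers[[1]]$W, up$layers[[1]]$W)
  expect_equal(up2$state[[1]]$W[1], 0.9 * 0.1)
  # cold-cache update magnitude is bounded by lr / sqrt(1 - rho)
  g <- matrix(rnorm(1, sd = 10), 1, 1)
  up3 <- rmspropStep(layers, list(list(W = g)), rmspropInit(layers), cfg)
  expect_lte(abs(up3$layers[[1]]$W[1] - 2),
             cfg@learningRate / sqrt(1 - cfg@rho) + 1e-12)
})

test_that("orthogonal init yields orthonormal rows/columns, deterministically", {
  Q <- orthogonalInit(8, 8, seed = 4)
  expect_lt(max(abs(crossprod(Q) - diag(8))), 1e-6)
  W <- orthogonalInit(4, 8, seed = 4)
  expect_lt(max(abs(W %*% t(W) - diag(4))), 1e-6)
  T1 <- orthogonalInit(8, 3, seed = 5)
  expect_lt(max(abs(crossprod(T1) - diag(3))), 1e-6)
  expect_identical(orthogonalInit(6, 6, seed = 9), orthogonalInit(6, 6, seed = 9))
  expect_equal(orthogonalInit(5), numeric(5))   # 1-D shapes are biases: zeros
})

test_that("inverted dropout preserves expectation and zero fraction", {
  x <- rep(1, 1e5)
  expect_identical(dropoutApply(x, 0, training = TRUE), x)
  expect_identical(dropoutApply(x, 0.7, training = FALSE), x)
  set.seed(6)
  y <- dropoutApply(x, 0.5, training = TRUE)
  zeroFrac <- mean(y == 0)
  se <- sqrt(0.25 / 1e5)
  expect_lt(abs(zeroFrac - 0.5), 3 * se)
  # survivors scaled by 1/(1-p): mean stays ~1 (sd of mean = 1/sqrt(n))
  expect_lt(abs(mean(y) - 1), 3 * sqrt(1 / 1e5))
})

test_that("gradients agree with central finite differences on tiny models", {
  for (variant in c("convlstm", "cnn")) {
    sp <- tinySpec(variant)
    m <- buildModel(sp, 7)
    set.seed(11)
    M <- 5
    X <- array(runif(2 * 17 * M), c(2, 17, M))
    y <- sample(0:1, M, replace = TRUE)
    wb <- asBatch(X, y)
    fb <- computeGradients(m, wb)
    lossAt <- function(layers) {
      m2 <- m; m2@layers <- layers
      crossEntropyLoss(modelForward(m2, wb), y)
    }
    for (l in seq_along(m@layers)) {
      for (nm in names(fb$grads[[l]])) {
        g <- fb$grads[[l]][[nm]]
        if (!is.numeric(g)) next
        for (ii in sample(length(g), min(3, length(g)))) {
          h <- 1e-5
          lay <- m@layers
          lay[[l]][[nm]][ii] <- lay[[l]][[nm]][ii] + h
          lp <- lossAt(lay)
          lay[[l]][[nm]][ii] <- lay[[l]][[nm]][ii] - 2 * h
          lm <- lossAt(lay)
          fd <- (lp - lm) / (2 * h)
          relErr <- abs(fd - g[ii]) / max(abs(fd), abs(g[ii]), 1e-6)
          expect_lt(relErr, 1e-4)
        }
      }
    }
  }
})

test_that("parameters killed by ReLU receive zero gradient", {
  sp <- tinySpec("cnn")
  m <- buildModel(sp, 13)
  m@layers[[1]]$b[2] <- -100   # map 2 of layer 1 is dead everywhere
  wb <- separableBatch(M = 8)
  fb <- computeGradients(m, wb)
  expect_true(all(fb$grads[[1]]$K[2, , ] == 0))
  expect_equal(fb$grads[[1]]$b[2], 0)
})

test_that("training drives the loss down on a separable toy and is deterministic", {
  wb <- separableBatch()
  sp <- modelSpec("cnn", 2, 2, windowLen = 17, nFilters = 4L, nUnits = 8L)
  cfg <- trainingConfig(learningRate = 1e-2, batchSize = 20L, dropoutP = 0,
                        maxEpochs = 50L, patience = 50L, seed = 3L)
  fit1 <- trainModel(buildModel(sp, 3), wb, valBatch = NULL, cfg)
  expect_lt(tail(fit1$history$loss, 1), 0.1 * log(2))
  expect_lt(tail(fit1$history$loss, 1), fit1$history$loss[1])
  fit2 <- trainModel(buildModel(sp, 3), wb, valBatch = NULL, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model@layers, fit2$model@layers)
})

test_that("early stopping with patience 0 stops one epoch past the best", {
  wb <- separableBatch(M = 24)
  sp <- modelSpec("cnn", 2, 2, windowLen = 17, nFilters = 2L, nUnits = 4L)
  # huge learning rate so the monitored loss degrades quickly after epoch 1
  cfg <- trainingConfig(learningRate = 1, batchSize = 24L, dropoutP = 0,
                        maxEpochs = 30L, patience = 0L, seed = 2L)
  fit <- trainModel(buildModel(sp, 2), wb, valBatch = NULL, cfg)
  best <- which.max(-fit$history$loss)
  expect_equal(nrow(fit$history), best + 1L)
})
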