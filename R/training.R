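# Training: orthogonal initialisation, inverted dropout, RMSProp and the
# mini-batch training loop with early stopping on validation weighted F1.

#' Random orthogonal matrix initialisation
#'
#' Draws a Gaussian matrix and orthonormalises it by QR decomposition
#' (with the sign of the R diagonal fixed so the result is the unique
#' factor and therefore deterministic given the RNG state). Tall matrices
#' have orthonormal columns, wide matrices orthonormal rows.
#'
#' @param nrow,ncol matrix shape; omitting \code{ncol} requests a 1-D
#'   shape (a bias or peephole vector), which is initialised to zeros.
#' @param seed optional seed; default NULL draws from the current RNG
#'   stream (as during model building).
#' @param gain scalar multiplier on the orthonormal factor. Layers
#'   followed by a ReLU use sqrt(2), compensating the halving of the
#'   activation second moment by the rectifier so signal variance is
#'   preserved through deep stacks; saturating (LSTM, softmax) layers
#'   use the default 1.
#' @return numeric nrow x ncol matrix, or a zero vector of length
#'   \code{nrow} for 1-D shapes.
#' @export
orthogonalInit <- function(nrow, ncol = NULL, seed = NULL, gain = 1) {
  if (is.null(ncol)) return(numeric(nrow))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n1 <- max(nrow, ncol); n2 <- min(nrow, ncol)
  A <- matrix(rnorm(n1 * n2), n1, n2)
  qrA <- qr(A)
  Q <- qr.Q(qrA)
  Q <- Q %*% diag(sign(diag(qr.R(qrA))), n2, n2)
  gain * (if (nrow >= ncol) Q else t(Q))
}

# Bernoulli keep-mask scaled by 1/(1-p) (inverted dropout).
.dropoutMask <- function(dims, p) {
  m <- (runif(prod(dims)) >= p) / (1 - p)
  dim(m) <- dims
  m
}

#' Apply (inverted) dropout
#'
#' In training mode each element is zeroed independently with probability
#' p and the survivors are scaled by 1/(1 - p), so the expected activation
#' is unchanged and inference needs no compensation. In inference mode the
#' input is returned unchanged.
#'
#' @param a numeric vector, matrix or array.
#' @param p dropout probability in [0, 1).
#' @param training logical; FALSE returns \code{a} unchanged.
#' @return object of the same shape as \code{a}.
#' @export
dropoutApply <- function(a, p, training = TRUE) {
  stopifnot(p >= 0, p < 1)
  if (!training || p == 0) return(a)
  dims <- if (is.null(dim(a))) length(a) else dim(a)
  a * .dropoutMask(dims, p)
}

#' One RMSProp update
#'
#' Per-parameter adaptive step: cache <- rho * cache + (1 - rho) * g^2;
#' theta <- theta - lr * g / sqrt(cache + epsilon), applied element-wise
#' to every trainable array.
#'
#' @param layers model layer list (as \code{modelLayers(model)}).
#' @param grads gradient list parallel to \code{layers}.
#' @param state squared-gradient cache (same shapes); use
#'   \code{rmspropInit(layers)} for the zero cache.
#' @param cfg a \linkS4class{TrainingConfig}.
#' @return list with updated \code{layers} and \code{state}.
#' @export
rmspropStep <- function(layers, grads, state, cfg) {
  lr <- cfg@learningRate; rho <- cfg@rho; eps <- cfg@epsilon
  for (l in seq_along(grads)) {
    for (nm in names(grads[[l]])) {
      g <- grads[[l]][[nm]]
      if (!is.numeric(g)) next
      c2 <- rho * state[[l]][[nm]] + (1 - rho) * g * g
      state[[l]][[nm]] <- c2
      layers[[l]][[nm]] <- layers[[l]][[nm]] - lr * g / sqrt(c2 + eps)
    }
  }
  list(layers = layers, state = state)
}

#' Zero RMSProp cache for a layer list
#'
#' @param layers model layer list.
#' @return list of zero arrays matching every trainable array.
#' @export
rmspropInit <- function(layers) {
  lapply(layers, function(lay)
    lapply(lay[!(names(lay) %in% c("type", "activation"))],
           function(x) x * 0))
}

#' Train a model by mini-batch RMSProp
#'
#' Each epoch shuffles the training windows (seeded), iterates mini-batches
#' of \code{batchSize} windows (the final partial batch is kept), applies
#' one RMSProp update per mini-batch with dropout active on the inputs of
#' the dense/recurrent layers, then scores the validation batch by
#' weighted F1 (dropout off). Training stops early after \code{patience}
#' epochs without validation improvement and the best parameters are
#' restored. With no validation batch, the negative epoch loss is the
#' monitored quantity. The run is fully deterministic given (seed, data,
#' config) on a single thread.
#'
#' @param model a freshly built \linkS4class{HARModel}.
#' @param trainBatch a \linkS4class{WindowBatch} of training windows.
#' @param valBatch optional \linkS4class{WindowBatch} for validation.
#' @param cfg a \linkS4class{TrainingConfig}.
#' @param verbose print per-epoch progress.
#' @return list with \code{model} (best parameters) and \code{history}
#'   (data.frame epoch, loss, valF1).
#' @export
trainModel <- function(model, trainBatch, valBatch = NULL,
                       cfg = trainingConfig(), verbose = FALSE) {
  stopifnot(is(model, "HARModel"), is(trainBatch, "WindowBatch"))
  validObject(cfg)
  set.seed(cfg@seed)
  M <- nWindows(trainBatch)
  state <- rmspropInit(model@layers)
  best <- -Inf; bestLayers <- model@layers; wait <- 0L
  history <- data.frame(epoch = integer(), loss = numeric(),
                        valF1 = numeric())
  for (epoch in seq_len(cfg@maxEpochs)) {
    idx <- sample.int(M)
    starts <- seq.int(1L, M, by = cfg@batchSize)
    lossSum <- 0
    diverged <- FALSE
    for (s in starts) {
      take <- idx[s:min(s + cfg@batchSize - 1L, M)]
      xb <- trainBatch@sequences[, , take, drop = FALSE]
      yb <- trainBatch@labels[take]
      bb <- new("WindowBatch", sequences = xb, labels = yb,
                starts = seq_along(take), step = 1L)
      fb <- tryCatch(computeGradients(model, bb, dropoutP = cfg@dropoutP),
                     error = function(e) e)
      if (inherits(fb, "error")) {
        warning("training aborted at epoch ", epoch, ": ",
                conditionMessage(fb))
        diverged <- TRUE
        break
      }
      lossSum <- lossSum + fb$loss * length(take)
      upd <- rmspropStep(model@layers, fb$grads, state, cfg)
      model@layers <- upd$layers
      state <- upd$state
    }
    if (diverged) break
    epochLoss <- lossSum / M
    valF1 <- NA_real_
    if (!is.null(valBatch)) {
      pred <- predictClasses(model, valBatch)
      valF1 <- weightedF1(confusionMatrix(valBatch@labels, pred,
                                          model@spec@nClasses))
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = epochLoss,
                                valF1 = valF1))
    if (verbose)
      cat(sprintf("epoch %3d  loss %.4f  valF1 %s\n", epoch, epochLoss,
                  ifelse(is.na(valF1), "-", sprintf("%.4f", valF1))))
    monitor <- if (is.na(valF1)) -epochLoss else valF1
    if (monitor > best + 1e-12) {
      best <- monitor
      bestLayers <- model@layers
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > cfg@patience) break
    }
  }
  model@layers <- bestLayers
  list(model = model, history = history)
}

#' Write a training history log
#'
#' Plain tab-delimited log with columns epoch, loss, valF1.
#'
#' @param history data.frame as returned by \code{\link{trainModel}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeHistory <- function(history, path) {
  utils::write.table(history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
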