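# Hand-derived reverse-mode gradients of the mean cross-entropy at the
# final-time-step prediction with respect to every trainable scalar.

#' Mean cross-entropy of predicted class distributions
#'
#' Mean over the batch of -log p(true class). Probabilities below 1e-12
#' are clamped to keep the loss finite (a message notes the clamp).
#'
#' @param probs numeric matrix M x nc of class probabilities (rows sum
#'   to 1).
#' @param labelsVec integer vector of M true classes, 0-based.
#' @return non-negative scalar loss.
#' @examples
#' crossEntropyLoss(matrix(c(0.5, 0.5, 0.25, 0.75), 2, byrow = TRUE),
#'                  c(0L, 0L))  # (log 2 + log 4) / 2
#' @export
crossEntropyLoss <- function(probs, labelsVec) {
  probs <- as.matrix(probs)
  M <- nrow(probs)
  stopifnot(length(labelsVec) == M)
  pTrue <- probs[cbind(seq_len(M), as.integer(labelsVec) + 1L)]
  if (any(pTrue < 1e-12)) {
    message("cross-entropy: clamped ", sum(pTrue < 1e-12),
            " probabilities at 1e-12")
    pTrue <- pmax(pTrue, 1e-12)
  }
  -mean(log(pTrue))
}

# Zero-filled gradient structure matching a model's layers.
.zeroGrads <- function(model) {
  lapply(model@layers, function(lay) {
    g <- lapply(lay[!(names(lay) %in% c("type", "activation"))],
                function(x) x * 0)
    g
  })
}

#' Loss and exact gradients on a batch
#'
#' Runs a forward pass (optionally with dropout, drawn from the current
#' RNG stream) and backpropagates the mean cross-entropy of the
#' final-time-step softmax through the whole network: softmax and dense
#' layers, backwards through time across both peephole-LSTM layers (or
#' the two ReLU dense layers of the baseline), and through the four valid
#' convolutions. Gradients are exact (verified against central finite
#' differences in the test suite).
#'
#' @param model a \linkS4class{HARModel}.
#' @param batch a \linkS4class{WindowBatch} (labels 0-based, <
#'   nClasses).
#' @param dropoutP dropout probability on dense-layer inputs (0 disables;
#'   training-time masks are part of the differentiated function).
#' @return list with \code{loss} (scalar) and \code{grads} (list parallel
#'   to \code{modelLayers(model)}).
#' @export
computeGradients <- function(model, batch, dropoutP = 0) {
  stopifnot(is(model, "HARModel"), is(batch, "WindowBatch"))
  sp <- model@spec
  y <- batch@labels
  if (any(y < 0L) || any(y >= sp@nClasses))
    stop("labels out of range for the model's classes")
  fw <- .modelForwardBatch(model, batch@sequences, training = dropoutP > 0,
                           dropoutP = dropoutP, keepCache = TRUE)
  probs <- fw$probs
  M <- nrow(probs)
  loss <- crossEntropyLoss(probs, y)
  if (!is.finite(loss))
    stop(sprintf("non-finite loss (%g); check learning rate and data", loss))
  cache <- fw$cache
  grads <- .zeroGrads(model)
  # d(mean CE)/d(logits) for softmax + cross-entropy
  dLogits <- probs
  dLogits[cbind(seq_len(M), y + 1L)] <- dLogits[cbind(seq_len(M), y + 1L)] - 1
  dLogits <- dLogits / M
  nConv <- sp@nConvLayers
  lsm <- model@layers[[nConv + 3L]]
  if (sp@variant == "convlstm") {
    aTop <- cache$aTop
    grads[[nConv + 3L]]$W <- crossprod(aTop, dLogits)
    grads[[nConv + 3L]]$b <- colSums(dLogits)
    dATop <- dLogits %*% t(lsm$W)
    if (!is.null(cache$mask3)) dATop <- dATop * cache$mask3
    T <- cache$T
    n <- sp@nUnits
    zero <- matrix(0, M, n)
    dHs7 <- rep(list(zero), T)
    dHs7[[T]] <- dATop
    l7 <- model@layers[[nConv + 2L]]
    bk7 <- .batchLstmBackward(cache$Xs7, cache$lstm7$cache, l7, dHs7)
    grads[[nConv + 2L]] <- bk7$grads
    dHs6 <- bk7$dXs
    if (!is.null(cache$masks2))
      for (t in seq_len(T)) dHs6[[t]] <- dHs6[[t]] * cache$masks2[[t]]
    l6 <- model@layers[[nConv + 1L]]
    bk6 <- .batchLstmBackward(cache$Xs, cache$lstm6$cache, l6, dHs6)
    grads[[nConv + 1L]] <- bk6$grads
    # reassemble gradient w.r.t. conv output (sequence-last F, D, M, T)
    dA <- array(0, dim = cache$convOutDim)
    Fm <- sp@nFilters; D <- sp@nChannels
    for (t in seq_len(T)) {
      dx <- bk6$dXs[[t]]
      if (!is.null(cache$masks1)) dx <- dx * cache$masks1[[t]]
      dA[, , , t] <- array(t(dx), c(Fm, D, M))
    }
  } else {
    h7d <- cache$h7d
    grads[[nConv + 3L]]$W <- crossprod(h7d, dLogits)
    grads[[nConv + 3L]]$b <- colSums(dLogits)
    dH7 <- dLogits %*% t(lsm$W)
    if (!is.null(cache$mask3)) dH7 <- dH7 * cache$mask3
    dZ7 <- dH7 * (cache$z7 > 0)
    l7 <- model@layers[[nConv + 2L]]
    grads[[nConv + 2L]]$W <- crossprod(cache$h6d, dZ7)
    grads[[nConv + 2L]]$b <- colSums(dZ7)
    dH6 <- dZ7 %*% t(l7$W)
    if (!is.null(cache$mask2)) dH6 <- dH6 * cache$mask2
    dZ6 <- dH6 * (cache$z6 > 0)
    l6 <- model@layers[[nConv + 1L]]
    grads[[nConv + 1L]]$W <- crossprod(cache$a, dZ6)
    grads[[nConv + 1L]]$b <- colSums(dZ6)
    dFlatT <- dZ6 %*% t(l6$W)          # M x (F*D*S5)
    if (!is.null(cache$mask1)) dFlatT <- dFlatT * cache$mask1
    # back to the sequence-last conv layout (F, D, M, S5)
    cod <- cache$convOutDim
    dA <- aperm(array(t(dFlatT), cod[c(1L, 2L, 4L, 3L)]), c(1L, 2L, 4L, 3L))
  }
  for (l in rev(seq_len(nConv))) {
    cc <- cache$conv[[l]]
    lay <- model@layers[[l]]
    bk <- .batchConvBackward(dA, cc$Z, cc$A, lay$K, cc$inDim)
    grads[[l]]$K <- bk$dK
    grads[[l]]$b <- bk$db
    dA <- bk$dA
  }
  list(loss = loss, grads = grads)
}
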