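# Model assembly, parameter accounting and the full forward pass.

#' Layer input widths implied by an architecture
#'
#' Two widths matter when sizing the first dense/recurrent layer: the
#' per-time-step width F * D (all feature maps across all channels at one
#' time index of the last conv layer) fed to the LSTM variant, and the
#' fully flattened width F * D * S5 fed to the baseline CNN. For the
#' reference 113-channel, 24-sample architecture these are 7232 and
#' 57,856.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @return list with \code{perStep}, \code{flattened} and \code{finalMapLen}
#'   (the sequence length S after the conv stack).
#' @examples
#' inputWidths(modelSpec("convlstm", 113, 18))$perStep   # 7232
#' inputWidths(modelSpec("cnn", 113, 18))$flattened      # 57856
#' @export
inputWidths <- function(spec) {
  stopifnot(is(spec, "ModelSpec"))
  S <- spec@windowLen
  for (l in seq_len(spec@nConvLayers))
    S <- featureMapLength(S, spec@kernelLen)
  list(perStep = spec@nFilters * spec@nChannels,
       flattened = spec@nFilters * spec@nChannels * S,
       finalMapLen = S)
}

.emptyLstmLayer <- function(nIn, n) {
  list(type = "lstm",
       Wai = matrix(0, nIn, n), Waf = matrix(0, nIn, n),
       Wac = matrix(0, nIn, n), Wao = matrix(0, nIn, n),
       Whi = matrix(0, n, n), Whf = matrix(0, n, n),
       Whc = matrix(0, n, n), Who = matrix(0, n, n),
       wci = numeric(n), wcf = numeric(n), wco = numeric(n),
       bi = numeric(n), bf = numeric(n), bc = numeric(n), bo = numeric(n))
}

#' Build a model with freshly initialised parameters
#'
#' Allocates every layer at the shapes implied by the spec and initialises
#' all 2-D weight matrices (conv kernels reshaped to F_out x F_in * P, the
#' four LSTM input and four recurrent matrices separately, dense and
#' softmax weights) with random orthogonal matrices; ReLU-followed
#' layers (conv and hidden dense) carry a sqrt(2) gain so activation
#' variance is preserved through the rectified stack, LSTM and softmax
#' layers use gain 1. Biases and peephole vectors start at zero.
#' Deterministic given the seed.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param seed integer seed.
#' @return a \linkS4class{HARModel}.
#' @examples
#' m <- buildModel(modelSpec("convlstm", 6, 3, nFilters = 8L, nUnits = 4L), 1)
#' sum(countParameters(m)$parameters)
#' @export
buildModel <- function(spec, seed = 1L) {
  stopifnot(is(spec, "ModelSpec"))
  validObject(spec)
  set.seed(as.integer(seed))
  Fm <- spec@nFilters; P <- spec@kernelLen; U <- spec@nUnits
  layers <- vector("list", spec@nConvLayers + 3L)
  for (l in seq_len(spec@nConvLayers)) {
    Fin <- if (l == 1L) 1L else Fm
    K <- orthogonalInit(Fm, Fin * P, gain = sqrt(2))
    dim(K) <- c(Fm, Fin, P)
    layers[[l]] <- list(type = "conv", K = K, b = numeric(Fm))
  }
  w <- inputWidths(spec)
  if (spec@variant == "convlstm") {
    for (j in 1:2) {
      nIn <- if (j == 1L) w$perStep else U
      lay <- .emptyLstmLayer(nIn, U)
      for (nm in c("Wai", "Waf", "Wac", "Wao", "Whi", "Whf", "Whc", "Who"))
        lay[[nm]] <- orthogonalInit(nrow(lay[[nm]]), ncol(lay[[nm]]))
      layers[[spec@nConvLayers + j]] <- lay
    }
  } else {
    for (j in 1:2) {
      nIn <- if (j == 1L) w$flattened else U
      layers[[spec@nConvLayers + j]] <-
        list(type = "dense", W = orthogonalInit(nIn, U, gain = sqrt(2)),
             b = numeric(U), activation = "relu")
    }
  }
  layers[[spec@nConvLayers + 3L]] <-
    list(type = "dense", W = orthogonalInit(U, spec@nClasses),
         b = numeric(spec@nClasses), activation = "softmax")
  new("HARModel", spec = spec, layers = layers, seed = as.integer(seed))
}

#' Count trainable parameters per layer
#'
#' Counts every trainable scalar: conv kernels plus biases; for each LSTM
#' layer the four input matrices, four recurrent matrices, four biases and
#' three peephole vectors (4 n n_in + 4 n^2 + 4 n + 3 n); for dense layers
#' weights plus biases. Layer numbering follows the convention that the
#' input is layer 1, so the first convolutional layer is layer 2.
#'
#' @param model a \linkS4class{HARModel}.
#' @return data.frame with columns layer (2, 3, ...), type and parameters.
#' @examples
#' m <- buildModel(modelSpec("cnn", 6, 3, nFilters = 8L, nUnits = 4L), 1)
#' countParameters(m)
#' @export
countParameters <- function(model) {
  stopifnot(is(model, "HARModel"))
  counts <- vapply(model@layers, function(lay) {
    switch(lay$type,
      conv  = length(lay$K) + length(lay$b),
      lstm  = length(lay$Wai) * 4L + length(lay$Whi) * 4L +
              length(lay$bi) * 4L + length(lay$wci) * 3L,
      dense = length(lay$W) + length(lay$b))
  }, numeric(1))
  types <- vapply(model@layers, function(lay) {
    if (lay$type == "dense" && identical(lay$activation, "softmax"))
      "softmax" else lay$type
  }, character(1))
  data.frame(layer = seq_along(counts) + 1L, type = types,
             parameters = as.integer(counts))
}

# Full forward pass over a batch with optional dropout and caches.
# A0: D x S1 x M array. Returns probs (M x nc) and, if keepCache, the
# per-layer intermediates needed for the backward pass.
.modelForwardBatch <- function(model, A0, training = FALSE, dropoutP = 0,
                               keepCache = FALSE) {
  sp <- model@spec
  d <- dim(A0)
  if (d[1L] != sp@nChannels || d[2L] != sp@windowLen)
    stop(sprintf("window shape %d x %d does not match spec %d x %d",
                 d[1L], d[2L], sp@nChannels, sp@windowLen))
  M <- d[3L]
  # internal layout is sequence-last (F x D x M x S): kernel-tap slices
  # and per-time-step extraction then touch contiguous memory
  A <- aperm(A0, c(1L, 3L, 2L))
  dim(A) <- c(1L, d[1L], M, d[2L])
  convCache <- if (keepCache) vector("list", sp@nConvLayers) else NULL
  for (l in seq_len(sp@nConvLayers)) {
    lay <- model@layers[[l]]
    out <- .batchConvForward(A, lay$K, lay$b)
    if (keepCache)
      convCache[[l]] <- list(Z = out$Z, A = out$A, inDim = dim(A))
    A <- relu(out$Z)
  }
  useDrop <- training && dropoutP > 0
  nc <- sp@nClasses
  Fm <- sp@nFilters; D <- sp@nChannels
  if (sp@variant == "convlstm") {
    T <- dim(A)[4L]
    Xs <- vector("list", T)
    masks1 <- if (useDrop) vector("list", T) else NULL
    for (t in seq_len(T)) {
      x <- matrix(A[, , , t], Fm * D, M)
      x <- t(x)
      if (useDrop) {
        mk <- .dropoutMask(dim(x), dropoutP)
        masks1[[t]] <- mk
        x <- x * mk
      }
      Xs[[t]] <- x
    }
    l6 <- model@layers[[sp@nConvLayers + 1L]]
    l7 <- model@layers[[sp@nConvLayers + 2L]]
    out6 <- .batchLstmForward(Xs, l6, keepCache)
    Xs7 <- out6$Hs
    masks2 <- if (useDrop) vector("list", T) else NULL
    if (useDrop) {
      for (t in seq_len(T)) {
        mk <- .dropoutMask(dim(Xs7[[t]]), dropoutP)
        masks2[[t]] <- mk
        Xs7[[t]] <- Xs7[[t]] * mk
      }
    }
    out7 <- .batchLstmForward(Xs7, l7, keepCache)
    aTop <- out7$Hs[[T]]
    mask3 <- NULL
    if (useDrop) {
      mask3 <- .dropoutMask(dim(aTop), dropoutP)
      aTop <- aTop * mask3
    }
    lsm <- model@layers[[sp@nConvLayers + 3L]]
    logits <- aTop %*% lsm$W + rep(lsm$b, each = M)
    probs <- .rowSoftmax(logits)
    if (!keepCache) return(list(probs = probs))
    list(probs = probs,
         cache = list(conv = convCache, Xs = Xs, masks1 = masks1,
                      lstm6 = out6, Xs7 = Xs7, masks2 = masks2,
                      lstm7 = out7, mask3 = mask3, aTop = aTop,
                      convOutDim = dim(A), T = T))
  } else {
    # flattened order is map-fastest (F, D, S5) per window: permute the
    # sequence-last layout back before collapsing
    Ap <- aperm(A, c(1L, 2L, 4L, 3L))
    flat <- matrix(Ap, length(Ap) / M, M)   # (F*D*S5) x M
    a <- t(flat)
    mask1 <- NULL
    if (useDrop) {
      mask1 <- .dropoutMask(dim(a), dropoutP)
      a <- a * mask1
    }
    l6 <- model@layers[[sp@nConvLayers + 1L]]
    z6 <- a %*% l6$W + rep(l6$b, each = M)
    h6 <- relu(z6)
    mask2 <- NULL
    h6d <- h6
    if (useDrop) {
      mask2 <- .dropoutMask(dim(h6), dropoutP)
      h6d <- h6 * mask2
    }
    l7 <- model@layers[[sp@nConvLayers + 2L]]
    z7 <- h6d %*% l7$W + rep(l7$b, each = M)
    h7 <- relu(z7)
    mask3 <- NULL
    h7d <- h7
    if (useDrop) {
      mask3 <- .dropoutMask(dim(h7), dropoutP)
      h7d <- h7 * mask3
    }
    lsm <- model@layers[[sp@nConvLayers + 3L]]
    logits <- h7d %*% lsm$W + rep(lsm$b, each = M)
    probs <- .rowSoftmax(logits)
    if (!keepCache) return(list(probs = probs))
    list(probs = probs,
         cache = list(conv = convCache, a = a, mask1 = mask1,
                      z6 = z6, h6d = h6d, mask2 = mask2,
                      z7 = z7, h7d = h7d, mask3 = mask3,
                      convOutDim = dim(A)))
  }
}

#' Class probabilities for one window or a batch of windows
#'
#' Runs the full network: the conv stack, then either the two LSTM layers
#' with the softmax applied to the hidden value at the final time step
#' only (the recurrent variant reports its prediction once the whole
#' window has been observed), or flattening plus two ReLU dense layers and
#' the softmax (baseline CNN). Dropout is inactive at inference.
#'
#' @param model a \linkS4class{HARModel}.
#' @param windows a \linkS4class{WindowBatch}, a D x S1 matrix (single
#'   window) or a D x S1 x M array.
#' @return numeric matrix M x nClasses of class probabilities (rows sum
#'   to 1).
#' @export
modelForward <- function(model, windows) {
  stopifnot(is(model, "HARModel"))
  A0 <- if (is(windows, "WindowBatch")) windows@sequences
        else if (is.matrix(windows)) array(windows, c(dim(windows), 1L))
        else windows
  .modelForwardBatch(model, A0)$probs
}

#' Predicted classes for a batch of windows
#'
#' Argmax of \code{\link{modelForward}} per window; ties resolve to the
#' lowest class index so predictions are deterministic.
#'
#' @param model a \linkS4class{HARModel}.
#' @param windows as in \code{\link{modelForward}}.
#' @return integer vector of 0-based class labels.
#' @export
predictClasses <- function(model, windows) {
  probs <- modelForward(model, windows)
  max.col(probs, ties.method = "first") - 1L
}
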