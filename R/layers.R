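# Layer-level forward computations: valid temporal convolution applied to
# every sensor channel independently, peephole LSTM steps, dense layers and
# a shift-invariant softmax. Exported functions take a single sequence;
# the .batch* internals vectorise over a window batch via BLAS.

#' Length of a feature map after a valid convolution
#'
#' A valid (no-padding) convolution is only computed where kernel and input
#' fully overlap, so each layer shortens the sequence: S_out = S - P + 1.
#'
#' @param inputLen input sequence length S.
#' @param kernelLen kernel length P.
#' @return integer output length.
#' @examples
#' featureMapLength(24, 5)                    # 20
#' Reduce(featureMapLength, rep(5, 4), 24)    # 8 after four layers
#' @export
featureMapLength <- function(inputLen, kernelLen) {
  if (inputLen < kernelLen)
    stop(sprintf("kernel longer than input (%d > %d)", kernelLen, inputLen))
  as.integer(inputLen - kernelLen + 1L)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Forward pass of one temporal convolution layer
#'
#' Computes, for output map j, channel d and valid position tau,
#' ReLU(b_j + sum_f sum_p K[j, f, p] * x[f, d, tau + p - 1]). The kernels
#' are one-dimensional in time and shared across all D sensor channels;
#' there is no mixing across channels, so the channel axis is preserved
#' and only the time axis shrinks (by P - 1).
#'
#' @param x input feature maps, array F_in x D x S (the network input has
#'   F_in = 1).
#' @param kernels array F_out x F_in x P of kernel weights.
#' @param bias numeric vector of F_out biases.
#' @param activation "relu" (default) or "linear" (pre-activation, used to
#'   verify linearity).
#' @return array F_out x D x (S - P + 1) of feature maps.
#' @export
convLayerForward <- function(x, kernels, bias, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  if (length(dim(x)) != 3L) stop("x must be an F_in x D x S array")
  if (dim(x)[1L] != dim(kernels)[2L])
    stop(sprintf("input has %d maps but kernels expect %d",
                 dim(x)[1L], dim(kernels)[2L]))
  # a single window is a 1-element batch; with batch extent 1 inserted
  # before the time axis the memory layout is unchanged, so only the dim
  # attribute needs rewriting on the way in and out
  d3 <- dim(x)
  dim(x) <- c(d3[1L], d3[2L], 1L, d3[3L])
  out <- .batchConvForward(x, kernels, bias)
  z <- out$Z
  dz <- dim(z)
  dim(z) <- c(dz[1L], dz[2L], dz[4L])
  if (activation == "relu") relu(z) else z
}

# Batch conv forward in sequence-last layout. A: F_in x D x M x S (time
# as the outermost dimension, so each kernel-tap slice is one contiguous
# block). Accumulates one BLAS product per kernel tap p
# (Z_{:,s} += K_p A_{:,s+p-1}), avoiding any im2col buffer; the backward
# pass re-extracts the input slices from the cached layer input A.
.batchConvForward <- function(A, kernels, bias) {
  dA <- dim(A)
  Fin <- dA[1L]; D <- dA[2L]; M <- dA[3L]; S <- dA[4L]
  Fout <- dim(kernels)[1L]; P <- dim(kernels)[3L]
  if (S < P) stop(sprintf("kernel longer than input (%d > %d)", P, S))
  Sout <- S - P + 1L
  cols <- D * M * Sout
  Z <- matrix(bias, Fout, cols)
  for (p in seq_len(P)) {
    Xp <- A[, , , p:(p + Sout - 1L), drop = FALSE]
    dim(Xp) <- c(Fin, cols)
    Z <- Z + matrix(kernels[, , p], Fout, Fin) %*% Xp
  }
  dim(Z) <- c(Fout, D, M, Sout)
  list(Z = Z, A = A, Sout = Sout)
}

# Backward through one conv layer. dH: gradient w.r.t. ReLU output
# (F_out x D x M x Sout). A is the cached layer input
# (F_in x D x M x S). Returns gradients and dA (F_in x D x M x S).
.batchConvBackward <- function(dH, Z, A, kernels, inDim) {
  Fout <- dim(kernels)[1L]; Fin <- dim(kernels)[2L]; P <- dim(kernels)[3L]
  dZ <- dH * (Z > 0)
  cols <- length(dZ) / Fout
  dim(dZ) <- c(Fout, cols)
  db <- rowSums(dZ)
  D <- inDim[2L]; M <- inDim[3L]; S <- inDim[4L]
  Sout <- S - P + 1L
  dK <- array(0, dim = c(Fout, Fin, P))
  dA <- array(0, dim = inDim)
  for (p in seq_len(P)) {
    idx <- p:(p + Sout - 1L)
    Xp <- A[, , , idx, drop = FALSE]
    dim(Xp) <- c(Fin, cols)
    dK[, , p] <- tcrossprod(dZ, Xp)
    dAp <- crossprod(matrix(kernels[, , p], Fout, Fin), dZ)
    dim(dAp) <- c(Fin, D, M, Sout)
    dA[, , , idx] <- dA[, , , idx, drop = FALSE] + dAp
  }
  list(dK = dK, db = db, dA = dA)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One forward step of a peephole LSTM cell layer
#'
#' Gate order: input gate i and forget gate f read the previous cell state
#' through element-wise peephole weights; the cell is updated as
#' c_t = f_t * c_{t-1} + i_t * tanh(W_ac a_t + W_hc h_{t-1} + b_c); the
#' output gate reads the new cell state; h_t = o_t * tanh(c_t). Gate
#' nonlinearities are logistic sigmoids, cell input/output nonlinearities
#' hyperbolic tangents.
#'
#' @param input numeric vector a_t of length n_in.
#' @param state list with elements \code{h} and \code{c} (numeric vectors
#'   of length n_cells); use zeros at sequence start.
#' @param params list of LSTM parameters: matrices Wai, Waf, Wac, Wao
#'   (n_in x n), Whi, Whf, Whc, Who (n x n), peephole vectors wci, wcf,
#'   wco (n), biases bi, bf, bc, bo (n).
#' @return list(h, c), the updated state.
#' @export
lstmStep <- function(input, state, params) {
  p <- params
  n_in <- nrow(p$Wai)
  if (length(input) != n_in)
    stop(sprintf("input length %d does not match n_in = %d",
                 length(input), n_in))
  h <- state$h; c0 <- state$c
  i <- sigmoid(drop(input %*% p$Wai) + drop(h %*% p$Whi) + p$wci * c0 + p$bi)
  f <- sigmoid(drop(input %*% p$Waf) + drop(h %*% p$Whf) + p$wcf * c0 + p$bf)
  g <- tanh(drop(input %*% p$Wac) + drop(h %*% p$Whc) + p$bc)
  c1 <- f * c0 + i * g
  o <- sigmoid(drop(input %*% p$Wao) + drop(h %*% p$Who) + p$wco * c1 + p$bo)
  list(h = o * tanh(c1), c = c1)
}

#' Forward pass of an LSTM layer over a full sequence
#'
#' Iterates \code{\link{lstmStep}} over t = 1..T from a zero initial state
#' and returns every hidden value. In the full network, the input at time
#' t of the first recurrent layer is the flattened vector of all feature
#' maps of the last convolutional layer at time t (length F * D).
#'
#' @param inputs numeric matrix T x n_in (one row per time step).
#' @param params LSTM parameter list as in \code{\link{lstmStep}}.
#' @return numeric matrix T x n_cells of hidden values.
#' @export
lstmLayerForward <- function(inputs, params) {
  inputs <- as.matrix(inputs)
  T <- nrow(inputs)
  if (T == 0L) stop("empty input sequence")
  n <- length(params$bi)
  state <- list(h = numeric(n), c = numeric(n))
  H <- matrix(0, T, n)
  for (t in seq_len(T)) {
    state <- lstmStep(inputs[t, ], state, params)
    H[t, ] <- state$h
  }
  H
}

# Batch LSTM forward. Xs: list of T matrices (M x n_in). Returns hidden
# sequence plus the per-step cache needed for backpropagation through time.
.batchLstmForward <- function(Xs, p, keepCache = FALSE) {
  T <- length(Xs)
  M <- nrow(Xs[[1L]])
  n <- length(p$bi)
  H <- matrix(0, M, n); C <- matrix(0, M, n)
  Hs <- vector("list", T)
  cache <- if (keepCache) vector("list", T) else NULL
  for (t in seq_len(T)) {
    X <- Xs[[t]]
    i <- sigmoid(X %*% p$Wai + H %*% p$Whi + C * rep(p$wci, each = M) +
                   rep(p$bi, each = M))
    f <- sigmoid(X %*% p$Waf + H %*% p$Whf + C * rep(p$wcf, each = M) +
                   rep(p$bf, each = M))
    g <- tanh(X %*% p$Wac + H %*% p$Whc + rep(p$bc, each = M))
    C1 <- f * C + i * g
    o <- sigmoid(X %*% p$Wao + H %*% p$Who + C1 * rep(p$wco, each = M) +
                   rep(p$bo, each = M))
    tC1 <- tanh(C1)
    H1 <- o * tC1
    if (keepCache)
      cache[[t]] <- list(i = i, f = f, g = g, o = o, cPrev = C, c = C1,
                         tanhc = tC1)
    H <- H1; C <- C1
    Hs[[t]] <- H
  }
  list(Hs = Hs, cache = cache)
}

# BPTT through one LSTM layer. dHs: list of T matrices (M x n) of
# gradients arriving from above at each step (zero matrices where the loss
# does not touch the step). Returns per-parameter gradients and dXs.
.batchLstmBackward <- function(Xs, cache, p, dHs) {
  T <- length(Xs)
  M <- nrow(Xs[[1L]])
  n <- length(p$bi)
  g <- list(Wai = 0 * p$Wai, Waf = 0 * p$Waf, Wac = 0 * p$Wac,
            Wao = 0 * p$Wao, Whi = 0 * p$Whi, Whf = 0 * p$Whf,
            Whc = 0 * p$Whc, Who = 0 * p$Who,
            wci = 0 * p$wci, wcf = 0 * p$wcf, wco = 0 * p$wco,
            bi = 0 * p$bi, bf = 0 * p$bf, bc = 0 * p$bc, bo = 0 * p$bo)
  dXs <- vector("list", T)
  dHnext <- matrix(0, M, n)
  dCnext <- matrix(0, M, n)
  for (t in rev(seq_len(T))) {
    cc <- cache[[t]]
    hPrev <- if (t > 1L) cache[[t - 1L]]$o * cache[[t - 1L]]$tanhc
             else matrix(0, M, n)
    dH <- dHs[[t]] + dHnext
    do <- dH * cc$tanhc
    dzo <- do * cc$o * (1 - cc$o)
    dC <- dCnext + dH * cc$o * (1 - cc$tanhc^2) +
      dzo * rep(p$wco, each = M)
    di <- dC * cc$g
    dzi <- di * cc$i * (1 - cc$i)
    df <- dC * cc$cPrev
    dzf <- df * cc$f * (1 - cc$f)
    dg <- dC * cc$i
    dzg <- dg * (1 - cc$g^2)
    X <- Xs[[t]]
    g$Wai <- g$Wai + crossprod(X, dzi)
    g$Waf <- g$Waf + crossprod(X, dzf)
    g$Wac <- g$Wac + crossprod(X, dzg)
    g$Wao <- g$Wao + crossprod(X, dzo)
    g$Whi <- g$Whi + crossprod(hPrev, dzi)
    g$Whf <- g$Whf + crossprod(hPrev, dzf)
    g$Whc <- g$Whc + crossprod(hPrev, dzg)
    g$Who <- g$Who + crossprod(hPrev, dzo)
    g$wci <- g$wci + colSums(dzi * cc$cPrev)
    g$wcf <- g$wcf + colSums(dzf * cc$cPrev)
    g$wco <- g$wco + colSums(dzo * cc$c)
    g$bi <- g$bi + colSums(dzi)
    g$bf <- g$bf + colSums(dzf)
    g$bc <- g$bc + colSums(dzg)
    g$bo <- g$bo + colSums(dzo)
    dXs[[t]] <- dzi %*% t(p$Wai) + dzf %*% t(p$Waf) +
      dzg %*% t(p$Wac) + dzo %*% t(p$Wao)
    dHnext <- dzi %*% t(p$Whi) + dzf %*% t(p$Whf) +
      dzg %*% t(p$Whc) + dzo %*% t(p$Who)
    dCnext <- dC * cc$f + dzi * rep(p$wci, each = M) +
      dzf * rep(p$wcf, each = M)
  }
  list(grads = g, dXs = dXs)
}

#' Forward pass of a dense (fully-connected) layer
#'
#' Computes activation(W' a + b).
#'
#' @param a numeric input vector of length n_in.
#' @param W weight matrix n_in x n_out.
#' @param b bias vector of length n_out.
#' @param activation "relu", "softmax" or "linear".
#' @return numeric vector of length n_out.
#' @export
denseLayerForward <- function(a, W, b, activation = c("relu", "softmax", "linear")) {
  activation <- match.arg(activation)
  if (length(a) != nrow(W))
    stop(sprintf("input length %d does not match weight rows %d",
                 length(a), nrow(W)))
  z <- drop(a %*% W) + b
  switch(activation, relu = relu(z), softmax = softmax(z), linear = z)
}

#' Shift-invariant softmax
#'
#' exp(z - max(z)) / sum(exp(z - max(z))); components are positive and sum
#' to one, and adding a constant to all logits leaves the output unchanged.
#'
#' @param z numeric vector of finite logits.
#' @return probability vector of the same length.
#' @examples
#' softmax(log(1:3))  # 1/6, 2/6, 3/6
#' @export
softmax <- function(z) {
  if (any(!is.finite(z))) stop("softmax requires finite logits")
  e <- exp(z - max(z))
  e / sum(e)
}

# Row-wise softmax for an M x nc logit matrix.
.rowSoftmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}
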