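# Independent brute-force oracles and small fixture builders. The oracles
# evaluate the defining formulas term by term with plain loops and never
# share code with the implementation they check.

# Valid 1-D convolution, direct double-sum evaluation per (j, d, tau).
convOracle <- function(x, K, b, reluOn = TRUE) {
  Fin <- dim(x)[1]; D <- dim(x)[2]; S <- dim(x)[3]
  Fout <- dim(K)[1]; P <- dim(K)[3]
  Sout <- S - P + 1
  out <- array(0, c(Fout, D, Sout))
  for (j in seq_len(Fout)) for (d in seq_len(D)) for (tau in seq_len(Sout)) {
    s <- b[j]
    for (f in seq_len(Fin)) for (p in seq_len(P))
      s <- s + K[j, f, p] * x[f, d, tau + p - 1]
    out[j, d, tau] <- if (reluOn) max(0, s) else s
  }
  out
}

# One peephole-LSTM step evaluated gate by gate with scalar arithmetic.
lstmStepOracle <- function(a, h, c0, p) {
  sig <- function(z) 1 / (1 + exp(-z))
  n <- length(p$bi)
  i <- f <- g <- cc <- o <- hh <- numeric(n)
  for (u in seq_len(n)) {
    i[u] <- sig(sum(a * p$Wai[, u]) + sum(h * p$Whi[, u]) +
                  p$wci[u] * c0[u] + p$bi[u])
    f[u] <- sig(sum(a * p$Waf[, u]) + sum(h * p$Whf[, u]) +
                  p$wcf[u] * c0[u] + p$bf[u])
    g[u] <- tanh(sum(a * p$Wac[, u]) + sum(h * p$Whc[, u]) + p$bc[u])
    cc[u] <- f[u] * c0[u] + i[u] * g[u]
  }
  for (u in seq_len(n)) {
    o[u] <- sig(sum(a * p$Wao[, u]) + sum(h * p$Who[, u]) +
                  p$wco[u] * cc[u] + p$bo[u])
    hh[u] <- o[u] * tanh(cc[u])
  }
  list(h = hh, c = cc)
}

denseOracle <- function(a, W, b, act = "relu") {
  n <- ncol(W)
  z <- numeric(n)
  for (u in seq_len(n)) z[u] <- sum(a * W[, u]) + b[u]
  switch(act,
         relu = pmax(0, z),
         linear = z,
         softmax = exp(z - max(z)) / sum(exp(z - max(z))))
}

# Random LSTM parameter set at a modest weight scale.
randomLstmParams <- function(nIn, n, scale = 0.4) {
  rm <- function(a, b) matrix(rnorm(a * b, sd = scale), a, b)
  list(Wai = rm(nIn, n), Waf = rm(nIn, n), Wac = rm(nIn, n),
       Wao = rm(nIn, n),
       Whi = rm(n, n), Whf = rm(n, n), Whc = rm(n, n), Who = rm(n, n),
       wci = rnorm(n, sd = scale), wcf = rnorm(n, sd = scale),
       wco = rnorm(n, sd = scale),
       bi = rnorm(n, sd = scale), bf = rnorm(n, sd = scale),
       bc = rnorm(n, sd = scale), bo = rnorm(n, sd = scale))
}

# Wrap an array of windows as a WindowBatch.
asBatch <- function(X, y) {
  new("WindowBatch", sequences = X, labels = as.integer(y),
      starts = seq_along(y), step = 1L)
}

# Tiny two-class linearly separable window set: class 1 has a higher mean
# level on channel 1. Used for learnability and determinism checks.
separableBatch <- function(M = 60, D = 2, S1 = 17, seed = 5) {
  set.seed(seed)
  y <- rep(0:1, length.out = M)
  X <- array(runif(D * S1 * M, 0, 0.4), c(D, S1, M))
  X[1, , y == 1] <- X[1, , y == 1] + 0.5
  asBatch(X, y)
}

# Tiny model specs used across gradient and oracle tests.
tinySpec <- function(variant) {
  modelSpec(variant, nChannels = 2, nClasses = 2, windowLen = 17,
            nFilters = 3L, nUnits = 4L)
}

# Preprocess a recording into windows, reusing training bounds if given.
prepWindows <- function(rec, bounds = NULL, cfg = windowConfig(),
                        dropNull = FALSE) {
  nb <- normalizeChannels(interpolateMissing(rec), bounds)
  wb <- slidingWindows(nb$recording, cfg)
  if (dropNull) wb <- dropNullWindows(wb)
  list(wb = wb, bounds = nb$bounds)
}
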