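# Forward computations and parameter accounting of the two architectures.

test_that("feature-map length shrinks by P-1 per valid convolution", {
  expect_equal(featureMapLength(24, 5), 20L)
  expect_equal(Reduce(featureMapLength, rep(5, 4), 24), 8L)
  expect_equal(featureMapLength(5, 5), 1L)
  expect_error(featureMapLength(4, 5), "kernel longer than input")
})

test_that("conv layer reproduces degenerate kernels exactly", {
  x <- array(runif(1 * 2 * 10), c(1, 2, 10))
  # all-zero kernels: output is ReLU of the bias everywhere
  K0 <- array(0, c(3, 1, 5))
  out <- convLayerForward(x, K0, c(0.3, -0.2, 0))
  expect_true(all(out[1, , ] == 0.3))
  expect_true(all(out[2, , ] == 0))
  # delta kernel: unit weight at the first tap copies the input
  Kd <- array(0, c(1, 1, 5)); Kd[1, 1, 1] <- 1
  out <- convLayerForward(x, Kd, 0)
  expect_equal(out[1, , ], x[1, , 1:6])
})

test_that("conv layer matches the brute-force double-sum oracle", {
  set.seed(11)
  x <- array(rnorm(1 * 3 * 10), c(1, 3, 10))
  K <- array(rnorm(2 * 1 * 5), c(2, 1, 5)); b <- rnorm(2)
  got <- convLayerForward(x, K, b)
  want <- convOracle(x, K, b)
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-10)
  # multi-map input as in deeper layers
  x2 <- array(rnorm(4 * 2 * 9), c(4, 2, 9))
  K2 <- array(rnorm(3 * 4 * 5), c(3, 4, 5)); b2 <- rnorm(3)
  got2 <- convLayerForward(x2, K2, b2)
  want2 <- convOracle(x2, K2, b2)
  expect_lt(max(abs(got2 - want2)) / max(abs(want2)), 1e-10)
})

test_that("pre-activation convolution is linear and shift-equivariant", {
  set.seed(12)
  K <- array(rnorm(2 * 1 * 5), c(2, 1, 5)); b <- rnorm(2)
  x <- array(rnorm(1 * 2 * 12), c(1, 2, 12))
  y <- array(rnorm(1 * 2 * 12), c(1, 2, 12))
  lin <- function(v) convLayerForward(v, K, numeric(2), activation = "linear")
  expect_lt(max(abs(lin(2 * x + 3 * y) - (2 * lin(x) + 3 * lin(y)))), 1e-10)
  # translation equivariance: shifting the input in time shifts the output
  xs <- x; xs[, , 2:12] <- x[, , 1:11]; xs[, , 1] <- 0
  full <- lin(x); shifted <- lin(xs)
  expect_equal(shifted[, , 2:8], full[, , 1:7], tolerance = 1e-12)
})

test_that("zero-parameter and saturated LSTM cells behave analytically", {
  nIn <- 3; n <- 2
  zp <- list(Wai = matrix(0, nIn, n), Waf = matrix(0, nIn, n),
             Wac = matrix(0, nIn, n), Wao = matrix(0, nIn, n),
             Whi = matrix(0, n, n), Whf = matrix(0, n, n),
             Whc = matrix(0, n, n), Who = matrix(0, n, n),
             wci = numeric(n), wcf = numeric(n), wco = numeric(n),
             bi = numeric(n), bf = numeric(n), bc = numeric(n),
             bo = numeric(n))
  st <- lstmStep(runif(nIn), list(h = numeric(n), c = numeric(n)), zp)
  expect_equal(st$h, numeric(n))
  expect_equal(st$c, numeric(n))
  # saturated forget gate with a dead input path preserves the cell state
  mem <- zp; mem$bf <- rep(100, n)
  c0 <- c(0.7, -1.2)
  st <- lstmStep(runif(nIn), list(h = numeric(n), c = c0), mem)
  expect_equal(st$c, c0, tolerance = 1e-12)
})

test_that("lstm layer equals chained scalar-oracle steps", {
  set.seed(13)
  p <- randomLstmParams(2, 1)
  X <- matrix(rnorm(6), 3, 2)
  H <- lstmLayerForward(X, p)
  h <- numeric(1); c0 <- numeric(1)
  for (t in 1:3) {
    st <- lstmStepOracle(X[t, ], h, c0, p)
    h <- st$h; c0 <- st$c
    expect_equal(H[t, ], h, tolerance = 1e-12)
  }
  # T = 1 reduces to a single step; multi-cell chaining also matches
  p2 <- randomLstmParams(3, 4)
  X2 <- matrix(rnorm(12), 4, 3)
  H2 <- lstmLayerForward(X2, p2)
  expect_equal(H2[1, ],
               lstmStep(X2[1, ], list(h = numeric(4), c = numeric(4)), p2)$h)
  h <- numeric(4); c0 <- numeric(4)
  for (t in 1:4) {
    st <- lstmStepOracle(X2[t, ], h, c0, p2)
    h <- st$h; c0 <- st$c
  }
  expect_equal(H2[4, ], h, tolerance = 1e-12)
  expect_error(lstmLayerForward(matrix(0, 0, 3), p2), "empty")
  expect_error(lstmStep(rnorm(5), list(h = numeric(4), c = numeric(4)), p2),
               "does not match")
})

test_that("dense layer matches direct summation and handles identities", {
  a <- c(0.2, 0.5, 0.1)
  expect_equal(denseLayerForward(a, diag(3), numeric(3)), a)
  expect_equal(denseLayerForward(a, matrix(0, 3, 2), c(-1, 2)), c(0, 2))
  set.seed(14)
  W <- matrix(rnorm(12), 3, 4); b <- rnorm(4)
  expect_equal(denseLayerForward(a, W, b), denseOracle(a, W, b),
               tolerance = 1e-12)
  expect_equal(denseLayerForward(a, W, b, activation = "softmax"),
               denseOracle(a, W, b, "softmax"), tolerance = 1e-12)
  expect_error(denseLayerForward(c(1, 2), W, b), "does not match")
})

test_that("softmax is a shift-invariant probability vector", {
  expect_equal(softmax(rep(3, 5)), rep(0.2, 5))
  expect_equal(softmax(log(1:3)), (1:3) / 6)
  z <- rnorm(7)
  expect_equal(softmax(z), softmax(z + 42), tolerance = 1e-12)
  expect_equal(sum(softmax(z)), 1)
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("reference architecture widths and per-layer counts are exact", {
  spL <- modelSpec("convlstm", 113, 18)
  spC <- modelSpec("cnn", 113, 18)
  expect_equal(inputWidths(spL)$perStep, 7232L)
  expect_equal(inputWidths(spC)$flattened, 57856L)
  expect_equal(inputWidths(spC)$finalMapLen, 8L)
  ptL <- countParameters(buildModel(spL, 1))
  ptC <- countParameters(buildModel(spC, 1))
  expect_equal(ptL$parameters[1], 384L)            # 64*5 kernels + 64 biases
  expect_equal(ptL$parameters[2:4], rep(20544L, 3))
  expect_equal(ptC$parameters[5], 7405696L)        # 57856*128 + 128
  expect_equal(ptC$parameters[6], 16512L)
  # closed-form LSTM count: 4*n*n_in + 4*n^2 + 4n + 3n
  expect_equal(ptL$parameters[6], 4L*128L*128L + 4L*128L*128L + 4L*128L + 3L*128L)
  expect_equal(ptL$parameters[6], 131968L)
  expect_equal(ptL$parameters[7], 128L * 18L + 18L)
})

test_that("parameter counts match closed forms for arbitrary shapes", {
  sp <- modelSpec("convlstm", nChannels = 7, nClasses = 3, windowLen = 20,
                  nFilters = 6L, nUnits = 5L)
  pt <- countParameters(buildModel(sp, 2))
  Fm <- 6; P <- 5; n <- 5; nIn <- 6 * 7
  expect_equal(pt$parameters,
               as.integer(c(Fm * P + Fm, rep(Fm * Fm * P + Fm, 3),
                            4 * n * nIn + 4 * n^2 + 4 * n + 3 * n,
                            4 * n * n + 4 * n^2 + 4 * n + 3 * n,
                            n * 3 + 3)))
})

test_that("model building is deterministic and validates window length", {
  sp <- tinySpec("convlstm")
  m1 <- buildModel(sp, 9); m2 <- buildModel(sp, 9)
  expect_identical(m1@layers, m2@layers)
  m3 <- buildModel(sp, 10)
  expect_false(identical(m1@layers, m3@layers))
  expect_error(modelSpec("convlstm", 2, 2, windowLen = 16),
               "at least 17")
})

test_that("model forward matches the composed per-layer oracles", {
  for (variant in c("convlstm", "cnn")) {
    sp <- tinySpec(variant)
    m <- buildModel(sp, 21)
    set.seed(22)
    x <- array(runif(2 * 17), c(2, 17))
    got <- modelForward(m, x)[1, ]
    # oracle: compose the brute-force layer evaluations
    A <- array(x, c(1, 2, 17))
    for (l in 1:4) A <- convOracle(A, m@layers[[l]]$K, m@layers[[l]]$b)
    Fm <- sp@nFilters; D <- sp@nChannels; S5 <- dim(A)[3]
    if (variant == "convlstm") {
      X6 <- t(sapply(seq_len(S5), function(t) as.vector(A[, , t])))
      H6 <- matrix(0, S5, sp@nUnits); h <- numeric(sp@nUnits); c0 <- h
      for (t in seq_len(S5)) {
        st <- lstmStepOracle(X6[t, ], h, c0, m@layers[[5]])
        h <- st$h; c0 <- st$c; H6[t, ] <- h
      }
      h <- numeric(sp@nUnits); c0 <- h
      for (t in seq_len(S5)) {
        st <- lstmStepOracle(H6[t, ], h, c0, m@layers[[6]])
        h <- st$h; c0 <- st$c
      }
      top <- h
    } else {
      a <- as.vector(A)
      top <- denseOracle(denseOracle(a, m@layers[[5]]$W, m@layers[[5]]$b),
                         m@layers[[6]]$W, m@layers[[6]]$b)
    }
    want <- denseOracle(top, m@layers[[7]]$W, m@layers[[7]]$b, "softmax")
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-10)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
})

test_that("shape conservation holds through random conv stacks", {
  set.seed(23)
  for (rep in 1:5) {
    D <- sample(1:6, 1); S1 <- sample(17:30, 1); M <- sample(1:4, 1)
    sp <- modelSpec("cnn", D, 2, windowLen = S1, nFilters = 4L, nUnits = 3L)
    m <- buildModel(sp, rep)
    A <- array(runif(D * S1 * M), c(1, D, M, S1))  # sequence-last layout
    S <- S1
    for (l in 1:4) {
      out <- deepHAR:::.batchConvForward(A, m@layers[[l]]$K, m@layers[[l]]$b)
      A <- out$Z; A[A < 0] <- 0
      S <- S - 4
      expect_equal(dim(A), c(4L, D, M, S))
    }
  }
})

test_that("prediction depends only on samples inside the window", {
  sp <- tinySpec("convlstm")
  m <- buildModel(sp, 31)
  set.seed(32)
  rec1 <- matrix(runif(2 * 60), 2, 60)
  rec2 <- rec1; rec2[, 41:60] <- runif(2 * 20)  # perturb outside window 1
  w1 <- rec1[, 1:17]; w2 <- rec2[, 1:17]
  expect_identical(modelForward(m, w1), modelForward(m, w2))
})

test_that("checkpoints round-trip bit-exactly through the text archive", {
  for (variant in c("convlstm", "cnn")) {
    sp <- tinySpec(variant)
    m <- buildModel(sp, 77)
    # perturb away from the initial state so the test is not trivial
    m@layers[[1]]$b <- rnorm(length(m@layers[[1]]$b))
    path <- tempfile(fileext = ".ckpt")
    saveModel(m, path)
    m2 <- loadModel(path)
    expect_identical(m2@layers, m@layers)
    expect_equal(spec(m2)@variant, variant)
    unlink(path)
  }
})
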