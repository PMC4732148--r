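# Confusion matrices and the sample-weighted F1 headline metric.

test_that("confusion matrix tallies actual rows against predicted columns", {
  cm <- confusionMatrix(c(0, 0, 1), c(0, 1, 1), 2)
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 1L), 2))
  # perfect prediction: diagonal with row sums = class counts
  y <- sample(0:3, 50, replace = TRUE)
  cmp <- confusionMatrix(y, y, 4)
  expect_equal(unname(diag(cmp)), unname(as.vector(table(factor(y, 0:3)))))
  expect_true(all(cmp[upper.tri(cmp) | lower.tri(cmp)] == 0))
  # conservation
  p <- sample(0:3, 50, replace = TRUE)
  expect_equal(sum(confusionMatrix(y, p, 4)), 50)
  expect_error(confusionMatrix(c(0, 5), c(0, 1), 4), "lie in")
})

test_that("weighted F1 matches hand-evaluated confusion matrices", {
  expect_equal(weightedF1(diag(c(5, 9, 2))), 1)
  # 2-class: F1_1 = 0.8421..., F1_2 = 0.8571..., weights 0.5/0.5
  cm <- matrix(c(8, 1, 2, 9), 2)
  f11 <- 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8)
  f12 <- 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9)
  expect_equal(weightedF1(cm), 0.5 * f11 + 0.5 * f12)
  expect_equal(weightedF1(cm), 0.84962, tolerance = 1e-4)
  # everything predicted as class 1 on balanced classes
  cm2 <- matrix(c(10, 10, 0, 0), 2)
  expect_equal(weightedF1(cm2), 1 / 3)
  expect_error(weightedF1(matrix(0, 2, 2)), "empty")
})

test_that("weighted F1 agrees with the caret reference implementation", {
  skip_if_not_installed("caret")
  set.seed(42)
  for (rep in 1:500) {
    nc <- sample(2:6, 1)
    cm <- matrix(rpois(nc * nc, 3), nc)
    if (sum(cm) == 0 || any(rowSums(cm) == 0)) next
    # expand the matrix into label vectors for the reference library
    actual <- rep(rep(0:(nc - 1), each = nc), times = as.vector(t(cm)))
    predicted <- rep(rep(0:(nc - 1), times = nc), times = as.vector(t(cm)))
    ref <- caret::confusionMatrix(factor(predicted, 0:(nc - 1)),
                                  factor(actual, 0:(nc - 1)),
                                  mode = "prec_recall")
    f1 <- if (nc == 2) {
      # caret reports the positive class only in binary mode; use byClass
      # for both orientations
      pos <- ref$byClass["F1"]
      neg <- caret::confusionMatrix(factor(predicted, 0:1),
                                    factor(actual, 0:1), positive = "1",
                                    mode = "prec_recall")$byClass["F1"]
      c(pos, neg)
    } else ref$byClass[, "F1"]
    f1[is.na(f1)] <- 0
    w <- rowSums(cm) / sum(cm)
    expect_equal(weightedF1(cm), sum(w * f1), tolerance = 1e-12)
  }
})

test_that("weighted F1 is bounded, permutation-invariant and maximal iff diagonal", {
  set.seed(43)
  for (rep in 1:50) {
    nc <- sample(2:5, 1)
    cm <- matrix(rpois(nc * nc, 2), nc)
    if (sum(cm) == 0) next
    f <- weightedF1(cm)
    expect_gte(f, 0); expect_lte(f, 1)
    perm <- sample(nc)
    expect_equal(weightedF1(cm[perm, perm]), f, tolerance = 1e-12)
    offDiag <- sum(cm) - sum(diag(cm))
    if (f == 1) expect_equal(offDiag, 0)
    if (offDiag == 0 && all(diag(cm) > 0)) expect_equal(f, 1)
  }
})

test_that("evaluateModel reproduces the metric computed independently", {
  sp <- modelSpec("cnn", 2, 3, windowLen = 17, nFilters = 3L, nUnits = 4L)
  m <- buildModel(sp, 17)
  set.seed(18)
  X <- array(runif(2 * 17 * 40), c(2, 17, 40))
  y <- sample(0:2, 40, replace = TRUE)
  wb <- asBatch(X, y)
  rep <- evaluateModel(m, wb)
  pred <- predictClasses(m, wb)
  expect_equal(weightedF1Score(rep),
               weightedF1(confusionMatrix(y, pred, 3)))
  expect_equal(sum(confusion(rep)), 40)
  expect_equal(perClassMetrics(rep)$n, as.vector(table(factor(y, 0:2))))
  expect_equal(sum(perClassMetrics(rep)$weight), 1)
})

test_that("excluding the Null class shrinks the evaluated set accordingly", {
  # model over the 2 gesture classes; batch still carries Null windows
  sp <- modelSpec("cnn", 2, 2, windowLen = 17, nFilters = 3L, nUnits = 4L)
  m <- buildModel(sp, 19)
  set.seed(20)
  X <- array(runif(2 * 17 * 40), c(2, 17, 40))
  y <- c(rep(0L, 30), rep(1L, 5), rep(2L, 5))  # 75% Null
  wb <- asBatch(X, y)
  rep <- evaluateModel(m, wb, nullMode = "excluded")
  expect_equal(sum(confusion(rep)), 10)
  expect_equal(nrow(confusion(rep)), 2)
  # a model sized for the full class set is flagged as a mismatch
  expect_error(evaluateModel(m, wb, nullMode = "included"), "nc mismatch")
})

test_that("a perfect predictor scores weighted F1 1 in both modes", {
  # construct a model-free check through the metric path used by reports
  y <- c(rep(0L, 12), 1L, 1L, 2L, 2L, 2L)
  cmInc <- confusionMatrix(y, y, 3)
  expect_equal(weightedF1(cmInc), 1)
  yg <- y[y != 0L] - 1L
  expect_equal(weightedF1(confusionMatrix(yg, yg, 2)), 1)
})

test_that("evaluation reports serialise as delimited tables", {
  sp <- modelSpec("cnn", 2, 2, windowLen = 17, nFilters = 2L, nUnits = 3L)
  m <- buildModel(sp, 23)
  wb <- separableBatch(M = 20)
  rep <- evaluateModel(m, wb)
  prefix <- tempfile()
  paths <- writeEvaluationReport(rep, prefix)
  expect_true(all(file.exists(paths)))
  cm <- as.matrix(read.table(paths[1], sep = "\t", header = TRUE,
                             row.names = 1))
  expect_equal(sum(cm), 20)
  summaryLine <- readLines(paths[3])
  expect_match(summaryLine, "weighted_f1")
  unlink(paths)
})
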