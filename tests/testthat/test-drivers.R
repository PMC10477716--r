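test_that("random forest finds a dominant linear driver", {
  set.seed(20)
  n <- 48
  X <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(X) <- c("x1", "x2", "x3", "x4", "x5")
  tbl <- cbind(Cum = 2 * X$x1 + rnorm(n, sd = 0.5), X)
  res <- rfImportance(tbl, response = "Cum", nTrees = 300, nPerm = 30,
                      seed = 4)
  expect_equal(res$importance$predictor[1], "x1")
  expect_lt(res$importance$p[res$importance$predictor == "x1"], 0.05)
  expect_gt(res$modelR2, 0.5)
  expect_lt(res$modelP, 0.05)

  # bit-reproducible under the same seed
  res2 <- rfImportance(tbl, response = "Cum", nTrees = 300, nPerm = 30,
                       seed = 4)
  expect_identical(res$importance, res2$importance)
  expect_identical(res$modelP, res2$modelP)
})

test_that("random forest guards its degenerate inputs", {
  set.seed(21)
  tbl <- data.frame(Cum = rep(3, 12), a = rnorm(12), b = rnorm(12))
  expect_error(rfImportance(tbl, nTrees = 50, nPerm = 20, seed = 1),
               "constant response")
  tbl2 <- data.frame(Cum = rnorm(12), a = rnorm(12), b = rnorm(12))
  expect_warning(rfImportance(tbl2, nTrees = 50, nPerm = 5, seed = 1),
                 "coarse")
})

test_that("variance partition fractions always sum to one", {
  set.seed(22)
  n <- 40
  X1 <- matrix(rnorm(n * 2), n, 2)
  X2 <- matrix(rnorm(n * 2), n, 2)
  y <- X1[, 1] + 0.5 * X2[, 1] + rnorm(n)
  v <- variancePartition(y, X1, X2)
  expect_equal(v$uniqueX1 + v$uniqueX2 + v$shared + v$residual, 1,
               tolerance = 1e-9)

  # swapping blocks swaps unique fractions exactly
  w <- variancePartition(y, X2, X1)
  expect_equal(w$uniqueX1, v$uniqueX2, tolerance = 1e-12)
  expect_equal(w$uniqueX2, v$uniqueX1, tolerance = 1e-12)
  expect_equal(w$shared, v$shared, tolerance = 1e-12)

  # affine rescaling of a predictor changes nothing
  X1b <- X1; X1b[, 1] <- 100 * X1b[, 1] - 7
  vb <- variancePartition(y, X1b, X2)
  expect_equal(vb$uniqueX1, v$uniqueX1, tolerance = 1e-9)
  expect_equal(vb$shared, v$shared, tolerance = 1e-9)
})

test_that("variance partition limits behave as expected", {
  set.seed(23)
  n <- 60
  X1 <- matrix(rnorm(n * 2), n, 2)
  y <- X1 %*% c(1, -2)  # exactly in span(X1)
  noise <- matrix(rnorm(n * 2), n, 2)
  v <- variancePartition(as.numeric(y), X1, noise)
  expect_equal(v$R2X1, 1, tolerance = 1e-9)
  expect_lt(v$residual, 1e-9)

  # duplicated block: no unique fractions, all shared
  y2 <- X1[, 1] + rnorm(n)
  vd <- variancePartition(y2, X1, X1)
  expect_equal(vd$uniqueX1, 0, tolerance = 1e-9)
  expect_equal(vd$uniqueX2, 0, tolerance = 1e-9)
  expect_equal(vd$shared, vd$R2X1, tolerance = 1e-9)

  expect_error(variancePartition(rnorm(5), matrix(rnorm(25), 5),
                                 matrix(rnorm(5), 5)),
               "unidentifiable")
})

test_that("orthogonalized blocks share almost nothing", {
  set.seed(24)
  n <- 200
  X1 <- matrix(rnorm(n * 2), n, 2)
  raw <- matrix(rnorm(n * 2), n, 2)
  X2 <- qr.resid(qr(cbind(1, X1)), raw)  # orthogonal to X1
  y <- X1[, 1] + X2[, 1] + rnorm(n)
  v <- variancePartition(y, X1, X2)
  expect_lt(abs(v$shared), 0.02)
})

test_that("within-category shares cover trivial and symmetric cases", {
  set.seed(25)
  n <- 100
  x <- rnorm(n)
  y <- x + rnorm(n, sd = 0.3)
  one <- withinCategoryShare(y, data.frame(x = x))
  expect_equal(one$shareStandalone, 1)
  expect_equal(one$shareHierarchical, 1)

  # orthogonal centered predictors with equal standalone R2: 50/50
  b <- scale(matrix(rnorm(n * 2), n, 2), center = TRUE, scale = FALSE)
  b <- qr.Q(qr(b))  # orthonormal, still mean-zero
  y2 <- b[, 1] + b[, 2]
  sh <- withinCategoryShare(y2, data.frame(p1 = b[, 1], p2 = b[, 2]))
  expect_equal(sh$shareStandalone, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sh$shareHierarchical, c(0.5, 0.5), tolerance = 1e-9)

  # a dominant driver takes most of its block's share
  z <- rnorm(n)
  yd <- 3 * z + rnorm(n, sd = 0.4)
  blk <- data.frame(acc = z, other = rnorm(n), more = rnorm(n))
  shd <- withinCategoryShare(yd, blk)
  expect_gt(shd$shareStandalone[shd$predictor == "acc"], 0.85)

  expect_error(withinCategoryShare(rep(2, 10),
                                   data.frame(a = rnorm(10))),
               "undefined|shares")
})
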