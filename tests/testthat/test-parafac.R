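test_that("Tucker congruence is a scale-invariant cosine", {
  a <- c(1, 2, 3)
  expect_equal(tuckerCongruence(a, a), 1.0)
  expect_equal(tuckerCongruence(a, 2 * a), 1.0)
  expect_equal(tuckerCongruence(c(1, 0), c(0, 1)), 0.0)
  expect_error(tuckerCongruence(a, c(0, 0, 0)), "zero vector")
  expect_error(tuckerCongruence(a, c(1, 2)), "equal length")
})

test_that("noiseless rank-3 cubes are recovered essentially exactly", {
  d <- synthDesign(seed = 21, noiseSd = 0)
  sim <- simulateEEMs(d)
  corr <- correctEEMs(sim$cube, sim$blank)
  m <- fitParafac(corr, 3, nStarts = 2, seed = 3)
  expect_gte(explainedVariance(m), 0.999)
  tc <- truthCongruence(m, sim$truth)
  expect_true(all(tc$tccEx >= 0.999))
  expect_true(all(tc$tccEm >= 0.999))

  # scores proportional to truth scores, component-wise
  area <- corr@ramanArea
  sc <- scores(m)[, tc$perm, drop = FALSE]
  for (r in 1:3) {
    ratio <- sc[, r] / (sim$truth$scores[, r] / area)
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-3)
  }

  # components ordered by ascending emission peak
  pk <- componentPeaks(m)
  expect_identical(order(pk$em), 1:3)
})

test_that("ALS is deterministic and its loss never increases", {
  d <- synthDesign(seed = 22)
  sim <- simulateEEMs(d)
  corr <- correctEEMs(sim$cube, sim$blank)
  m1 <- fitParafac(corr, 3, nStarts = 2, seed = 11)
  m2 <- fitParafac(corr, 3, nStarts = 2, seed = 11)
  expect_identical(scores(m1), scores(m2))
  expect_identical(emLoadings(m1), emLoadings(m2))
  tr <- m1@convergence$lossTrace
  expect_true(all(diff(tr) <= 1e-8 * tr[1]))
})

test_that("the fit is invariant to sample order", {
  d <- synthDesign(seed = 23, noiseSd = 0, replicates = 4)
  sim <- simulateEEMs(d)
  corr <- correctEEMs(sim$cube, sim$blank)
  set.seed(99)
  perm <- sample(seq_along(sampleIds(corr)))
  permCube <- EEMCube(
    intensities(corr)[perm, , , drop = FALSE], exGrid(corr), emGrid(corr),
    sampleIds = sampleIds(corr)[perm], corrected = TRUE,
    blankId = corr@blankId, ramanArea = corr@ramanArea,
    excisedCells = corr@excisedCells
  )
  m1 <- fitParafac(corr, 3, nStarts = 2, seed = 5)
  m2 <- fitParafac(permCube, 3, nStarts = 2, seed = 5)
  for (r in 1:3) {
    expect_gt(tuckerCongruence(emLoadings(m1)[, r], emLoadings(m2)[, r]),
              0.99999)
    expect_gt(tuckerCongruence(exLoadings(m1)[, r], exLoadings(m2)[, r]),
              0.99999)
  }
  expect_equal(scores(m2), scores(m1)[perm, ], tolerance = 1e-4)
})

test_that("a rank-1 cube is identified up to scale", {
  d <- synthDesign(seed = 24, noiseSd = 0)
  sim <- simulateEEMs(d, list(componentSpec(280, 401, 15, 28)))
  corr <- correctEEMs(sim$cube, sim$blank)
  m <- fitParafac(corr, 1, nStarts = 2, seed = 2)
  expect_gte(explainedVariance(m), 0.9999)
  ratio <- scores(m)[, 1] / sim$truth$scores[, 1]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
})

test_that("Fmax is score times the loading maxima", {
  d <- synthDesign(seed = 25, noiseSd = 0)
  sim <- simulateEEMs(d)
  corr <- correctEEMs(sim$cube, sim$blank)
  m <- fitParafac(corr, 3, nStarts = 2, seed = 3)
  fm <- computeFmax(m)
  manual <- scores(m)[2, 2] * max(exLoadings(m)[, 2]) *
    max(emLoadings(m)[, 2])
  expect_equal(fm[2, 2], manual)
  expect_true(all(fm >= 0))

  # zero score gives zero Fmax
  m0 <- m
  m0@scores[1, 1] <- 0
  expect_equal(computeFmax(m0)[1, 1], 0)

  # relative Fmax matches truth proportions on noiseless data
  tc <- truthCongruence(m, sim$truth)
  mxT <- apply(sim$truth$exLoadings, 2, max) *
    apply(sim$truth$emLoadings, 2, max)
  fmT <- sweep(sim$truth$scores, 2, mxT, `*`)
  relT <- fmT / rowSums(fmT)
  rel <- computeFmax(m, relative = TRUE)[, tc$perm]
  expect_equal(unname(rel), unname(relT), tolerance = 1e-5)
})

test_that("split halves of duplicated noiseless samples agree perfectly", {
  d <- synthDesign(seed = 26, noiseSd = 0, replicates = 4)
  sim <- simulateEEMs(d)
  corr <- correctEEMs(sim$cube, sim$blank)
  dupVals <- intensities(corr)[rep(seq_len(12), 2), , , drop = FALSE]
  dup <- EEMCube(dupVals, exGrid(corr), emGrid(corr),
                 sampleIds = paste0("S", 1:24), corrected = TRUE,
                 blankId = corr@blankId, ramanArea = corr@ramanArea,
                 excisedCells = corr@excisedCells)
  sh <- splitHalfValidate(dup, 3, nSplits = 2, seed = 4, nStarts = 2)
  expect_true(sh$pass)
  expect_true(all(sh$splits$tccEx > 1 - 1e-6))
  expect_true(all(sh$splits$tccEm > 1 - 1e-6))
})

test_that("library matching follows the >0.95-on-both-modes rule", {
  d <- synthDesign(seed = 27, noiseSd = 0)
  sim <- simulateEEMs(d)
  corr <- correctEEMs(sim$cube, sim$blank)
  m <- fitParafac(corr, 3, nStarts = 2, seed = 3)

  mt <- matchComponents(m)  # default library holds the truth templates
  expect_true(all(mt$matched))
  expect_true(all(mt$tccEx >= 0.999 & mt$tccEm >= 0.999))
  expect_setequal(mt$entry, c("LIB1", "LIB2", "LIB3"))
  expect_true("Microbial humic acid-like" %in% mt$label)

  # orthogonalized library entries never match
  orthLib <- lapply(1:3, function(i) {
    ex <- numeric(51); ex[i] <- 1
    em <- numeric(351); em[i] <- 1
    list(id = paste0("ORTH", i), label = "orthogonal",
         exWavelength = stdExGrid, exLoading = ex,
         emWavelength = stdEmGrid, emLoading = em)
  })
  mo <- matchComponents(m, orthLib)
  expect_false(any(mo$matched))

  expect_error(matchComponents(m, list()), "empty")
})
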