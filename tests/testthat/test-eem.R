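rawBlank <- function(fill) {
  arr <- array(fill, dim = c(1, length(stdEmGrid), length(stdExGrid)))
  EEMCube(arr, stdExGrid, stdEmGrid, sampleIds = "blank")
}

test_that("Raman area integrates the ex-350 emission scan", {
  # constant emission 1.0 over the 57-nm window: rectangle of area 57
  expect_equal(ramanArea(rawBlank(1)), 57)

  # zeros: degenerate
  expect_error(ramanArea(rawBlank(0)), "non-positive Raman area")

  # triangular peak height h, base w: area h*w/2 (within trapezoid error)
  h <- 4
  arr <- array(0, dim = c(1, length(stdEmGrid), length(stdExGrid)))
  peak <- 399.5
  w <- 40
  tri <- pmax(0, h * (1 - abs(stdEmGrid - peak) / (w / 2)))
  arr[1, , which(stdExGrid == 350)] <- tri
  blank <- EEMCube(arr, stdExGrid, stdEmGrid, sampleIds = "blank")
  expect_equal(ramanArea(blank), h * w / 2, tolerance = 0.02)
})

test_that("correction subtracts the normalized blank and masks scatter", {
  d <- synthDesign(seed = 7, noiseSd = 0)
  sim <- simulateEEMs(d)

  # a cube identical to the blank corrects to ~0 outside excised bands
  blk <- intensities(sim$blank)
  arr <- array(rep(blk, each = 2), dim = c(2, dim(blk)[2], dim(blk)[3]))
  same <- EEMCube(arr, stdExGrid, stdEmGrid)
  corr0 <- correctEEMs(same, sim$blank)
  expect_lt(max(abs(intensities(corr0)), na.rm = TRUE), 1e-10)

  # blank + trilinear signal corrects to signal / ramanArea
  corr <- correctEEMs(sim$cube, sim$blank)
  area <- ramanArea(sim$blank)
  vals <- intensities(corr)
  recon <- array(0, dim = dim(vals))
  for (r in 1:3) {
    slab <- outer(sim$truth$emLoadings[, r], sim$truth$exLoadings[, r])
    for (i in seq_len(dim(vals)[1])) {
      recon[i, , ] <- recon[i, , ] + sim$truth$scores[i, r] * slab / area
    }
  }
  obs <- !is.na(vals)
  expect_lt(max(abs(vals[obs] - recon[obs])), 1e-8)

  # masked cells exist and are counted
  expect_gt(corr@excisedCells, 0)
  expect_equal(sum(is.na(vals[1, , ])), corr@excisedCells)
})

test_that("Raman normalization is scale-invariant", {
  d <- synthDesign(seed = 9, noiseSd = 0)
  sim <- simulateEEMs(d)
  corrA <- correctEEMs(sim$cube, sim$blank)
  scaled <- EEMCube(intensities(sim$cube) * 7.3, stdExGrid, stdEmGrid,
                    sampleIds = sampleIds(sim$cube))
  blankScaled <- EEMCube(intensities(sim$blank) * 7.3, stdExGrid,
                         stdEmGrid, sampleIds = "blank")
  corrB <- correctEEMs(scaled, blankScaled)
  expect_equal(intensities(corrA), intensities(corrB), tolerance = 1e-10)
})

test_that("correcting an already-corrected cube raises", {
  d <- synthDesign(seed = 7, noiseSd = 0)
  sim <- simulateEEMs(d)
  corr <- correctEEMs(sim$cube, sim$blank)
  expect_error(correctEEMs(corr, sim$blank), "already corrected")
})

test_that("grid mismatch is reported with the offending axis", {
  d <- synthDesign(seed = 7, noiseSd = 0)
  sim <- simulateEEMs(d)
  blkVals <- intensities(sim$blank)[, , -1, drop = FALSE]
  oddBlank <- EEMCube(blkVals, stdExGrid[-1], stdEmGrid,
                      sampleIds = "blank")
  expect_error(correctEEMs(sim$cube, oddBlank), "excitation grids")
})

test_that("BIX equals the em380/em430 ratio at ex 310", {
  cube <- deltaCube(list(
    list(sample = 1, em = 380, ex = 310, value = 2),
    list(sample = 1, em = 430, ex = 310, value = 1)
  ))
  idx <- suppressWarnings(fluorescenceIndices(cube))
  expect_equal(idx$BIX, 2.0, tolerance = 1e-9)
  expect_true(idx$autochthonous)
})

test_that("HIX is the humic proportion of ex-254 emission", {
  # all ex-254 fluorescence in the 435-480 band: HIX = 1
  cubeHi <- bandCube(c(250, 255), 435, 480, 3)
  expect_equal(suppressWarnings(fluorescenceIndices(cubeHi)$HIX), 1.0,
               tolerance = 1e-9)

  # equal band sums: HIX = 0.5 (bands have equal width, equal fill)
  arr <- intensities(bandCube(c(250, 255), 435, 480, 3))
  arr[, stdEmGrid >= 300 & stdEmGrid <= 345, stdExGrid %in% c(250, 255)] <- 3
  cubeEq <- EEMCube(arr, stdExGrid, stdEmGrid, corrected = TRUE)
  expect_equal(suppressWarnings(fluorescenceIndices(cubeEq)$HIX), 0.5,
               tolerance = 1e-9)

  # HIX is a proportion for any non-negative EEM
  d <- synthDesign(seed = 11)
  sim <- simulateEEMs(d)
  idx <- fluorescenceIndices(correctEEMs(sim$cube, sim$blank))
  expect_true(all(idx$HIX >= 0 & idx$HIX <= 1))
})

test_that("zero denominators yield missing indices with a warning", {
  cube <- deltaCube(list(
    list(sample = 1, em = 380, ex = 310, value = 2)
  ))
  expect_warning(idx <- fluorescenceIndices(cube), "missing")
  expect_true(is.na(idx$BIX))
})

test_that("EEM CSV round-trips through the grid dialect", {
  d <- synthDesign(seed = 12, replicates = 2)
  sim <- simulateEEMs(d)
  dir <- tempfile("eems")
  paths <- writeEEMCsv(sim$cube, dir)
  back <- readEEMCsv(paths)
  expect_equal(intensities(back)[order(sampleIds(back)), , ],
               intensities(sim$cube)[order(sampleIds(sim$cube)), , ],
               tolerance = 1e-12)
})
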