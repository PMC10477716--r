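#' Raman peak area of a blank EEM
#'
#' Trapezoidal integral of the blank's emission scan at excitation 350 nm
#' over the Raman emission window. The area is the unit basis for Raman
#' normalization: corrected intensities are expressed in Raman units.
#'
#' @param blank an [EEMCube-class] with a single sample (the blank).
#' @param window emission integration window (nm); the default
#'   371-428 nm brackets the water Raman band at ex 350 nm.
#' @return Positive scalar area.
#' @export
ramanArea <- function(blank, window = c(371, 428)) {
  .stopIfNot(is(blank, "EEMCube"), "blank must be an EEMCube")
  .stopIfNot(length(sampleIds(blank)) == 1L,
             "blank cube must contain exactly one sample")
  .stopIfNot(350 %in% exGrid(blank),
             "blank does not contain the ex = 350 nm column")
  em <- emGrid(blank)
  sel <- em >= window[1] & em <= window[2]
  scan <- intensities(blank)[1, sel, which(exGrid(blank) == 350)]
  area <- .trapz(em[sel], scan)
  if (!is.finite(area) || area <= 0) {
    stop(sprintf("non-positive Raman area for blank '%s'",
                 sampleIds(blank)), call. = FALSE)
  }
  area
}

# mask of first/second-order Rayleigh bands (em within +-width of ex and
# of 2*ex); TRUE = excise
.scatterMask <- function(exG, emG, width = 10) {
  mask <- matrix(FALSE, length(emG), length(exG))
  for (k in seq_along(exG)) {
    mask[, k] <- abs(emG - exG[k]) <= width | abs(emG - 2 * exG[k]) <= width
  }
  mask
}

#' Blank-correct and Raman-normalize an EEM cube
#'
#' Both sample cube and blank are divided by the blank's Raman peak area,
#' the normalized blank is subtracted cell-wise (removing Raman and most
#' scatter), residual first- and second-order Rayleigh bands are excised
#' to missing, and any remaining negative cells are clipped to zero (the
#' count is recorded in the result's provenance).
#'
#' @param cube raw sample [EEMCube-class].
#' @param blank raw single-sample blank [EEMCube-class] on the same grids.
#' @param scatterWidth half-width (nm) of the excised Rayleigh bands.
#' @param ramanWindow passed to [ramanArea()].
#' @return A corrected [EEMCube-class]; attributes `clippedNegatives`
#'   gives the number of cells clipped to 0.
#' @export
correctEEMs <- function(cube, blank, scatterWidth = 10,
                        ramanWindow = c(371, 428)) {
  .stopIfNot(!isCorrected(cube),
             "cube is already corrected (correction is not idempotent)")
  .stopIfNot(!isCorrected(blank), "blank must be uncorrected")
  if (!identical(exGrid(cube), exGrid(blank))) {
    stop("excitation grids of cube and blank differ", call. = FALSE)
  }
  if (!identical(emGrid(cube), emGrid(blank))) {
    stop("emission grids of cube and blank differ", call. = FALSE)
  }
  area <- ramanArea(blank, window = ramanWindow)
  vals <- intensities(cube) / area
  blankLayer <- intensities(blank)[1, , ] / area
  n <- dim(vals)[1]
  clipped <- 0L
  mask <- .scatterMask(exGrid(cube), emGrid(cube), width = scatterWidth)
  for (i in seq_len(n)) {
    layer <- vals[i, , ] - blankLayer
    layer[mask] <- NA_real_
    neg <- sum(layer < 0, na.rm = TRUE)
    clipped <- clipped + neg
    layer[!is.na(layer) & layer < 0] <- 0
    vals[i, , ] <- layer
  }
  out <- EEMCube(
    vals, exGrid(cube), emGrid(cube), sampleIds = sampleIds(cube),
    corrected = TRUE, blankId = sampleIds(blank), ramanArea = area,
    excisedCells = sum(mask)
  )
  attr(out, "clippedNegatives") <- clipped
  out
}

.bandSum <- function(slice, emG, lo, hi) {
  rowSums(slice[, emG >= lo & emG <= hi, drop = FALSE], na.rm = FALSE)
}

#' Scalar fluorescence indices (BIX, HIX, FI)
#'
#' BIX (biological index) = F(em 380)/F(em 430) at ex 310 nm; values above
#' 0.8 indicate autochthonous, microbially derived organic matter. HIX
#' (humification index) is the proportion of ex-254 emission falling in
#' 435-480 nm relative to 300-345 plus 435-480 nm, so it lies in [0, 1].
#' FI (fluorescence index) = F(em 450)/F(em 500) at ex 370 nm. Ex 254 nm
#' is off the 5-nm lattice and is obtained by linear interpolation between
#' the 250 and 255 nm columns.
#'
#' @param cube a corrected [EEMCube-class].
#' @param bixThreshold BIX value above which a sample is flagged
#'   autochthonous.
#' @return data.frame with columns `sample`, `BIX`, `HIX`, `FI`,
#'   `autochthonous`. Indices with zero denominators are `NA` (with a
#'   warning), never an error.
#' @export
fluorescenceIndices <- function(cube, bixThreshold = 0.8) {
  .stopIfNot(isCorrected(cube),
             "indices are defined on corrected cubes only")
  emG <- emGrid(cube)
  ids <- sampleIds(cube)

  s310 <- .exSlice(cube, 310)
  bixNum <- s310[, which(emG == 380)]
  bixDen <- s310[, which(emG == 430)]
  bix <- ifelse(is.na(bixDen) | bixDen == 0, NA_real_, bixNum / bixDen)

  s254 <- .exSlice(cube, 254)
  humic <- .bandSum(s254, emG, 435, 480)
  fresh <- .bandSum(s254, emG, 300, 345)
  hixDen <- fresh + humic
  hix <- ifelse(is.na(hixDen) | hixDen == 0, NA_real_, humic / hixDen)

  s370 <- .exSlice(cube, 370)
  fiNum <- s370[, which(emG == 450)]
  fiDen <- s370[, which(emG == 500)]
  fi <- ifelse(is.na(fiDen) | fiDen == 0, NA_real_, fiNum / fiDen)

  if (anyNA(c(bix, hix, fi))) {
    warning("some indices are missing (zero or missing denominator)",
            call. = FALSE)
  }
  data.frame(
    sample = ids, BIX = bix, HIX = hix, FI = fi,
    autochthonous = !is.na(bix) & bix > bixThreshold,
    stringsAsFactors = FALSE
  )
}

#' Write / read the per-sample EEM CSV dialect
#'
#' One CSV per sample: first column is the emission wavelength (nm), the
#' header row carries the excitation wavelengths (nm).
#'
#' @param cube an [EEMCube-class].
#' @param dir output directory (created if needed).
#' @return `writeEEMCsv`: invisibly, the written paths. `readEEMCsv`: an
#'   [EEMCube-class].
#' @export
writeEEMCsv <- function(cube, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(sampleIds(cube))) {
    m <- intensities(cube)[i, , ]
    df <- data.frame(em = emGrid(cube), m, check.names = FALSE)
    names(df) <- c("em", exGrid(cube))
    path <- file.path(dir, paste0(sampleIds(cube)[i], ".csv"))
    write.csv(df, path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname writeEEMCsv
#' @param paths CSV files, one per sample (sample id = file name).
#' @export
readEEMCsv <- function(paths) {
  cubes <- lapply(paths, function(p) {
    df <- read.csv(p, check.names = FALSE)
    list(
      em = df[[1]],
      ex = as.numeric(names(df)[-1]),
      vals = as.matrix(df[, -1, drop = FALSE])
    )
  })
  exG <- cubes[[1]]$ex
  emG <- cubes[[1]]$em
  arr <- array(0, dim = c(length(paths), length(emG), length(exG)))
  for (i in seq_along(cubes)) {
    .stopIfNot(identical(cubes[[i]]$ex, exG) &&
               identical(cubes[[i]]$em, emG),
               "EEM CSV files are not on a shared wavelength lattice")
    arr[i, , ] <- cubes[[i]]$vals
  }
  EEMCube(arr, exG, emG,
          sampleIds = sub("\\.csv$", "", basename(paths)))
}
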