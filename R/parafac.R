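#' Tucker congruence coefficient
#'
#' Cosine similarity between two loading vectors,
#' `sum(a*b) / sqrt(sum(a^2) * sum(b^2))`; scale-invariant, in `[-1, 1]`.
#' The >0.95-on-both-modes rule on this coefficient drives split-half
#' validation and component library matching.
#'
#' @param a,b numeric vectors of equal length, not all zero.
#' @return Scalar congruence.
#' @export
tuckerCongruence <- function(a, b) {
  .stopIfNot(length(a) == length(b), "vectors must have equal length")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero vector in Tucker congruence",
                               call. = FALSE)
  sum(a * b) / (na * nb)
}

# shared missing-cell mask (missingness comes from scatter excision, which
# depends on wavelengths only, so the mask must agree across samples)
.cubeMask <- function(arr) {
  n <- dim(arr)[1]
  miss <- is.na(arr[1, , ])
  if (n > 1) {
    for (i in 2:n) {
      if (!identical(is.na(arr[i, , ]), miss)) {
        stop("missing-cell pattern differs between samples", call. = FALSE)
      }
    }
  }
  !miss
}

.normalizeModel <- function(A, B, C) {
  R <- ncol(A)
  for (r in seq_len(R)) {
    nb <- sqrt(sum(B[, r]^2))
    nc <- sqrt(sum(C[, r]^2))
    if (nb > 0) B[, r] <- B[, r] / nb
    if (nc > 0) C[, r] <- C[, r] / nc
    A[, r] <- A[, r] * nb * nc
  }
  list(A = A, B = B, C = C)
}

.orderByEmPeak <- function(A, B, C, emG, exG) {
  emPk <- emG[apply(B, 2, which.max)]
  exPk <- exG[apply(C, 2, which.max)]
  ord <- order(emPk, exPk)
  list(A = A[, ord, drop = FALSE], B = B[, ord, drop = FALSE],
       C = C[, ord, drop = FALSE])
}

#' Fit a non-negative PARAFAC model to a corrected EEM cube
#'
#' Alternating least squares with exact non-negative least squares per
#' row on all three modes. Cells excised during scatter removal carry
#' zero weight in the loss (no imputation). The best of `nStarts` random
#' non-negative initializations plus one SVD-magnitude start is retained.
#' Loadings are normalized to unit Euclidean norm (magnitude absorbed by
#' the scores) and components are ordered by ascending emission-peak
#' wavelength, ties broken by excitation peak.
#'
#' @param cube corrected [EEMCube-class].
#' @param nComponents model rank R (>= 1).
#' @param nStarts number of random starts (an SVD start is always added).
#' @param tol relative loss-change convergence tolerance.
#' @param maxIter maximum ALS sweeps per start.
#' @param seed integer seed controlling all initializations.
#' @return A [ParafacModel-class]. Warnings are raised if no start
#'   converged or if two components are mutually degenerate (Tucker
#'   congruence > 0.98 on both modes).
#' @export
fitParafac <- function(cube, nComponents = 3L, nStarts = 10L,
                       tol = 1e-8, maxIter = 2500L, seed = 1L) {
  .stopIfNot(is(cube, "EEMCube"), "cube must be an EEMCube")
  .stopIfNot(isCorrected(cube), "PARAFAC requires a corrected cube")
  .stopIfNot(nComponents >= 1, "nComponents must be >= 1")
  arr <- intensities(cube)
  n <- dim(arr)[1]
  .stopIfNot(n > nComponents,
             "need more samples than components")
  J <- dim(arr)[2]
  K <- dim(arr)[3]
  R <- as.integer(nComponents)

  maskMat <- .cubeMask(arr)          # em x ex, TRUE = observed
  mvec <- as.numeric(as.vector(maskMat))
  Xmat <- .unfoldCube(arr)
  Xmat[is.na(Xmat)] <- 0

  set.seed(seed)
  starts <- list()
  for (s in seq_len(nStarts)) {
    starts[[s]] <- list(
      A = matrix(runif(n * R, 0.1, 1), n, R),
      B = matrix(runif(J * R, 0.1, 1), J, R),
      C = matrix(runif(K * R, 0.1, 1), K, R)
    )
  }
  avg <- matrix(colMeans(Xmat), J, K)
  sv <- svd(avg, nu = R, nv = R)
  starts[[nStarts + 1L]] <- list(
    A = matrix(runif(n * R, 0.1, 1), n, R),
    B = abs(sv$u[, seq_len(R), drop = FALSE]) + 1e-6,
    C = abs(sv$v[, seq_len(R), drop = FALSE]) + 1e-6
  )

  best <- NULL
  for (s in seq_along(starts)) {
    fit <- cpAlsNN(Xmat, mvec, J, K,
                   starts[[s]]$A, starts[[s]]$B, starts[[s]]$C,
                   as.integer(maxIter), tol)
    if (is.null(best) || tail(fit$losses, 1) < tail(best$losses, 1)) {
      best <- fit
    }
  }
  if (!best$converged) {
    warning("no ALS start converged within maxIter", call. = FALSE)
  }

  nm <- .normalizeModel(best$A, best$B, best$C)
  ord <- .orderByEmPeak(nm$A, nm$B, nm$C, emGrid(cube), exGrid(cube))

  ssTot <- sum(Xmat[, mvec == 1]^2)
  finalLoss <- tail(best$losses, 1)
  ev <- if (ssTot > 0) 1 - finalLoss / ssTot else NA_real_

  degenerate <- FALSE
  if (R >= 2) {
    for (i in seq_len(R - 1)) {
      for (j in (i + 1):R) {
        if (sum(ord$B[, i]^2) == 0 || sum(ord$B[, j]^2) == 0) next
        if (tuckerCongruence(ord$B[, i], ord$B[, j]) > 0.98 &&
            tuckerCongruence(ord$C[, i], ord$C[, j]) > 0.98) {
          degenerate <- TRUE
        }
      }
    }
  }
  if (degenerate) {
    warning("degenerate solution: two components with mutual TCC > 0.98",
            call. = FALSE)
  }

  dimnames(ord$A) <- list(sampleIds(cube), paste0("C", seq_len(R)))
  dimnames(ord$B) <- list(NULL, paste0("C", seq_len(R)))
  dimnames(ord$C) <- list(NULL, paste0("C", seq_len(R)))

  new("ParafacModel",
    nComponents = R,
    exLoadings = ord$C, emLoadings = ord$B, scores = ord$A,
    exGrid = exGrid(cube), emGrid = emGrid(cube),
    sampleIds = sampleIds(cube),
    explainedVariance = ev,
    convergence = list(
      iterations = best$iterations,
      finalLoss = finalLoss,
      nStarts = length(starts),
      converged = best$converged,
      degenerate = degenerate,
      lossTrace = best$losses
    )
  )
}

#' Fmax component quantities
#'
#' The maximum fluorescence of each component in each sample:
#' `Fmax[i, r] = score[i, r] * max(exLoading[, r]) * max(emLoading[, r])`
#' (Raman units). Fmax values quantify the components downstream; their
#' per-sample proportions are the components' relative abundances.
#'
#' @param model a fitted [ParafacModel-class].
#' @param relative if `TRUE`, rows are normalized to proportions.
#' @return sample x component matrix.
#' @export
computeFmax <- function(model, relative = FALSE) {
  .stopIfNot(is(model, "ParafacModel"), "model must be a ParafacModel")
  mx <- apply(model@exLoadings, 2, max) * apply(model@emLoadings, 2, max)
  out <- sweep(scores(model), 2, mx, `*`)
  if (relative) {
    tot <- rowSums(out)
    .stopIfNot(all(tot > 0), "zero total Fmax in some sample")
    out <- out / tot
  }
  out
}

#' Split-half validation of a PARAFAC model
#'
#' Samples are randomly partitioned into halves (`nSplits` repetitions);
#' a model of the same rank is fit to each half and components are
#' matched between halves by the bijection maximizing summed Tucker
#' congruence. The model passes when every matched pair exceeds the
#' congruence threshold on both the excitation and the emission mode.
#'
#' @param cube corrected [EEMCube-class] with at least `2 * nComponents`
#'   samples.
#' @param nComponents model rank.
#' @param nSplits number of random half-partitions.
#' @param seed integer seed (partitions and fits).
#' @param threshold TCC pass threshold (default 0.95).
#' @param nStarts,tol,maxIter passed to [fitParafac()] for the half fits.
#' @return list with `pass` (logical), `threshold`, and `splits`, a
#'   data.frame of per-split per-component `tccEx` / `tccEm`.
#' @export
splitHalfValidate <- function(cube, nComponents = 3L, nSplits = 4L,
                              seed = 1L, threshold = 0.95,
                              nStarts = 2L, tol = 1e-7, maxIter = 1000L) {
  n <- length(sampleIds(cube))
  .stopIfNot(n >= 2 * nComponents,
             "too few samples for split-half validation")
  set.seed(deriveSeed(seed, "split-half"))
  rows <- list()
  for (s in seq_len(nSplits)) {
    perm <- sample.int(n)
    h1 <- sort(perm[seq_len(floor(n / 2))])
    h2 <- sort(perm[(floor(n / 2) + 1):n])
    sub <- function(idx) {
      EEMCube(
        intensities(cube)[idx, , , drop = FALSE], exGrid(cube),
        emGrid(cube), sampleIds = sampleIds(cube)[idx], corrected = TRUE,
        blankId = cube@blankId, ramanArea = cube@ramanArea,
        excisedCells = cube@excisedCells
      )
    }
    seeds <- sample.int(2^31 - 2, 2)
    m1 <- suppressWarnings(fitParafac(sub(h1), nComponents,
                                      nStarts = nStarts, tol = tol,
                                      maxIter = maxIter, seed = seeds[1]))
    m2 <- suppressWarnings(fitParafac(sub(h2), nComponents,
                                      nStarts = nStarts, tol = tol,
                                      maxIter = maxIter, seed = seeds[2]))
    ok1 <- colSums(exLoadings(m1)^2) > 0 & colSums(emLoadings(m1)^2) > 0
    ok2 <- colSums(exLoadings(m2)^2) > 0 & colSums(emLoadings(m2)^2) > 0
    if (!all(ok1) || !all(ok2)) {
      rows[[s]] <- data.frame(
        split = s, component = seq_len(nComponents),
        tccEx = 0, tccEm = 0
      )
      next
    }
    mt <- .matchComponentsBijective(
      exLoadings(m1), emLoadings(m1), exLoadings(m2), emLoadings(m2)
    )
    rows[[s]] <- data.frame(
      split = s, component = seq_len(nComponents),
      tccEx = mt$tccEx, tccEm = mt$tccEm
    )
  }
  splits <- do.call(rbind, rows)
  list(
    pass = all(splits$tccEx > threshold & splits$tccEm > threshold),
    threshold = threshold,
    splits = splits
  )
}

#' Default reference library of component templates
#'
#' Spectral templates on the instrument lattice for the three humic-like
#' components the pipeline targets: C1 "Microbial humic acid-like"
#' (ex/em 280/401 nm), C2 "Terrestrial humic acid-like" (355/443 nm), C3
#' "Terrestrial humic acid-like" (275/468 nm). These are synthetic
#' Gaussian templates, not measured spectra; they stand in for an
#' external spectral database in local matching.
#'
#' @return list of entries, each with `id`, `label`, `exWavelength`,
#'   `exLoading`, `emWavelength`, `emLoading`.
#' @export
defaultComponentLibrary <- function() {
  exG <- .defaultExGrid()
  emG <- .defaultEmGrid()
  comps <- defaultComponents()
  lapply(seq_along(comps), function(i) {
    cp <- comps[[i]]
    list(
      id = paste0("LIB", i),
      label = cp$label,
      exWavelength = exG,
      exLoading = .gaussLoading(exG, cp$exPeak, cp$exWidth),
      emWavelength = emG,
      emLoading = .gaussLoading(emG, cp$emPeak, cp$emWidth)
    )
  })
}

#' Match model components against a reference library
#'
#' Each model component is compared to every library entry by Tucker
#' congruence on both modes (library spectra are linearly interpolated
#' onto the model grids); the best entry by `min(tccEx, tccEm)` is
#' reported and flagged matched when both congruences exceed 0.95.
#'
#' @param model a fitted [ParafacModel-class].
#' @param library list of library entries (see
#'   [defaultComponentLibrary()]).
#' @param threshold match threshold on both modes.
#' @return data.frame: `component`, `entry`, `label`, `tccEx`, `tccEm`,
#'   `matched`.
#' @export
matchComponents <- function(model, library = defaultComponentLibrary(),
                            threshold = 0.95) {
  .stopIfNot(length(library) >= 1, "component library is empty")
  R <- model@nComponents
  out <- data.frame(
    component = paste0("C", seq_len(R)), entry = NA_character_,
    label = NA_character_, tccEx = NA_real_, tccEm = NA_real_,
    matched = FALSE, stringsAsFactors = FALSE
  )
  for (r in seq_len(R)) {
    bestMin <- -Inf
    for (e in library) {
      exI <- approx(e$exWavelength, e$exLoading, xout = exGrid(model),
                    rule = 2)$y
      emI <- approx(e$emWavelength, e$emLoading, xout = emGrid(model),
                    rule = 2)$y
      tEx <- tuckerCongruence(exLoadings(model)[, r], exI)
      tEm <- tuckerCongruence(emLoadings(model)[, r], emI)
      if (min(tEx, tEm) > bestMin) {
        bestMin <- min(tEx, tEm)
        out$entry[r] <- e$id
        out$label[r] <- e$label
        out$tccEx[r] <- tEx
        out$tccEm[r] <- tEm
      }
    }
    out$matched[r] <- out$tccEx[r] > threshold && out$tccEm[r] > threshold
  }
  out
}

#' Compare a fitted model to synthetic ground truth
#'
#' Matches fitted components to the truth components bijectively and
#' returns the per-mode Tucker congruences, in truth-component order.
#'
#' @param model a [ParafacModel-class].
#' @param truth the `truth` element of [simulateEEMs()].
#' @return list with `tccEx`, `tccEm` (per matched pair) and `perm`, the
#'   model component matched to each truth component.
#' @export
truthCongruence <- function(model, truth) {
  mt <- .matchComponentsBijective(
    truth$exLoadings, truth$emLoadings,
    exLoadings(model), emLoadings(model)
  )
  list(tccEx = mt$tccEx, tccEm = mt$tccEm, perm = mt$perm)
}
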