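#' Permutation random-forest importance
#'
#' Fits a regression random forest of the response on all predictors and
#' reports the out-of-bag %IncMSE importance (normalized by its standard
#' deviation, the classical convention). Each predictor's p-value is the
#' tail probability of its observed importance against a null built by
#' refitting the forest with that predictor's values permuted `nPerm`
#' times. The whole-model p-value permutes the response and compares
#' out-of-bag pseudo-R^2.
#'
#' @param table data.frame holding the response and the predictors.
#' @param response name of the response column (default `"Cum"`).
#' @param nTrees trees per forest.
#' @param nPerm permutations per predictor and for the model test; below
#'   20 a granularity warning is raised.
#' @param seed integer seed controlling every forest and permutation.
#' @return list: `importance` data.frame (`predictor`, `incMSE`, `p`),
#'   `modelR2` (out-of-bag pseudo-R^2), `modelP`.
#' @export
rfImportance <- function(table, response = "Cum", nTrees = 500L,
                         nPerm = 50L, seed = 1L) {
  .stopIfNot(response %in% names(table),
             sprintf("response '%s' not in table", response))
  y <- table[[response]]
  X <- table[, setdiff(names(table), response), drop = FALSE]
  .stopIfNot(!anyNA(y), "response must have no missing values")
  if (var(y) == 0) stop("constant response", call. = FALSE)
  .stopIfNot(nrow(table) >= 10, "need >= 10 samples")
  .stopIfNot(ncol(X) >= 2, "need >= 2 predictors")
  if (nPerm < 20) {
    warning("nPerm < 20: permutation p-values are coarse", call. = FALSE)
  }
  fitOnce <- function(Xf, yf, s) {
    set.seed(s)
    randomForest::randomForest(x = Xf, y = yf, ntree = nTrees,
                               importance = TRUE)
  }
  rf <- fitOnce(X, y, deriveSeed(seed, "rf-base"))
  obs <- randomForest::importance(rf, type = 1)[, 1]
  obs[!is.finite(obs)] <- 0  # constant predictors: zero importance
  obsR2 <- 1 - rf$mse[nTrees] / mean((y - mean(y))^2)

  pvals <- numeric(ncol(X))
  names(pvals) <- colnames(X)
  for (j in seq_len(ncol(X))) {
    exceed <- 0L
    for (b in seq_len(nPerm)) {
      s <- deriveSeed(seed, sprintf("rf-perm-%d-%d", j, b))
      set.seed(s)
      Xp <- X
      Xp[[j]] <- Xp[[j]][sample.int(nrow(X))]
      rfp <- fitOnce(Xp, y, s + 1L)
      impP <- randomForest::importance(rfp, type = 1)[j, 1]
      if (!is.finite(impP)) impP <- 0
      if (impP >= obs[j]) exceed <- exceed + 1L
    }
    pvals[j] <- (1 + exceed) / (nPerm + 1)
  }

  exceedM <- 0L
  for (b in seq_len(nPerm)) {
    s <- deriveSeed(seed, sprintf("rf-model-%d", b))
    set.seed(s)
    yp <- y[sample.int(length(y))]
    rfp <- fitOnce(X, yp, s + 1L)
    r2p <- 1 - rfp$mse[nTrees] / mean((yp - mean(yp))^2)
    if (r2p >= obsR2) exceedM <- exceedM + 1L
  }

  imp <- data.frame(
    predictor = names(obs), incMSE = unname(obs), p = unname(pvals),
    stringsAsFactors = FALSE
  )
  imp <- imp[order(-imp$incMSE), ]
  rownames(imp) <- NULL
  list(
    importance = imp,
    modelR2 = obsR2,
    modelP = (1 + exceedM) / (nPerm + 1)
  )
}

# R^2 of a (possibly multivariate) centered response on a predictor block
# via least-squares projection; the constrained-ordination (RDA-style)
# explained-inertia fraction, which reduces to linear-model R^2 for a
# univariate response
.blockR2 <- function(Y, X, adjusted = FALSE) {
  Y <- as.matrix(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  X <- as.matrix(X)
  .stopIfNot(ncol(X) < nrow(X) - 1,
             "predictors >= samples: unidentifiable block")
  if (sum(Yc^2) == 0) return(0)  # constant response: nothing to explain
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  if (qrX$rank == 0) return(0)  # constant block explains nothing
  fitted <- qr.fitted(qrX, Yc)
  r2 <- sum(fitted^2) / sum(Yc^2)
  if (adjusted) {
    n <- nrow(Y)
    p <- qrX$rank
    r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  }
  r2
}

#' Variance partitioning between two predictor blocks
#'
#' Explained-variance fractions of the response attributable uniquely to
#' block `X1` (e.g. DOC characteristics), uniquely to `X2` (e.g. network
#' complexity), shared between them, and residual:
#' `uniqueX1 = R2(X1+X2) - R2(X2)`, `uniqueX2 = R2(X1+X2) - R2(X1)`,
#' `shared = R2(X1) + R2(X2) - R2(X1+X2)`, `residual = 1 - R2(X1+X2)`.
#' The four fractions sum to 1 exactly. A negative shared fraction
#' (suppression) is reported as-is with a flag.
#'
#' @param response numeric vector (e.g. cumulative mineralization) or a
#'   multivariate matrix (community data).
#' @param X1,X2 data.frames/matrices of the two predictor blocks.
#' @param adjusted use Ezekiel-adjusted R^2.
#' @return list: `uniqueX1`, `uniqueX2`, `shared`, `residual`,
#'   `R2X1`, `R2X2`, `R2Both`, `suppression`.
#' @export
variancePartition <- function(response, X1, X2, adjusted = FALSE) {
  X1 <- as.matrix(X1)
  X2 <- as.matrix(X2)
  .stopIfNot(ncol(X1) >= 1 && ncol(X2) >= 1, "blocks must be non-empty")
  .stopIfNot(nrow(X1) == nrow(X2) &&
             nrow(X1) == NROW(response), "samples must be aligned")
  r1 <- .blockR2(response, X1, adjusted)
  r2 <- .blockR2(response, X2, adjusted)
  rb <- .blockR2(response, cbind(X1, X2), adjusted)
  u1 <- rb - r2
  u2 <- rb - r1
  sh <- r1 + r2 - rb
  list(
    uniqueX1 = u1, uniqueX2 = u2, shared = sh, residual = 1 - rb,
    R2X1 = r1, R2X2 = r2, R2Both = rb,
    suppression = sh < 0
  )
}

#' Per-predictor share of a block's explained variance
#'
#' For each predictor in a block, its standalone R^2 against the response
#' divided by the sum of all standalone R^2 in the block (reported as
#' `shareStandalone`), together with the hierarchical-partitioning
#' alternative: the average, over all orderings of the block, of the
#' sequential R^2 increment attributable to the predictor
#' (`shareHierarchical`, normalized to the block's joint R^2).
#'
#' @param response numeric vector.
#' @param block data.frame/matrix of the block's predictors.
#' @return data.frame: `predictor`, `r2Alone`, `shareStandalone`,
#'   `shareHierarchical`.
#' @export
withinCategoryShare <- function(response, block) {
  block <- as.data.frame(block)
  p <- ncol(block)
  .stopIfNot(p >= 1, "block must contain at least one predictor")
  r2Alone <- vapply(
    seq_len(p),
    function(j) .blockR2(response, block[, j, drop = FALSE]),
    numeric(1)
  )
  tot <- sum(r2Alone)
  if (tot == 0) stop("block explains no variance: shares undefined",
                     call. = FALSE)
  hier <- numeric(p)
  if (p == 1) {
    hier <- 1
  } else {
    .stopIfNot(p <= 7, "hierarchical partitioning limited to 7 predictors")
    perms <- .permutations(p)
    incr <- numeric(p)
    for (k in seq_len(nrow(perms))) {
      ord <- perms[k, ]
      prev <- 0
      for (step in seq_len(p)) {
        cur <- .blockR2(response, block[, ord[seq_len(step)],
                                        drop = FALSE])
        incr[ord[step]] <- incr[ord[step]] + (cur - prev)
        prev <- cur
      }
    }
    incr <- incr / nrow(perms)
    hier <- incr / sum(incr)
  }
  data.frame(
    predictor = colnames(block),
    r2Alone = r2Alone,
    shareStandalone = r2Alone / tot,
    shareHierarchical = hier,
    stringsAsFactors = FALSE
  )
}
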