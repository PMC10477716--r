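#' Assemble an OTU table as a SummarizedExperiment
#'
#' @param counts OTU x sample non-negative integer matrix with dimnames.
#' @param taxonomy data.frame of ranked labels (rows = OTUs, e.g. domain
#'   .. genus).
#' @param metadata data.frame with columns `sample`, `treatment`,
#'   `replicate`.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`.
#' @export
makeOtuExperiment <- function(counts, taxonomy, metadata) {
  .stopIfNot(all(is.finite(counts)) && all(counts >= 0),
             "counts must be finite and non-negative")
  .stopIfNot(!anyDuplicated(colnames(counts)), "sample ids must be unique")
  .stopIfNot(all(colnames(counts) %in% metadata$sample),
             "every sample needs metadata (treatment)")
  md <- metadata[match(colnames(counts), metadata$sample), , drop = FALSE]
  rownames(md) <- md$sample
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(taxonomy[rownames(counts), ,
                                            drop = FALSE]),
    colData = S4Vectors::DataFrame(md)
  )
}

.otuCounts <- function(otu) SummarizedExperiment::assay(otu, "counts")

.otuTreatments <- function(otu) {
  as.character(SummarizedExperiment::colData(otu)$treatment)
}

#' Relative abundance at a taxonomic rank
#'
#' Aggregates counts by the labels at `rank` and divides by sample
#' totals, so columns sum to one. OTUs unassigned at that rank are pooled
#' into `"unclassified"`.
#'
#' @param otu OTU SummarizedExperiment (see [makeOtuExperiment()]).
#' @param rank column of the taxonomy to aggregate at (`NULL`: per OTU).
#' @return taxa x sample proportion matrix.
#' @export
relativeAbundance <- function(otu, rank = NULL) {
  counts <- .otuCounts(otu)
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop(sprintf("sample(s) with zero total counts: %s",
                 paste(colnames(counts)[tot == 0], collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(rank)) {
    tx <- SummarizedExperiment::rowData(otu)
    .stopIfNot(rank %in% colnames(tx),
               sprintf("rank '%s' not present in taxonomy", rank))
    lab <- as.character(tx[[rank]])
    lab[is.na(lab) | lab == ""] <- "unclassified"
    counts <- rowsum(counts, lab)
  }
  sweep(counts, 2, tot, `/`)
}

#' Bray-Curtis distance between samples
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over taxa; entries lie in
#' `[0, 1]`.
#'
#' @param x OTU SummarizedExperiment, or a taxa x sample numeric matrix.
#' @return A symmetric sample x sample distance matrix (class `matrix`).
#' @export
brayCurtis <- function(x) {
  m <- if (is(x, "SummarizedExperiment")) .otuCounts(x) else x
  .stopIfNot(ncol(m) >= 2, "need at least two samples")
  if (any(colSums(m) == 0)) {
    stop("all-zero sample: Bray-Curtis undefined", call. = FALSE)
  }
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centers the squared distance matrix and eigendecomposes it;
#' coordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues. Negative eigenvalues are reported but excluded
#' from the axis fractions.
#'
#' @param d symmetric distance matrix.
#' @param k number of axes to return.
#' @return list: `coordinates` (n x k), `eigenvalues`, `fractions`
#'   (positive-eigenvalue fractions, summing to <= 1 over returned axes).
#' @export
pcoaOrdination <- function(d, k = 2L) {
  d <- as.matrix(d)
  .stopIfNot(isSymmetric(unname(d)), "distance matrix must be symmetric")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (d^2) %*% J
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- eg$values > sqrt(.Machine$double.eps) * abs(eg$values[1])
  k <- min(k, sum(pos))
  coords <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(k)]), k, k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(
    coordinates = coords,
    eigenvalues = eg$values,
    fractions = eg$values[seq_len(k)] / sum(eg$values[pos])
  )
}

#' One-way PERMANOVA (Adonis) from a distance matrix
#'
#' Partitions the Gower-centered inner-product matrix between and within
#' groups. `R2 = SS_between / SS_total`; the p-value is
#' `(1 + #{F_perm >= F_obs}) / (nPerm + 1)` under free permutation of
#' sample labels.
#'
#' @param d symmetric distance matrix.
#' @param groups factor-like group labels, one per sample.
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed.
#' @return list: `R2`, `F`, `p`, `nPerm`.
#' @export
permanovaTest <- function(d, groups, nPerm = 999L, seed = 1L) {
  d <- as.matrix(d)
  .stopIfNot(isSymmetric(unname(d)), "distance matrix must be symmetric")
  .stopIfNot(nPerm >= 1, "nPerm must be >= 1")
  groups <- as.factor(groups)
  .stopIfNot(length(groups) == nrow(d), "one group label per sample")
  .stopIfNot(nlevels(droplevels(groups)) >= 2, "need >= 2 groups")
  .stopIfNot(all(table(droplevels(groups)) >= 2),
             "each group needs >= 2 samples")
  n <- nrow(d)
  a <- nlevels(droplevels(groups))
  d2 <- d^2
  ssTotal <- sum(d2[upper.tri(d2)]) / n
  if (ssTotal <= 0) stop("degenerate distances (SS_total = 0)",
                         call. = FALSE)
  ssWithin <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1) {
        s <- s + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
      }
    }
    s
  }
  fstat <- function(g) {
    ssw <- ssWithin(g)
    ssb <- ssTotal - ssw
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  fObs <- fstat(groups)
  r2 <- (ssTotal - ssWithin(groups)) / ssTotal
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    g <- groups[sample.int(n)]
    if (fstat(g) >= fObs) exceed <- exceed + 1L
  }
  list(
    R2 = r2, F = fObs, p = (1 + exceed) / (nPerm + 1),
    nPerm = as.integer(nPerm)
  )
}
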