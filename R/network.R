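#' Prevalence filter
#'
#' Retains OTUs with nonzero counts in strictly more than `minFraction`
#' of the samples (the "present in more than half of the samples" rule at
#' the default 0.5). Row order is preserved.
#'
#' @param otu OTU SummarizedExperiment.
#' @param minFraction prevalence fraction; strict inequality.
#' @return Filtered OTU SummarizedExperiment.
#' @export
prevalenceFilter <- function(otu, minFraction = 0.5) {
  counts <- .otuCounts(otu)
  .stopIfNot(nrow(counts) > 0, "empty OTU table")
  prev <- rowMeans(counts > 0)
  keep <- prev > minFraction
  if (!any(keep)) {
    stop("no OTU passes the prevalence filter; lower minFraction",
         call. = FALSE)
  }
  otu[keep, ]
}

# pairwise Spearman rho and two-sided p; t-approximation for n >= 10,
# exact (cor.test) below
.spearmanMatrix <- function(m) {
  n <- ncol(m)
  rho <- suppressWarnings(cor(t(m), method = "spearman"))
  if (n >= 10) {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p[abs(rho) >= 1] <- 0
  } else {
    p <- matrix(NA_real_, nrow(m), nrow(m))
    for (i in seq_len(nrow(m) - 1)) {
      for (j in (i + 1):nrow(m)) {
        if (is.na(rho[i, j])) next
        ct <- suppressWarnings(
          cor.test(m[i, ], m[j, ], method = "spearman", exact = TRUE)
        )
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  list(rho = rho, p = p)
}

#' Spearman/FDR co-occurrence network
#'
#' All pairwise Spearman rank correlations between OTUs (average ranks
#' for ties), two-sided p-values, Benjamini-Hochberg adjustment over the
#' upper triangle, and edges wherever the adjusted p-value is below
#' `alpha`. Constant-abundance OTUs (undefined rank correlation) are
#' excluded, with the count recorded in the provenance. Nodes are the
#' endpoints of retained edges.
#'
#' @param otu OTU SummarizedExperiment (typically prevalence-filtered).
#' @param alpha adjusted-p cutoff (default 0.01).
#' @return A [CooccurrenceNetwork-class].
#' @export
correlationNetwork <- function(otu, alpha = 0.01) {
  counts <- .otuCounts(otu)
  .stopIfNot(ncol(counts) >= 5,
             "rank correlation needs at least 5 samples")
  constant <- apply(counts, 1, function(x) length(unique(x)) == 1)
  nConstant <- sum(constant)
  m <- counts[!constant, , drop = FALSE]
  sp <- .spearmanMatrix(m)
  ids <- rownames(m)
  ut <- which(upper.tri(sp$rho), arr.ind = TRUE)
  praw <- sp$p[ut]
  rho <- sp$rho[ut]
  padj <- p.adjust(praw, method = "BH")
  keep <- !is.na(padj) & padj < alpha
  edges <- data.frame(
    from = ids[ut[keep, 1]], to = ids[ut[keep, 2]],
    rho = rho[keep], p = praw[keep], padj = padj[keep],
    sign = sign(rho[keep]), stringsAsFactors = FALSE
  )
  nodes <- sort(unique(c(edges$from, edges$to)))
  new("CooccurrenceNetwork",
    nodes = nodes, edges = edges,
    modules = stats::setNames(integer(length(nodes)), nodes),
    alpha = alpha,
    provenance = list(
      method = "spearman", alpha = alpha,
      nTaxa = nrow(counts), nSamples = ncol(counts),
      constantTaxaDropped = nConstant,
      nTested = length(praw)
    )
  )
}

.networkIgraph <- function(network) {
  igraph::graph_from_data_frame(
    d = cbind(network@edges, weight = abs(network@edges$rho)),
    directed = FALSE,
    vertices = data.frame(name = network@nodes)
  )
}

#' Treatment-specific subnetwork
#'
#' Induced subgraph of the global network on the OTUs present (nonzero)
#' in strictly more than `minFraction` of the treatment's replicates;
#' edges survive iff both endpoints survive. Nodes that lose all their
#' edges are dropped (the node set stays the endpoints of retained
#' edges).
#'
#' @param network global [CooccurrenceNetwork-class].
#' @param otu the OTU SummarizedExperiment the network was built from.
#' @param treatment treatment label to subset on.
#' @param minFraction within-treatment prevalence rule.
#' @return A [CooccurrenceNetwork-class].
#' @export
treatmentSubnetwork <- function(network, otu, treatment,
                                minFraction = 0.5) {
  tr <- .otuTreatments(otu)
  .stopIfNot(treatment %in% tr,
             sprintf("unknown treatment '%s'", treatment))
  counts <- .otuCounts(otu)[, tr == treatment, drop = FALSE]
  present <- rownames(counts)[rowMeans(counts > 0) > minFraction]
  keepNodes <- intersect(network@nodes, present)
  e <- network@edges
  e <- e[e$from %in% keepNodes & e$to %in% keepNodes, , drop = FALSE]
  nodes <- sort(unique(c(e$from, e$to)))
  mods <- network@modules[nodes]
  if (!length(nodes)) mods <- stats::setNames(integer(0), character(0))
  prov <- network@provenance
  prov$subnetwork <- list(treatment = treatment,
                          minFraction = minFraction)
  new("CooccurrenceNetwork",
    nodes = nodes, edges = e, modules = mods,
    modularity = NA_real_, alpha = network@alpha, provenance = prov
  )
}

#' Topology metrics of a co-occurrence network
#'
#' Treats the graph as unsigned and simple. The local clustering
#' coefficient of a node of degree k is `2 * triangles / (k * (k - 1))`;
#' nodes with degree < 2 contribute 0. ACC (the network-complexity proxy)
#' is the mean over all nodes; average degree is `2 * edges / nodes`.
#'
#' @param network a [CooccurrenceNetwork-class].
#' @return list: `nodes`, `edges`, `averageClusteringCoefficient`,
#'   `averageDegree`, `positiveEdges`, `negativeEdges`.
#' @export
networkTopology <- function(network) {
  e <- network@edges
  nNodes <- length(network@nodes)
  if (nNodes == 0) {
    warning("empty network: topology metrics are zero", call. = FALSE)
    return(list(
      nodes = 0L, edges = 0L, averageClusteringCoefficient = 0,
      averageDegree = 0, positiveEdges = 0L, negativeEdges = 0L
    ))
  }
  g <- .networkIgraph(network)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  list(
    nodes = nNodes,
    edges = nrow(e),
    averageClusteringCoefficient = mean(cc),
    averageDegree = 2 * nrow(e) / nNodes,
    positiveEdges = sum(e$sign > 0),
    negativeEdges = sum(e$sign < 0)
  )
}

#' Detect network modules by modularity maximization
#'
#' Louvain community detection on the unsigned graph with edge weights
#' `|rho|`, under a fixed seed. Modules are labeled by descending size
#' (module 1 is the largest); the modularity Q of the partition is
#' stored on the returned network.
#'
#' @param network a [CooccurrenceNetwork-class] with at least one edge.
#' @param seed integer seed.
#' @param resolution Louvain resolution parameter.
#' @return The network with `modules` and `modularity` filled in.
#' @export
detectModules <- function(network, seed = 1L, resolution = 1.0) {
  .stopIfNot(nrow(network@edges) >= 1, "network has no edges")
  g <- .networkIgraph(network)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  mem <- igraph::membership(cl)
  sizes <- sort(table(mem), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  mods <- as.integer(relabel[as.character(mem)])
  names(mods) <- names(mem)
  network@modules <- mods[network@nodes]
  network@modularity <- igraph::modularity(
    g, mem, weights = igraph::E(g)$weight
  )
  network
}

#' Module eigengene
#'
#' First principal component of the z-scored abundances of a module's
#' member OTUs, one value per sample. The sign is oriented so that the
#' eigengene correlates non-negatively with the module's mean
#' standardized abundance. Members with zero variance are dropped (their
#' count is reported); if all are dropped, an error is raised.
#'
#' @param otu OTU SummarizedExperiment (or taxa x sample matrix).
#' @param members OTU ids of the module (>= 2).
#' @return list: `eigengene` (named per-sample vector),
#'   `varianceExplained`, `nDropped`.
#' @export
moduleEigengene <- function(otu, members) {
  m <- if (is(otu, "SummarizedExperiment")) .otuCounts(otu) else otu
  .stopIfNot(length(members) >= 2, "module needs >= 2 members")
  .stopIfNot(all(members %in% rownames(m)),
             "module members missing from the table")
  x <- m[members, , drop = FALSE]
  vars <- apply(x, 1, var)
  dropped <- sum(vars == 0)
  x <- x[vars > 0, , drop = FALSE]
  if (nrow(x) == 0) stop("all module members have zero variance",
                         call. = FALSE)
  z <- t(scale(t(x)))  # z-score each taxon across samples
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  eig <- pc$x[, 1]
  zbar <- colMeans(z)
  # orientation undefined when the module mean is flat (e.g. two exactly
  # anti-correlated members); keep the PCA sign then
  if (sd(zbar) > 0 && !is.na(cor(eig, zbar)) && cor(eig, zbar) < 0) {
    eig <- -eig
  }
  list(
    eigengene = stats::setNames(eig, colnames(m)),
    varianceExplained = pc$sdev[1]^2 / sum(pc$sdev^2),
    nDropped = dropped
  )
}

#' Eigengenes for every detected module
#'
#' @param otu OTU SummarizedExperiment.
#' @param network a [CooccurrenceNetwork-class] with detected modules.
#' @param minSize smallest module summarized.
#' @return sample x module matrix (columns `M1`, `M2`, ...).
#' @export
moduleEigengenes <- function(otu, network, minSize = 2L) {
  mods <- network@modules
  ids <- sort(unique(mods[mods > 0]))
  out <- NULL
  for (m in ids) {
    members <- names(mods)[mods == m]
    if (length(members) < minSize) next
    eg <- moduleEigengene(otu, members)
    out <- cbind(out, eg$eigengene)
    colnames(out)[ncol(out)] <- paste0("M", m)
  }
  .stopIfNot(!is.null(out), "no module large enough for an eigengene")
  out
}

#' Module eigengene - environment associations
#'
#' Pearson correlation of each module eigengene with each environmental
#' variable (soil properties, DOC descriptors, cumulative
#' mineralization), with both the analytic p-value and a seeded
#' permutation p-value, plus significance stars (* p < 0.05, ** p <
#' 0.01). Constant variables yield missing associations.
#'
#' @param eigengenes sample x module matrix ([moduleEigengenes()]).
#' @param env data.frame of per-sample variables (rownames = sample ids).
#' @param nPerm permutations for the permutation p-value.
#' @param seed integer seed.
#' @return data.frame: `module`, `variable`, `r`, `pAnalytic`, `pPerm`,
#'   `stars`.
#' @export
moduleEnvAssociation <- function(eigengenes, env, nPerm = 999L,
                                 seed = 1L) {
  .stopIfNot(nrow(eigengenes) == nrow(env),
             "eigengenes and env must share the sample set")
  if (!is.null(rownames(env)) && !is.null(rownames(eigengenes))) {
    env <- env[rownames(eigengenes), , drop = FALSE]
  }
  set.seed(seed)
  rows <- list()
  n <- nrow(eigengenes)
  for (m in colnames(eigengenes)) {
    for (v in colnames(env)) {
      x <- eigengenes[, m]
      y <- env[[v]]
      if (sd(y) == 0 || sd(x) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          module = m, variable = v, r = NA_real_,
          pAnalytic = NA_real_, pPerm = NA_real_, stars = ""
        )
        next
      }
      r <- cor(x, y)
      pA <- cor.test(x, y)$p.value
      exceed <- 0L
      for (b in seq_len(nPerm)) {
        if (abs(cor(x, y[sample.int(n)])) >= abs(r)) exceed <- exceed + 1L
      }
      pP <- (1 + exceed) / (nPerm + 1)
      stars <- if (pP < 0.01) "**" else if (pP < 0.05) "*" else ""
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, variable = v, r = r, pAnalytic = pA, pPerm = pP,
        stars = stars
      )
    }
  }
  do.call(rbind, rows)
}

#' Mantel test
#'
#' Pearson correlation between the off-diagonal entries of two distance
#' matrices; the p-value permutes rows and columns of `d2` jointly,
#' `p = (1 + #{r_perm >= r}) / (nPerm + 1)` (one-sided).
#'
#' @param d1,d2 symmetric distance matrices over the same samples.
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return list: `r`, `p`, `nPerm`.
#' @export
mantelTest <- function(d1, d2, nPerm = 999L, seed = 1L) {
  d1 <- as.matrix(d1)
  d2 <- as.matrix(d2)
  .stopIfNot(all(dim(d1) == dim(d2)),
             "distance matrices must have the same size")
  n <- nrow(d1)
  lt <- lower.tri(d1)
  r <- cor(d1[lt], d2[lt])
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    idx <- sample.int(n)
    if (cor(d1[lt], d2[idx, idx][lt]) >= r) exceed <- exceed + 1L
  }
  list(r = r, p = (1 + exceed) / (nPerm + 1), nPerm = as.integer(nPerm))
}

#' Export a network
#'
#' `writeNetworkGraphML` writes GraphML (module and sign attributes
#' included); `writeEdgeList` writes the edge list as CSV with per-node
#' module columns.
#'
#' @param network a [CooccurrenceNetwork-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeNetworkGraphML <- function(network, path) {
  g <- .networkIgraph(network)
  if (length(network@modules)) {
    igraph::V(g)$module <- as.integer(network@modules[
      igraph::V(g)$name])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname writeNetworkGraphML
#' @export
writeEdgeList <- function(network, path) {
  e <- network@edges
  mods <- network@modules
  e$module_from <- unname(mods[e$from])
  e$module_to <- unname(mods[e$to])
  names(e)[names(e) == "from"] <- "otu_a"
  names(e)[names(e) == "to"] <- "otu_b"
  names(e)[names(e) == "p"] <- "p_raw"
  names(e)[names(e) == "padj"] <- "p_adj"
  write.csv(e, path, row.names = FALSE)
  invisible(path)
}
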