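# shared fixtures and independent oracles, all built in code

stdExGrid <- seq(200, 450, by = 5)
stdEmGrid <- seq(250, 600, by = 1)

# corrected cube with arbitrary cell values (zero elsewhere);
# cells: list of list(sample, em, ex, value)
deltaCube <- function(cells, nSamples = 1) {
  arr <- array(0, dim = c(nSamples, length(stdEmGrid), length(stdExGrid)))
  for (cl in cells) {
    arr[cl$sample, which(stdEmGrid == cl$em), which(stdExGrid == cl$ex)] <-
      cl$value
  }
  EEMCube(arr, stdExGrid, stdEmGrid, corrected = TRUE)
}

# fill a whole emission band at one excitation column (and optionally a
# neighbouring column, for interpolation targets)
bandCube <- function(exCols, emLo, emHi, value, nSamples = 1) {
  arr <- array(0, dim = c(nSamples, length(stdEmGrid), length(stdExGrid)))
  for (ex in exCols) {
    sel <- stdEmGrid >= emLo & stdEmGrid <= emHi
    arr[, sel, which(stdExGrid == ex)] <- value
  }
  EEMCube(arr, stdExGrid, stdEmGrid, corrected = TRUE)
}

# a pure-noise "corrected" cube (no trilinear structure)
noiseCube <- function(n = 24, seed = 1, sd = 1) {
  set.seed(seed)
  arr <- array(abs(rnorm(n * length(stdEmGrid) * length(stdExGrid),
                         sd = sd)),
               dim = c(n, length(stdEmGrid), length(stdExGrid)))
  EEMCube(arr, stdExGrid, stdEmGrid, corrected = TRUE)
}

# brute-force local clustering coefficients (triangle enumeration)
bruteClustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) { cc[i] <- 0; next }
    tri <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] > 0) tri <- tri + 1
      }
    }
    cc[i] <- 2 * tri / (k * (k - 1))
  }
  cc
}

# build a CooccurrenceNetwork directly from an adjacency matrix
networkFromAdjacency <- function(adj, rho = 0.5) {
  ids <- rownames(adj)
  if (is.null(ids)) ids <- paste0("N", seq_len(nrow(adj)))
  ut <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(
    from = ids[ut[, 1]], to = ids[ut[, 2]],
    rho = rho, p = 0, padj = 0, sign = sign(rho),
    stringsAsFactors = FALSE
  )
  nodes <- sort(unique(c(edges$from, edges$to)))
  new("CooccurrenceNetwork",
    nodes = nodes, edges = edges,
    modules = stats::setNames(integer(length(nodes)), nodes),
    alpha = 0.01, provenance = list()
  )
}

# step-up Benjamini-Hochberg oracle, straight from the definition
stepUpBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# small OTU experiment from a counts matrix with default 3x(n/3) design
otuFromCounts <- function(counts,
                          treatments = rep(c("NPK", "GM", "GMC"),
                                           length.out = ncol(counts))) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("OTU", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  meta <- data.frame(
    sample = colnames(counts), treatment = treatments,
    replicate = seq_len(ncol(counts)), stringsAsFactors = FALSE
  )
  tax <- data.frame(
    domain = "Bacteria", phylum = "P", class = "C",
    genus = rownames(counts), row.names = rownames(counts),
    stringsAsFactors = FALSE
  )
  makeOtuExperiment(counts, tax, meta)
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)
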