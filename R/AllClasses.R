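#' @import methods
#' @importFrom stats approx cor cor.test ecdf lm median na.omit p.adjust
#'   pf predict prcomp pt quantile rbinom rlnorm rnorm rpois runif sd var
#' @importFrom utils head tail read.csv read.delim write.csv write.table
#' @useDynLib soilCNet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' EEMCube: a stack of excitation-emission fluorescence matrices
#'
#' Holds one excitation-emission matrix (EEM) per sample on a shared
#' wavelength lattice. The default instrument lattice is excitation
#' 200-450 nm in 5 nm steps (51 columns) and emission 250-600 nm in
#' 1 nm steps (351 rows). Cells may be `NA` only after scatter excision
#' (i.e. in a corrected cube).
#'
#' @slot sampleIds character, one id per sample.
#' @slot exGrid numeric, strictly increasing excitation wavelengths (nm).
#' @slot emGrid numeric, strictly increasing emission wavelengths (nm).
#' @slot intensities numeric array, sample x emission x excitation.
#' @slot corrected logical flag; `TRUE` once blank-corrected and
#'   Raman-normalized.
#' @slot blankId character, id of the blank used for correction ("" if raw).
#' @slot ramanArea numeric, Raman peak area of the blank used (NA if raw).
#' @slot excisedCells integer, number of cells masked per sample during
#'   scatter excision (0 if raw).
#'
#' @export
setClass("EEMCube",
  representation(
    sampleIds = "character",
    exGrid = "numeric",
    emGrid = "numeric",
    intensities = "array",
    corrected = "logical",
    blankId = "character",
    ramanArea = "numeric",
    excisedCells = "integer"
  ),
  prototype(
    corrected = FALSE, blankId = "", ramanArea = NA_real_,
    excisedCells = 0L
  )
)

setValidity("EEMCube", function(object) {
  msg <- character()
  d <- dim(object@intensities)
  if (length(d) != 3L) {
    msg <- c(msg, "intensities must be a 3-d array (sample x em x ex)")
  } else {
    if (d[1] != length(object@sampleIds))
      msg <- c(msg, "dim 1 of intensities must match sampleIds")
    if (d[2] != length(object@emGrid))
      msg <- c(msg, "dim 2 of intensities must match emGrid")
    if (d[3] != length(object@exGrid))
      msg <- c(msg, "dim 3 of intensities must match exGrid")
  }
  if (any(diff(object@exGrid) <= 0))
    msg <- c(msg, "exGrid must be strictly increasing")
  if (any(diff(object@emGrid) <= 0))
    msg <- c(msg, "emGrid must be strictly increasing")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sample ids must be unique")
  vals <- object@intensities
  if (!object@corrected && anyNA(vals))
    msg <- c(msg, "missing cells are only allowed after scatter excision")
  if (any(vals < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an EEMCube
#'
#' @param intensities sample x emission x excitation array.
#' @param exGrid,emGrid wavelength grids (nm).
#' @param sampleIds sample identifiers; defaults to `S1..Sn`.
#' @param corrected whether the cube is already blank-corrected.
#' @param blankId,ramanArea,excisedCells correction provenance.
#' @return An [EEMCube-class] object.
#' @export
EEMCube <- function(intensities, exGrid, emGrid,
                    sampleIds = paste0("S", seq_len(dim(intensities)[1])),
                    corrected = FALSE, blankId = "",
                    ramanArea = NA_real_, excisedCells = 0L) {
  new("EEMCube",
    sampleIds = as.character(sampleIds),
    exGrid = as.numeric(exGrid), emGrid = as.numeric(emGrid),
    intensities = intensities, corrected = corrected,
    blankId = blankId, ramanArea = as.numeric(ramanArea),
    excisedCells = as.integer(excisedCells)
  )
}

setMethod("show", "EEMCube", function(object) {
  cat(
    "EEMCube with", length(object@sampleIds), "sample(s)\n",
    " emission:", length(object@emGrid), "points,",
    min(object@emGrid), "-", max(object@emGrid), "nm\n",
    " excitation:", length(object@exGrid), "points,",
    min(object@exGrid), "-", max(object@exGrid), "nm\n",
    " corrected:", object@corrected, "\n"
  )
  if (object@corrected) {
    cat(
      " blank:", object@blankId, " Raman area:",
      signif(object@ramanArea, 6), " excised cells/sample:",
      object@excisedCells, "\n"
    )
  }
})

#' ParafacModel: non-negative trilinear decomposition of an EEM cube
#'
#' Loadings have unit Euclidean norm per column; component magnitude is
#' absorbed by the sample scores. Components are ordered by ascending
#' emission-peak wavelength (ties broken by excitation peak).
#'
#' @slot nComponents integer, model rank R.
#' @slot exLoadings excitation x R non-negative unit-norm loading matrix.
#' @slot emLoadings emission x R non-negative unit-norm loading matrix.
#' @slot scores sample x R non-negative score matrix.
#' @slot exGrid,emGrid wavelength grids (nm).
#' @slot sampleIds sample identifiers.
#' @slot explainedVariance fraction of masked-cell sum of squares explained.
#' @slot convergence list: iterations, final loss, nStarts, converged,
#'   degenerate flag, loss trace of the winning start.
#'
#' @export
setClass("ParafacModel",
  representation(
    nComponents = "integer",
    exLoadings = "matrix",
    emLoadings = "matrix",
    scores = "matrix",
    exGrid = "numeric",
    emGrid = "numeric",
    sampleIds = "character",
    explainedVariance = "numeric",
    convergence = "list"
  )
)

setValidity("ParafacModel", function(object) {
  msg <- character()
  R <- object@nComponents
  if (ncol(object@exLoadings) != R || ncol(object@emLoadings) != R ||
      ncol(object@scores) != R)
    msg <- c(msg, "loadings/scores must have nComponents columns")
  if (any(object@exLoadings < 0) || any(object@emLoadings < 0) ||
      any(object@scores < 0))
    msg <- c(msg, "loadings and scores must be non-negative")
  nrm <- c(
    sqrt(colSums(object@exLoadings^2)),
    sqrt(colSums(object@emLoadings^2))
  )
  if (any(abs(nrm[nrm > 0] - 1) > 1e-6))
    msg <- c(msg, "non-zero loading columns must have unit norm")
  if (object@explainedVariance > 1 + 1e-12)
    msg <- c(msg, "explainedVariance must be <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ParafacModel", function(object) {
  cat(
    "ParafacModel with", object@nComponents, "component(s),",
    length(object@sampleIds), "sample(s)\n",
    " explained variance:",
    sprintf("%.4f", object@explainedVariance), "\n"
  )
  pk <- componentPeaks(object)
  for (r in seq_len(object@nComponents)) {
    cat(sprintf(
      "  C%d: ex/em %g/%g nm\n", r, pk$ex[r], pk$em[r]
    ))
  }
})

#' CooccurrenceNetwork: signed OTU co-occurrence graph
#'
#' Nodes are the endpoints of retained (FDR-significant) Spearman
#' correlation edges; isolated taxa that pass the prevalence filter but
#' participate in no significant edge are not nodes.
#'
#' @slot nodes character, OTU ids in the graph.
#' @slot edges data.frame with columns `from`, `to`, `rho`, `p`, `padj`,
#'   `sign`.
#' @slot modules named integer, module id per node (0 = unassigned).
#' @slot modularity numeric, modularity Q of the module partition (NA if
#'   modules not yet detected).
#' @slot alpha numeric, adjusted-p cutoff used.
#' @slot provenance list of filter settings (method, prevalence fraction,
#'   dropped constant taxa, etc.).
#'
#' @export
setClass("CooccurrenceNetwork",
  representation(
    nodes = "character",
    edges = "data.frame",
    modules = "integer",
    modularity = "numeric",
    alpha = "numeric",
    provenance = "list"
  ),
  prototype(modularity = NA_real_, provenance = list())
)

setValidity("CooccurrenceNetwork", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("from", "to", "rho", "p", "padj", "sign")
  if (!all(need %in% names(e)))
    msg <- c(msg, paste(
      "edges must have columns:", paste(need, collapse = ", ")
    ))
  else {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (nrow(e) && any(e$padj >= object@alpha))
      msg <- c(msg, "all edges must have adjusted p < alpha")
    if (nrow(e) && any(e$sign != sign(e$rho)))
      msg <- c(msg, "edge sign must equal sign(rho)")
    ep <- unique(c(e$from, e$to))
    if (!setequal(ep, object@nodes) && nrow(e))
      msg <- c(msg, "node set must equal the endpoints of retained edges")
  }
  if (length(object@modules) &&
      !setequal(names(object@modules), object@nodes))
    msg <- c(msg, "modules must be named by the node set")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CooccurrenceNetwork", function(object) {
  cat(
    "CooccurrenceNetwork:", length(object@nodes), "nodes,",
    nrow(object@edges), "edges (alpha =", object@alpha, ")\n"
  )
  if (nrow(object@edges)) {
    cat(
      "  positive:", sum(object@edges$sign > 0),
      " negative:", sum(object@edges$sign < 0), "\n"
    )
  }
  if (length(object@modules) && any(object@modules > 0)) {
    cat(
      "  modules:", max(object@modules),
      " modularity Q:", signif(object@modularity, 4), "\n"
    )
  }
})
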