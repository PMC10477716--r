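#' Accessor generics
#'
#' Small accessor API for the package's S4 containers.
#'
#' @param object an S4 object from this package.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("exGrid", function(object) standardGeneric("exGrid"))

#' @rdname accessors
#' @export
setGeneric("emGrid", function(object) standardGeneric("emGrid"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("isCorrected", function(object) standardGeneric("isCorrected"))

#' @rdname accessors
#' @export
setGeneric("exLoadings", function(object) standardGeneric("exLoadings"))

#' @rdname accessors
#' @export
setGeneric("emLoadings", function(object) standardGeneric("emLoadings"))

#' @rdname accessors
#' @export
setGeneric("scores", function(object, ...) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("explainedVariance",
           function(object) standardGeneric("explainedVariance"))

#' @rdname accessors
#' @export
setGeneric("componentPeaks",
           function(object) standardGeneric("componentPeaks"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("networkModules",
           function(object) standardGeneric("networkModules"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "EEMCube", function(object) object@sampleIds)

#' @rdname accessors
#' @export
setMethod("sampleIds", "ParafacModel", function(object) object@sampleIds)

#' @rdname accessors
#' @export
setMethod("exGrid", "EEMCube", function(object) object@exGrid)

#' @rdname accessors
#' @export
setMethod("emGrid", "EEMCube", function(object) object@emGrid)

#' @rdname accessors
#' @export
setMethod("exGrid", "ParafacModel", function(object) object@exGrid)

#' @rdname accessors
#' @export
setMethod("emGrid", "ParafacModel", function(object) object@emGrid)

#' @rdname accessors
#' @export
setMethod("intensities", "EEMCube", function(object) object@intensities)

#' @rdname accessors
#' @export
setMethod("isCorrected", "EEMCube", function(object) object@corrected)

#' @rdname accessors
#' @export
setMethod("exLoadings", "ParafacModel", function(object) object@exLoadings)

#' @rdname accessors
#' @export
setMethod("emLoadings", "ParafacModel", function(object) object@emLoadings)

#' @rdname accessors
#' @export
setMethod("scores", "ParafacModel", function(object, ...) object@scores)

#' @rdname accessors
#' @export
setMethod("explainedVariance", "ParafacModel",
          function(object) object@explainedVariance)

#' @rdname accessors
#' @export
setMethod("componentPeaks", "ParafacModel", function(object) {
  list(
    ex = object@exGrid[apply(object@exLoadings, 2, which.max)],
    em = object@emGrid[apply(object@emLoadings, 2, which.max)]
  )
})

#' @rdname accessors
#' @export
setMethod("networkNodes", "CooccurrenceNetwork",
          function(object) object@nodes)

#' @rdname accessors
#' @export
setMethod("networkEdges", "CooccurrenceNetwork",
          function(object) object@edges)

#' @rdname accessors
#' @export
setMethod("networkModules", "CooccurrenceNetwork",
          function(object) object@modules)
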