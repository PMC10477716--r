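#' Read / write OTU tables, metadata, and titration records
#'
#' The OTU TSV dialect has one row per OTU: an `otu` id column, the
#' taxonomy columns, then one column per sample. Metadata TSV: `sample`,
#' `treatment`, `replicate`. Titration TSV: `jar`, `treatment`, `day`,
#' `hclML`, `isBlank`.
#'
#' @param otu OTU SummarizedExperiment.
#' @param path file path.
#' @param taxonomyCols names of the taxonomy columns.
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @name otuIO
NULL

#' @rdname otuIO
#' @export
writeOtuTsv <- function(otu, path) {
  counts <- .otuCounts(otu)
  tx <- as.data.frame(SummarizedExperiment::rowData(otu))
  df <- cbind(otu = rownames(counts), tx, as.data.frame(counts),
              stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname otuIO
#' @param metadata data.frame with `sample`, `treatment`, `replicate`.
#' @export
readOtuTsv <- function(path, metadata,
                       taxonomyCols = c("domain", "phylum", "class",
                                        "genus")) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .stopIfNot("otu" %in% names(df), "OTU TSV needs an 'otu' column")
  taxonomyCols <- intersect(taxonomyCols, names(df))
  sampleCols <- setdiff(names(df), c("otu", taxonomyCols))
  counts <- as.matrix(df[, sampleCols, drop = FALSE])
  rownames(counts) <- df$otu
  storage.mode(counts) <- "integer"
  taxonomy <- df[, taxonomyCols, drop = FALSE]
  rownames(taxonomy) <- df$otu
  makeOtuExperiment(counts, taxonomy, metadata)
}

#' @rdname otuIO
#' @export
writeMetadataTsv <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname otuIO
#' @export
readMetadataTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname otuIO
#' @param titration titration data.frame (see
#'   [cumulativeMineralization()]).
#' @export
writeTitrationTsv <- function(titration, path) {
  df <- titration
  for (a in c("hclMolarity", "naohMolarity", "naohVolumeML",
              "soilMassKg")) {
    attr(df, a) <- NULL
  }
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname otuIO
#' @export
readTitrationTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$isBlank <- as.logical(df$isBlank)
  df
}
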