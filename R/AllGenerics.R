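#' @describeIn OmicsDataset-accessors mRNA matrix
#' @export
setGeneric("mrna", function(x) standardGeneric("mrna"))
#' @describeIn OmicsDataset-accessors protein matrix
#' @export
setGeneric("protein", function(x) standardGeneric("protein"))
#' @describeIn OmicsDataset-accessors miRNA matrix
#' @export
setGeneric("mirna", function(x) standardGeneric("mirna"))
#' @describeIn OmicsDataset-accessors sample count
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @describeIn CorrelationGrid-accessors gene identifiers
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @describeIn CorrelationGrid-accessors miRNA identifiers
#' @export
setGeneric("mirnas", function(x) standardGeneric("mirnas"))
#' @describeIn CorrelationGrid-accessors partial-correlation estimates
#' @export
setGeneric("partialR", function(x) standardGeneric("partialR"))
#' @describeIn CorrelationGrid-accessors partial-correlation p-values
#' @export
setGeneric("partialP", function(x) standardGeneric("partialP"))
#' @describeIn CorrelationGrid-accessors bivariate mRNA-protein estimates
#' @export
setGeneric("bivariateR", function(x) standardGeneric("bivariateR"))
#' @describeIn CorrelationGrid-accessors bivariate mRNA-protein p-values
#' @export
setGeneric("bivariateP", function(x) standardGeneric("bivariateP"))
#' @describeIn CorrelationGrid-accessors p-value improvement matrix
#' @export
setGeneric("improvement", function(x) standardGeneric("improvement"))
#' @describeIn TargetDatabase-accessors source label
#' @export
setGeneric("dbName", function(x) standardGeneric("dbName"))
#' @describeIn TargetDatabase-accessors pair data.frame
#' @export
setGeneric("dbPairs", function(x) standardGeneric("dbPairs"))
#' Test (miRNA, gene) pair membership in a target database
#'
#' @param x a \code{\linkS4class{TargetDatabase}}.
#' @param mirna,gene character vectors of equal length (recycled).
#' @return logical vector, one entry per queried pair.
#' @export
setGeneric("hasPair", function(x, mirna, gene) standardGeneric("hasPair"))

#' Accessors for OmicsDataset
#'
#' @param x an \code{\linkS4class{OmicsDataset}}.
#' @return \code{mrna}, \code{protein}, \code{mirna}: the stored numeric
#'   matrices; \code{nSamples}: integer sample count.
#' @name OmicsDataset-accessors
NULL

#' Accessors for CorrelationGrid
#'
#' @param x a \code{\linkS4class{CorrelationGrid}}.
#' @name CorrelationGrid-accessors
NULL

#' Accessors for TargetDatabase
#'
#' @param x a \code{\linkS4class{TargetDatabase}}.
#' @name TargetDatabase-accessors
NULL

#' @rdname OmicsDataset-accessors
#' @export
setMethod("mrna", "OmicsDataset", function(x) x@mrna)
#' @rdname OmicsDataset-accessors
#' @export
setMethod("protein", "OmicsDataset", function(x) x@protein)
#' @rdname OmicsDataset-accessors
#' @export
setMethod("mirna", "OmicsDataset", function(x) x@mirna)
#' @rdname OmicsDataset-accessors
#' @export
setMethod("nSamples", "OmicsDataset", function(x) ncol(x@mrna))
#' @rdname CorrelationGrid-accessors
#' @export
setMethod("nSamples", "CorrelationGrid", function(x) x@nSamples)
#' @rdname CorrelationGrid-accessors
#' @export
setMethod("genes", "CorrelationGrid", function(x) x@genes)
#' @rdname CorrelationGrid-accessors
#' @export
setMethod("mirnas", "CorrelationGrid", function(x) x@mirnas)
#' @rdname CorrelationGrid-accessors
#' @export
setMethod("partialR", "CorrelationGrid", function(x) x@partialR)
#' @rdname CorrelationGrid-accessors
#' @export
setMethod("partialP", "CorrelationGrid", function(x) x@partialP)
#' @rdname CorrelationGrid-accessors
#' @export
setMethod("bivariateR", "CorrelationGrid", function(x) x@bivariateR)
#' @rdname CorrelationGrid-accessors
#' @export
setMethod("bivariateP", "CorrelationGrid", function(x) x@bivariateP)
#' @rdname CorrelationGrid-accessors
#' @export
setMethod("improvement", "CorrelationGrid", function(x) x@improvement)
#' @rdname TargetDatabase-accessors
#' @export
setMethod("dbName", "TargetDatabase", function(x) x@name)
#' @rdname TargetDatabase-accessors
#' @export
setMethod("dbPairs", "TargetDatabase", function(x) x@pairs)
#' @rdname hasPair
#' @export
setMethod("hasPair", "TargetDatabase", function(x, mirna, gene) {
  paste(mirna, gene, sep = "\r") %in%
    paste(x@pairs$mirna, x@pairs$gene, sep = "\r")
})

setMethod("show", "OmicsDataset", function(object) {
  cat("OmicsDataset:", nrow(object@mrna), "genes,",
      nrow(object@mirna), "miRNAs,", ncol(object@mrna), "samples\n")
})
setMethod("show", "CorrelationGrid", function(object) {
  nm <- sum(is.na(object@partialP))
  cat("CorrelationGrid:", length(object@genes), "genes x",
      length(object@mirnas), "miRNAs (n =", object@nSamples, "samples)\n")
  if (nm) cat("  ", nm, "degenerate cell(s) marked NA\n")
})
setMethod("show", "TargetDatabase", function(object) {
  cat("TargetDatabase '", object@name, "': ", nrow(object@pairs),
      " (miRNA, gene) pairs\n", sep = "")
})
setMethod("show", "GeneModel", function(object) {
  cat("GeneModel ", object@geneId, " [", object@chrom, object@strand,
      " ", object@geneStart, "-", object@geneEnd, "] longest transcript ",
      object@txId, " (", object@txEnd - object@txStart + 1L, " bp span, ",
      length(object@cds), " CDS / ", length(object@utr5), " 5'UTR / ",
      length(object@utr3), " 3'UTR interval(s))\n", sep = "")
})
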