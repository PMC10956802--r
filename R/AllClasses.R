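#' @import methods
#' @importFrom stats cor median pt quantile p.adjust phyper rnorm rbinom var
#'   setNames
#' @importFrom utils read.delim write.table head
#' @importClassesFrom IRanges IRanges
NULL

#' Aligned multi-omic expression triple
#'
#' Container for the three matched expression matrices the target-prediction
#' method operates on: mRNA (\code{M}), protein (\code{P}) and miRNA
#' (\code{MI}).  All three share the same samples (columns, identical order);
#' \code{M} and \code{P} share the same gene identifiers (rows, identical
#' order).  Objects are normally produced by \code{\link{alignDataset}} or
#' \code{\link{preprocessDataset}}, after which no missing values remain.
#'
#' At least 4 samples are required: the partial-correlation p-value is based
#' on a t statistic with \code{n - 3} degrees of freedom.
#'
#' @slot mrna numeric matrix, genes x samples.
#' @slot protein numeric matrix, genes x samples (same dimnames as
#'   \code{mrna}).
#' @slot mirna numeric matrix, miRNAs x samples.
#'
#' @seealso \code{\link{computeGrid}}
#' @export
setClass("OmicsDataset",
  representation(mrna = "matrix", protein = "matrix", mirna = "matrix"),
  validity = function(object) {
    m <- object@mrna; p <- object@protein; mi <- object@mirna
    msg <- character()
    if (!identical(colnames(m), colnames(p)) ||
        !identical(colnames(m), colnames(mi)))
      msg <- c(msg, "sample columns of mrna, protein and mirna must be identical")
    if (!identical(rownames(m), rownames(p)))
      msg <- c(msg, "mrna and protein must have identical gene row names")
    if (anyNA(m) || anyNA(p) || anyNA(mi))
      msg <- c(msg, "no missing values are allowed; impute first")
    if (ncol(m) < 4L)
      msg <- c(msg, "at least 4 samples are required (partial-correlation df = n - 3)")
    if (anyDuplicated(rownames(m)) || anyDuplicated(rownames(mi)) ||
        anyDuplicated(colnames(m)))
      msg <- c(msg, "feature and sample identifiers must be unique")
    if (length(msg)) msg else TRUE
  })

#' Per-pair correlation grid
#'
#' Holds, for every (gene, miRNA) pair, the miRNA-conditioned partial
#' correlation between the gene's mRNA and protein profiles together with its
#' p-value, the per-gene bivariate mRNA-protein correlation and p-value, and
#' the improvement matrix
#' \code{improvement[g, mi] = bivariateP[g] - partialP[g, mi]}: positive
#' entries mark pairs for which conditioning on the miRNA made the
#' mRNA-protein association more significant.  Degenerate cells (constant
#' profiles, unit correlation with the conditioning variable) are \code{NA}
#' and are excluded from all downstream selection and testing.
#'
#' @slot genes character, gene identifiers (rows).
#' @slot mirnas character, miRNA identifiers (columns).
#' @slot partialR,partialP numeric matrices genes x miRNAs.
#' @slot bivariateR,bivariateP numeric vectors over genes.
#' @slot improvement numeric matrix genes x miRNAs.
#' @slot nSamples integer, number of samples the grid was computed from.
#'
#' @export
setClass("CorrelationGrid",
  representation(genes = "character", mirnas = "character",
    partialR = "matrix", partialP = "matrix",
    bivariateR = "numeric", bivariateP = "numeric",
    improvement = "matrix", nSamples = "integer"),
  validity = function(object) {
    g <- length(object@genes); m <- length(object@mirnas)
    msg <- character()
    for (nm in c("partialR", "partialP", "improvement")) {
      d <- dim(slot(object, nm))
      if (!identical(d, c(g, m)))
        msg <- c(msg, sprintf("%s must be %d x %d", nm, g, m))
    }
    if (length(object@bivariateR) != g || length(object@bivariateP) != g)
      msg <- c(msg, "bivariate vectors must have one entry per gene")
    rng <- function(x, lo, hi) all(x >= lo & x <= hi, na.rm = TRUE)
    if (!rng(object@partialR, -1, 1) || !rng(object@bivariateR, -1, 1))
      msg <- c(msg, "correlations must lie in [-1, 1]")
    if (!rng(object@partialP, 0, 1) || !rng(object@bivariateP, 0, 1))
      msg <- c(msg, "p-values must lie in [0, 1]")
    imp <- object@bivariateP - object@partialP
    ok <- abs(imp - object@improvement) < 1e-12
    if (!all(ok | (is.na(imp) & is.na(object@improvement))))
      msg <- c(msg, "improvement must equal bivariateP - partialP cellwise")
    if (length(msg)) msg else TRUE
  })

#' Known/predicted miRNA-target pair database
#'
#' A named, deduplicated set of (miRNA, gene) pairs used to flag and to test
#' enrichment of predicted interactions.  Matching is on exact string
#' equality of identifiers.
#'
#' @slot name character scalar, source label (e.g. a database name).
#' @slot pairs data.frame with character columns \code{mirna} and
#'   \code{gene}; no duplicate rows, no empty identifiers.
#'
#' @export
setClass("TargetDatabase",
  representation(name = "character", pairs = "data.frame"),
  validity = function(object) {
    msg <- character()
    p <- object@pairs
    if (!all(c("mirna", "gene") %in% names(p)))
      msg <- c(msg, "pairs must have columns 'mirna' and 'gene'")
    else {
      if (anyDuplicated(paste(p$mirna, p$gene, sep = "\r")))
        msg <- c(msg, "pairs must be unique")
      if (nrow(p) && any(!nzchar(p$mirna) | !nzchar(p$gene)))
        msg <- c(msg, "identifiers must be non-empty")
    }
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "name must be a non-empty scalar")
    if (length(msg)) msg else TRUE
  })

#' Gene model for seed scanning
#'
#' Per-gene annotation reduced to its longest transcript: chromosome, strand,
#' genomic span and the 5'UTR/CDS/3'UTR intervals of that transcript (1-based
#' inclusive genomic coordinates, as in GTF).  The sequence scanned for seed
#' matches is the unspliced genomic span of this transcript, read 5' to 3' in
#' transcript orientation.
#'
#' @slot geneId,chrom,strand,txId character scalars; strand is "+" or "-".
#' @slot geneStart,geneEnd,txStart,txEnd integer genomic coordinates,
#'   1-based inclusive.
#' @slot utr5,cds,utr3,exons \code{\link[IRanges]{IRanges}} of genomic
#'   intervals of the longest transcript; mutually disjoint for
#'   utr5/cds/utr3.
#'
#' @export
setClass("GeneModel",
  representation(geneId = "character", chrom = "character",
    strand = "character", geneStart = "integer", geneEnd = "integer",
    txId = "character", txStart = "integer", txEnd = "integer",
    utr5 = "IRanges", cds = "IRanges", utr3 = "IRanges", exons = "IRanges"),
  validity = function(object) {
    msg <- character()
    if (!object@strand %in% c("+", "-"))
      msg <- c(msg, "strand must be '+' or '-'")
    if (object@geneStart > object@geneEnd || object@txStart > object@txEnd)
      msg <- c(msg, "start must not exceed end")
    reg <- c(object@utr5, object@cds, object@utr3)
    if (length(reg) &&
        (min(IRanges::start(reg)) < object@txStart ||
         max(IRanges::end(reg)) > object@txEnd))
      msg <- c(msg, "annotated intervals must lie within the transcript span")
    ov <- function(a, b) length(a) && length(b) &&
      any(IRanges::overlapsAny(a, b))
    if (ov(object@utr5, object@cds) || ov(object@utr3, object@cds) ||
        ov(object@utr5, object@utr3))
      msg <- c(msg, "UTR and CDS intervals must be mutually disjoint")
    if (length(msg)) msg else TRUE
  })
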