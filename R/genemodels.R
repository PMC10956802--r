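#' Build gene models (longest transcript per gene) from a GTF file
#'
#' Imports the annotation with \pkg{rtracklayer} and reduces each gene to
#' its longest transcript, measured as genomic span (end - start + 1); ties
#' break by transcript ID (lexicographic).  5'UTR/CDS/3'UTR intervals are
#' taken from explicit \code{five_prime_utr}/\code{three_prime_utr} (or
#' \code{UTR}) features when present; otherwise UTRs are derived as the
#' exonic regions outside the CDS span, assigned 5' or 3' by strand.
#' Coordinates are 1-based inclusive throughout, as in GTF.
#'
#' @param gtf path to a GTF file (Ensembl-style \code{gene_id} /
#'   \code{transcript_id} attributes).
#' @param geneIds optional character vector restricting which genes are
#'   modelled.
#' @return named list of \code{\linkS4class{GeneModel}} objects.
#' @export
readGeneModels <- function(gtf, geneIds = NULL) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!is.null(geneIds)) {
    gr <- gr[!is.na(meta$gene_id) & meta$gene_id %in% geneIds]
    meta <- S4Vectors::mcols(gr)
  }
  gsplit <- split(seq_along(gr), meta$gene_id)
  models <- lapply(names(gsplit), function(g)
    longestTranscript(gr[gsplit[[g]]], g))
  names(models) <- names(gsplit)
  if (!is.null(geneIds)) {
    missing <- setdiff(geneIds, names(models))
    if (length(missing))
      message("readGeneModels: ", length(missing),
              " gene(s) absent from the GTF: ",
              paste(head(missing, 3L), collapse = ", "),
              if (length(missing) > 3L) ", ...")
  }
  models
}

#' Reduce one gene's annotation to its longest transcript
#'
#' @param gr \code{GRanges} of all GTF features of a single gene.
#' @param geneId the gene identifier (error if no transcript is found).
#' @return a \code{\linkS4class{GeneModel}}.
#' @export
longestTranscript <- function(gr, geneId) {
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  txid <- as.character(meta$transcript_id)
  hastx <- !is.na(txid)
  if (!any(hastx)) stop("gene ", geneId, " has no transcript in the GTF")
  ## per-transcript genomic span: transcript lines when present, else the
  ## union of that transcript's features
  spans <- vapply(split(seq_along(gr)[hastx], txid[hastx]), function(i) {
    c(min(BiocGenerics::start(gr[i])), max(BiocGenerics::end(gr[i])))
  }, integer(2L))
  lens <- spans[2L, ] - spans[1L, ] + 1L
  best <- colnames(spans)[order(-lens, colnames(spans))][1L]
  sel <- hastx & txid == best
  strand <- as.character(BiocGenerics::strand(gr[sel]))[1L]
  if (!strand %in% c("+", "-")) strand <- "+"
  pick <- function(types) {
    i <- sel & type %in% types
    IRanges::IRanges(BiocGenerics::start(gr[i]), BiocGenerics::end(gr[i]))
  }
  exons <- pick("exon")
  cds <- pick("CDS")
  utr5 <- pick("five_prime_utr")
  utr3 <- pick("three_prime_utr")
  plainUtr <- pick("UTR")
  if (!length(utr5) && !length(utr3)) {
    utrs <- if (length(plainUtr)) plainUtr
            else if (length(cds) && length(exons))
              BiocGenerics::setdiff(exons,
                IRanges::IRanges(min(IRanges::start(cds)),
                                 max(IRanges::end(cds))))
            else IRanges::IRanges()
    if (length(utrs) && length(cds)) {
      cdsStart <- min(IRanges::start(cds)); cdsEnd <- max(IRanges::end(cds))
      before <- utrs[IRanges::end(utrs) < cdsStart]
      after <- utrs[IRanges::start(utrs) > cdsEnd]
      if (strand == "+") { utr5 <- before; utr3 <- after }
      else { utr5 <- after; utr3 <- before }
    }
  }
  new("GeneModel", geneId = geneId,
      chrom = as.character(GenomeInfoDb::seqnames(gr[sel]))[1L],
      strand = strand,
      geneStart = as.integer(min(BiocGenerics::start(gr))),
      geneEnd = as.integer(max(BiocGenerics::end(gr))),
      txId = best,
      txStart = as.integer(spans[1L, best]),
      txEnd = as.integer(spans[2L, best]),
      utr5 = utr5, cds = cds, utr3 = utr3, exons = exons)
}

#' Map transcript-oriented positions to genomic coordinates
#'
#' Positions are 1-based offsets into the unspliced genomic span of the
#' longest transcript read 5' to 3' in transcript orientation, i.e. into
#' the string returned by \code{\link{geneSequence}}.
#'
#' @param model a \code{\linkS4class{GeneModel}}.
#' @param pos integer vector of transcript-oriented positions.
#' @return integer vector of genomic coordinates (1-based).
#' @export
transcriptToGenomic <- function(model, pos) {
  L <- model@txEnd - model@txStart + 1L
  stopifnot(all(pos >= 1L & pos <= L))
  if (model@strand == "+") model@txStart + pos - 1L
  else model@txEnd - pos + 1L
}

#' Map genomic coordinates to transcript-oriented positions
#'
#' Inverse of \code{\link{transcriptToGenomic}}.
#'
#' @param model a \code{\linkS4class{GeneModel}}.
#' @param gpos integer vector of genomic coordinates within the transcript
#'   span.
#' @return integer vector of transcript-oriented positions.
#' @export
genomicToTranscript <- function(model, gpos) {
  stopifnot(all(gpos >= model@txStart & gpos <= model@txEnd))
  if (model@strand == "+") gpos - model@txStart + 1L
  else model@txEnd - gpos + 1L
}
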