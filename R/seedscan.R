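#' Extract a miRNA seed region
#'
#' The seed is the 7-nt stretch from base 2 to base 8 (1-based, inclusive),
#' counting from the miRNA's 5' end -- the primary determinant of
#' target-site complementarity.  \code{T} is accepted and normalised to
#' \code{U}.
#'
#' @param mirnaSeq miRNA sequence (character or \code{RNAString}), length
#'   >= 8, alphabet A/C/G/U (T tolerated).
#' @param start,end seed boundaries, defaults 2 and 8.
#' @return seed as an RNA character string.
#' @export
extractSeed <- function(mirnaSeq, start = 2L, end = 8L) {
  s <- toupper(as.character(mirnaSeq))
  s <- chartr("T", "U", s)
  if (nchar(s) < end)
    stop("miRNA sequence shorter than ", end, " nt")
  if (grepl("[^ACGU]", s)) stop("invalid base in miRNA sequence")
  substr(s, start, end)
}

#' Extract the gene sequence scanned for seed matches
#'
#' Returns the unspliced genomic span of the gene's longest transcript
#' (introns included), reverse-complemented for minus-strand genes so that
#' the result reads 5' to 3' in transcript orientation.
#'
#' @param model a \code{\linkS4class{GeneModel}}.
#' @param genome a named \code{\link[Biostrings]{DNAStringSet}} (names =
#'   chromosome IDs), e.g. from \code{\link[Biostrings]{readDNAStringSet}}.
#' @return a \code{DNAString}.
#' @export
geneSequence <- function(model, genome) {
  if (!model@chrom %in% names(genome))
    stop("chromosome ", model@chrom, " not in the genome")
  chr <- genome[[model@chrom]]
  if (model@txEnd > length(chr))
    stop("transcript span exceeds chromosome length")
  s <- Biostrings::subseq(chr, model@txStart, model@txEnd)
  if (model@strand == "-") Biostrings::reverseComplement(s) else s
}

#' Find exact seed matches in a gene sequence
#'
#' In \code{"reverse_complement"} mode (default) the DNA reverse complement
#' of the seed is searched -- the miRNA seed base-pairs antiparallel to the
#' target, so a target site carries the seed's reverse complement.  In
#' \code{"literal"} mode the seed itself (U transliterated to T) is
#' searched.  Matches may overlap.
#'
#' @param geneSeq \code{DNAString} or character, transcript-oriented (from
#'   \code{\link{geneSequence}}).
#' @param seed 7-nt RNA seed from \code{\link{extractSeed}}.
#' @param matchMode \code{"reverse_complement"} or \code{"literal"}.
#' @return integer vector of 1-based match start positions in
#'   transcript-oriented coordinates (empty when no match).
#' @export
findSeed <- function(geneSeq, seed,
                     matchMode = c("reverse_complement", "literal")) {
  matchMode <- match.arg(matchMode)
  if (nchar(seed) != 7L) stop("seed must be 7 nt")
  pat <- Biostrings::DNAString(chartr("U", "T", toupper(seed)))
  if (matchMode == "reverse_complement")
    pat <- Biostrings::reverseComplement(pat)
  if (is.character(geneSeq)) geneSeq <- Biostrings::DNAString(geneSeq)
  BiocGenerics::start(Biostrings::matchPattern(pat, geneSeq))
}

#' Classify seed matches by annotated transcript region
#'
#' Converts each transcript-oriented match back to genomic coordinates and
#' flags overlap of the 7-bp site with the 5'UTR, CDS and 3'UTR intervals
#' of the longest transcript.  A single interaction can set several flags
#' (multiple sites in different regions).  A site falling only in introns
#' sets no region flag, but \code{anywhere} remains true.
#'
#' @param model a \code{\linkS4class{GeneModel}}.
#' @param positions integer vector of match starts from
#'   \code{\link{findSeed}} (site length 7).
#' @return named logical vector: \code{anywhere}, \code{utr5}, \code{cds},
#'   \code{utr3}, \code{any_region}.
#' @export
classifyMatchRegions <- function(model, positions) {
  flags <- c(anywhere = length(positions) > 0L,
             utr5 = FALSE, cds = FALSE, utr3 = FALSE, any_region = FALSE)
  for (p in positions) {
    gp <- transcriptToGenomic(model, c(p, p + 6L))
    site <- IRanges::IRanges(min(gp), max(gp))
    if (length(model@utr5) && any(IRanges::overlapsAny(site, model@utr5)))
      flags["utr5"] <- TRUE
    if (length(model@cds) && any(IRanges::overlapsAny(site, model@cds)))
      flags["cds"] <- TRUE
    if (length(model@utr3) && any(IRanges::overlapsAny(site, model@utr3)))
      flags["utr3"] <- TRUE
  }
  flags["any_region"] <- flags["utr5"] || flags["cds"] || flags["utr3"]
  flags
}

#' Seed-presence summary over an interaction table
#'
#' For every selected (gene, miRNA) interaction with available sequences:
#' extract the miRNA seed, scan the gene's longest-transcript sequence for
#' exact matches, classify match regions, and report the percentage of
#' interactions with a seed match anywhere in the gene, in the 5'UTR, in
#' the 3'UTR, in the CDS, and in at least one of the three annotated
#' regions.  Because one interaction can match in several regions, the
#' "any region" percentage is at most -- not equal to -- the sum of the
#' three region percentages.  Interactions with a missing gene model or
#' miRNA sequence are excluded from the denominator (and counted in
#' \code{n_skipped}).
#'
#' @param table interaction data.frame with \code{gene} and \code{mirna}
#'   columns.
#' @param models named list of \code{\linkS4class{GeneModel}}s.
#' @param genome named \code{DNAStringSet} genome.
#' @param mirnaSeqs named character vector or \code{RNAStringSet}/
#'   \code{DNAStringSet} of miRNA sequences (names matching miRNA IDs).
#' @param matchMode passed to \code{\link{findSeed}}.
#' @return list with \code{n_interactions}, \code{n_skipped}, percentages
#'   \code{with_seed_anywhere}, \code{in_5putr}, \code{in_3putr},
#'   \code{in_cds}, \code{in_any_annotated_region} (all in [0, 100]; all
#'   \code{NA} for an empty table), and the per-interaction \code{flags}
#'   data.frame.
#' @export
summarizeSeedPresence <- function(table, models, genome, mirnaSeqs,
                                  matchMode = "reverse_complement") {
  stopifnot(is.data.frame(table))
  if (!is.character(mirnaSeqs))
    mirnaSeqs <- setNames(as.character(mirnaSeqs), names(mirnaSeqs))
  have <- table$gene %in% names(models) & table$mirna %in% names(mirnaSeqs)
  skipped <- sum(!have)
  if (skipped)
    message("summarizeSeedPresence: skipping ", skipped,
            " interaction(s) lacking a gene model or miRNA sequence")
  tab <- table[have, , drop = FALSE]
  if (!nrow(tab))
    return(list(n_interactions = 0L, n_skipped = skipped,
                with_seed_anywhere = NA_real_, in_5putr = NA_real_,
                in_3putr = NA_real_, in_cds = NA_real_,
                in_any_annotated_region = NA_real_,
                flags = data.frame()))
  ## cache oriented gene sequences: the same gene recurs across miRNAs
  ug <- unique(tab$gene)
  seqs <- setNames(lapply(ug, function(g)
    geneSequence(models[[g]], genome)), ug)
  fl <- t(vapply(seq_len(nrow(tab)), function(i) {
    g <- tab$gene[i]
    seed <- extractSeed(mirnaSeqs[[tab$mirna[i]]])
    classifyMatchRegions(models[[g]],
                         findSeed(seqs[[g]], seed, matchMode))
  }, logical(5L)))
  pct <- function(col) 100 * mean(fl[, col])
  list(n_interactions = nrow(tab), n_skipped = skipped,
       with_seed_anywhere = pct("anywhere"),
       in_5putr = pct("utr5"), in_3putr = pct("utr3"), in_cds = pct("cds"),
       in_any_annotated_region = pct("any_region"),
       flags = data.frame(gene = tab$gene, mirna = tab$mirna, fl,
                          stringsAsFactors = FALSE))
}
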