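#' Specification for a synthetic matched multi-omic dataset
#'
#' Describes the generative model used to validate the method.  Per sample:
#' miRNA abundances z ~ N(0, 1); mRNA abundances x ~ N(0, 1); protein
#' y = a * x + noise for unregulated genes, and
#' y = a * x - b * z + noise for a gene with a planted miRNA regulator --
#' translational repression: the miRNA lowers the protein at fixed mRNA, so
#' conditioning the mRNA-protein correlation on the miRNA removes the b^2
#' variance term and strictly increases it.  An optional mRNA-decay channel
#' (\code{decay > 0}) additionally subtracts \code{decay * z} from the
#' mRNA of planted genes.  Matrices are exported on a positive scale
#' (mRNA and miRNA as 2^value, so the standard log2 preprocessing recovers
#' the Gaussian scale exactly; protein as raw ratio-scale values), and
#' missing entries are injected uniformly at random in the protein and
#' miRNA matrices.
#'
#' @param nSamples,nGenes,nMirnas dimensions (defaults 100, 50, 10).
#' @param planted either an integer (that many pairs planted on distinct
#'   genes, miRNAs recycled) or a data.frame with columns \code{gene},
#'   \code{mirna} (integer indices) and optionally \code{a}, \code{b}.
#' @param a transcription coupling (protein-per-mRNA slope), default 0.3:
#'   with the default noise SD this gives unregulated genes an
#'   mRNA-protein correlation of a/sqrt(a^2 + noiseSd^2) = 0.51, in the
#'   range reported for proteogenomic cohorts.
#' @param b repression strength of planted miRNAs on protein, default 1.5
#'   (>= 1 SD of the miRNA signal gives a clearly detectable effect).
#' @param decay mRNA-decay strength of planted miRNAs, default 0.
#' @param noiseSd protein noise SD, default 0.5.
#' @param missingRate fraction of missing entries injected in protein and
#'   miRNA matrices, default 0.05.
#' @param seed RNG seed recorded with the ground truth.
#' @return a \code{synthSpec} list.
#' @export
synthSpec <- function(nSamples = 100L, nGenes = 50L, nMirnas = 10L,
                      planted = 20L, a = 0.3, b = 1.5, decay = 0,
                      noiseSd = 0.5, missingRate = 0.05, seed = 1L) {
  stopifnot(nSamples >= 4L, nGenes >= 1L, nMirnas >= 1L, noiseSd > 0,
            missingRate >= 0, missingRate < 1, b >= 0)
  if (is.numeric(planted) && length(planted) == 1L) {
    stopifnot(planted <= nGenes)
    planted <- data.frame(
      gene = seq_len(planted),
      mirna = rep_len(seq_len(nMirnas), planted))
  }
  stopifnot(is.data.frame(planted),
            all(planted$gene >= 1L & planted$gene <= nGenes),
            all(planted$mirna >= 1L & planted$mirna <= nMirnas))
  if (is.null(planted$a)) planted$a <- rep(a, nrow(planted))
  if (is.null(planted$b)) planted$b <- rep(b, nrow(planted))
  list(nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
       nMirnas = as.integer(nMirnas), planted = planted, a = a, b = b,
       decay = decay, noiseSd = noiseSd, missingRate = missingRate,
       seed = as.integer(seed))
}

.fmtIds <- function(prefix, n)
  sprintf("%s%0*d", prefix, max(2L, nchar(n)), seq_len(n))

#' Generate a synthetic matched (mRNA, protein, miRNA) dataset
#'
#' Draws raw matrices under the model of \code{\link{synthSpec}}.  Planted
#' genes are shuffled over the gene index space so that signal carriers are
#' not clustered at the top of the matrix.  All randomness comes from
#' \code{spec$seed}; the same spec yields bit-identical matrices.
#'
#' @param spec a \code{\link{synthSpec}}.
#' @return list with \code{M}, \code{P}, \code{MI} (raw matrices, possibly
#'   with injected \code{NA}s in \code{P}/\code{MI}) and
#'   \code{groundTruth}: the planted (gene, mirna, a, b) pairs with IDs,
#'   the seed, and a record of the generative equations.
#' @export
generateDataset <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$nSamples; G <- spec$nGenes; Z <- spec$nMirnas
  geneIds <- .fmtIds("G", G)
  mirnaIds <- .fmtIds("miR-", Z)
  sampleIds <- .fmtIds("S", n)

  zmat <- matrix(rnorm(Z * n), Z, n, dimnames = list(mirnaIds, sampleIds))
  xmat <- matrix(rnorm(G * n), G, n, dimnames = list(geneIds, sampleIds))

  perm <- sample.int(G)                 # scatter planted genes
  pl <- spec$planted
  pl$gene <- perm[pl$gene]
  pl$mirna <- sample.int(Z)[((pl$mirna - 1L) %% Z) + 1L]

  if (spec$decay > 0)
    for (i in seq_len(nrow(pl)))
      xmat[pl$gene[i], ] <- xmat[pl$gene[i], ] -
        spec$decay * zmat[pl$mirna[i], ]

  ymat <- spec$a * xmat +
    matrix(rnorm(G * n, sd = spec$noiseSd), G, n)
  for (i in seq_len(nrow(pl)))
    ymat[pl$gene[i], ] <- ymat[pl$gene[i], ] -
      pl$b[i] * zmat[pl$mirna[i], ] + (pl$a[i] - spec$a) * xmat[pl$gene[i], ]
  dimnames(ymat) <- dimnames(xmat)

  ## positive count-like export for the log2-transformed layers
  M <- 2^xmat; MI <- 2^zmat; P <- ymat
  if (spec$missingRate > 0) {
    P[matrix(rbinom(length(P), 1L, spec$missingRate) == 1L,
             nrow(P))] <- NA
    MI[matrix(rbinom(length(MI), 1L, spec$missingRate) == 1L,
              nrow(MI))] <- NA
  }
  gt <- data.frame(gene = geneIds[pl$gene], mirna = mirnaIds[pl$mirna],
                   a = pl$a, b = pl$b, stringsAsFactors = FALSE)
  list(M = structure(M, layer = "mrna"),
       P = structure(P, layer = "protein"),
       MI = structure(MI, layer = "mirna"),
       groundTruth = list(
         planted = gt, seed = spec$seed, spec = spec,
         equations = paste(
           "z ~ N(0,1); x ~ N(0,1) [- decay*z if planted];",
           "y = a*x - b*z[planted] + N(0, noiseSd);",
           "export: M = 2^x, MI = 2^z, P = y")))
}

.revcompDNA <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

## oriented transcript layout of every toy gene (700 bp long transcript)
.toyLayout <- list(
  utr5 = c(1L, 100L), cds1 = c(101L, 200L), intron = c(201L, 400L),
  cds2 = c(401L, 550L), utr3 = c(551L, 700L),
  exon1 = c(1L, 200L), exon2 = c(401L, 700L),
  txLen = 700L, shortOff = c(800L, 999L), geneLen = 1000L)

## implant offsets (oriented, start of the 7-bp site) per region
.toyImplantAt <- c(`5putr` = 21L, cds = 451L, `3putr` = 601L,
                   intron = 301L, shortonly = NA)

#' Write a toy genome / annotation / miRNA fixture for seed scanning
#'
#' Each requested gene gets its own chromosome with a fixed two-transcript
#' structure: a 700-bp "long" transcript (100-bp 5'UTR, split CDS around a
#' 200-bp intron, 150-bp 3'UTR) and a 200-bp non-coding "short" transcript
#' lying outside the long transcript's span.  The background sequence is an
#' AC-dinucleotide repeat, which cannot contain any seed site whose DNA
#' reverse complement includes a G or T -- so every seed occurrence in the
#' fixture is an implant, never chance.  (Each implanted seed must
#' therefore contain at least one A or C.)  For each implant row the DNA
#' reverse complement of the seed is written into the stated region of the
#' longest transcript (or into the short transcript for region
#' \code{"shortonly"}, which the longest-transcript rule must ignore).
#' Strands alternate +/- across genes to exercise both orientations.
#'
#' @param dir output directory (created).
#' @param implants data.frame with columns \code{gene}, \code{mirna},
#'   \code{seed} (7-nt RNA) and \code{region} in \code{c("5putr", "cds",
#'   "3putr", "intron", "shortonly")}; one row per gene.
#' @param extraMirnas optional named character vector of additional miRNA
#'   sequences to include in the miRNA FASTA.
#' @return list with paths \code{genome}, \code{gtf}, \code{mirnaFasta}
#'   and the implant \code{plan} (with strand and genomic site
#'   coordinates).
#' @export
generateGenomeFixture <- function(dir, implants, extraMirnas = NULL) {
  stopifnot(is.data.frame(implants),
            all(c("gene", "mirna", "seed", "region") %in% names(implants)),
            !anyDuplicated(implants$gene),
            all(implants$region %in% names(.toyImplantAt)),
            all(nchar(implants$seed) == 7L))
  if (any(!grepl("[ACac]", chartr("U", "u", implants$seed))))
    stop("each seed must contain at least one A or C ",
         "(its site must be absent from the AC-repeat background)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lay <- .toyLayout
  s0 <- 101L                             # gene start on every chromosome
  chromLen <- s0 + lay$geneLen + 99L
  gtf <- character(); seqs <- character(); plan <- implants
  plan$strand <- rep_len(c("+", "-"), nrow(implants))
  plan$chrom <- paste0("chr", seq_len(nrow(implants)))
  plan$site_start <- NA_integer_

  orient <- function(a, b, strand, txStart, txEnd) {
    ## oriented offsets [a, b] -> genomic interval
    if (strand == "+") c(txStart + a - 1L, txStart + b - 1L)
    else c(txEnd - b + 1L, txEnd - a + 1L)
  }
  attr1 <- function(g, t = NULL)
    paste0("gene_id \"", g, "\";",
           if (!is.null(t)) paste0(" transcript_id \"", t, "\";"))
  for (i in seq_len(nrow(implants))) {
    g <- implants$gene[i]; strand <- plan$strand[i]; chrom <- plan$chrom[i]
    txStart <- s0; txEnd <- s0 + lay$txLen - 1L
    shortStart <- s0 + lay$shortOff[1L]; shortEnd <- s0 + lay$shortOff[2L]
    geneEnd <- s0 + lay$geneLen - 1L
    feat <- function(type, iv, tx)
      paste(chrom, "toy", type, iv[1L], iv[2L], ".", strand, ".",
            attr1(g, tx), sep = "\t")
    tL <- paste0(g, ".tL"); tS <- paste0(g, ".tS")
    gtf <- c(gtf,
      paste(chrom, "toy", "gene", s0, geneEnd, ".", strand, ".",
            attr1(g), sep = "\t"),
      feat("transcript", c(txStart, txEnd), tL),
      feat("exon", orient(lay$exon1[1L], lay$exon1[2L], strand,
                          txStart, txEnd), tL),
      feat("exon", orient(lay$exon2[1L], lay$exon2[2L], strand,
                          txStart, txEnd), tL),
      feat("five_prime_utr", orient(lay$utr5[1L], lay$utr5[2L], strand,
                                    txStart, txEnd), tL),
      feat("CDS", orient(lay$cds1[1L], lay$cds1[2L], strand,
                         txStart, txEnd), tL),
      feat("CDS", orient(lay$cds2[1L], lay$cds2[2L], strand,
                         txStart, txEnd), tL),
      feat("three_prime_utr", orient(lay$utr3[1L], lay$utr3[2L], strand,
                                     txStart, txEnd), tL),
      feat("transcript", c(shortStart, shortEnd), tS),
      feat("exon", c(shortStart, shortEnd), tS))

    chrSeq <- strsplit(paste(rep("AC", ceiling(chromLen / 2)),
                             collapse = ""), "")[[1L]][seq_len(chromLen)]
    site <- .revcompDNA(chartr("U", "T", toupper(implants$seed[i])))
    region <- implants$region[i]
    if (region == "shortonly") {
      gs <- shortStart + 50L           # oriented == genomic offset is fine
      bases <- if (strand == "+") site else .revcompDNA(site)
    } else {
      p <- .toyImplantAt[[region]]
      iv <- orient(p, p + 6L, strand, txStart, txEnd)
      gs <- iv[1L]
      bases <- if (strand == "+") site else .revcompDNA(site)
    }
    chrSeq[gs:(gs + 6L)] <- strsplit(bases, "")[[1L]]
    plan$site_start[i] <- gs
    seqs[chrom] <- paste(chrSeq, collapse = "")
  }
  genomePath <- file.path(dir, "genome.fa")
  gtfPath <- file.path(dir, "annotation.gtf")
  mirPath <- file.path(dir, "mirnas.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), genomePath)
  writeLines(gtf, gtfPath)
  mirSeqs <- setNames(
    paste0("A", chartr("T", "U", toupper(implants$seed)), "ACAACAACAACAAC"),
    implants$mirna)
  if (!is.null(extraMirnas))
    mirSeqs <- c(mirSeqs, extraMirnas[setdiff(names(extraMirnas),
                                              names(mirSeqs))])
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(mirSeqs), mirPath)
  list(genome = genomePath, gtf = gtfPath, mirnaFasta = mirPath,
       plan = plan)
}
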