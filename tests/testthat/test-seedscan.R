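# One shared toy genome fixture, rebuilt in a temp dir per test file run:
# five genes covering all implant regions, alternating strands.
localFixture <- function(env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  implants <- data.frame(
    gene = sprintf("TG%d", 1:5),
    mirna = sprintf("tmir%d", 1:5),
    seed = c("GUACGUA", "ACCGGUU", "CAUCAUC", "GGAACGG", "UACCAGU"),
    region = c("5putr", "cds", "3putr", "intron", "shortonly"),
    stringsAsFactors = FALSE)
  fix <- generateGenomeFixture(file.path(dir, "gf"), implants)
  genome <- Biostrings::readDNAStringSet(fix$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  models <- readGeneModels(fix$gtf)
  mirSeqs <- Biostrings::readRNAStringSet(fix$mirnaFasta)
  list(fix = fix, implants = implants, genome = genome, models = models,
       mirSeqs = setNames(as.character(mirSeqs), names(mirSeqs)))
}

test_that("seed extraction returns bases 2-8 from the 5' end", {
  expect_identical(extractSeed("ACGUACGUACGU"), "CGUACGU")
  expect_identical(extractSeed("ACGUACGU"), "CGUACGU")   # 8 nt boundary
  expect_identical(extractSeed("acguacgt"), "CGUACGU")   # case + T -> U
  expect_error(extractSeed("ACGUACG"), "shorter")
})

test_that("longest transcript is chosen by genomic span with ID tie-break", {
  f <- localFixture()
  m <- f$models[["TG1"]]
  expect_s4_class(m, "GeneModel")
  expect_identical(m@txId, "TG1.tL")          # 700 bp beats 200 bp
  expect_identical(m@txEnd - m@txStart + 1L, 700L)
  expect_length(m@cds, 2L)
  expect_length(m@utr5, 1L)
  expect_length(m@utr3, 1L)
  # tie-break: two equal-span transcripts pick the lexicographically first
  gtf2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1\tt\ttranscript\t1\t100\t.\t+\t.\tgene_id \"g\";",
          "transcript_id \"T2\";"),
    paste("chr1\tt\texon\t1\t100\t.\t+\t.\tgene_id \"g\";",
          "transcript_id \"T2\";"),
    paste("chr1\tt\ttranscript\t101\t200\t.\t+\t.\tgene_id \"g\";",
          "transcript_id \"T1\";"),
    paste("chr1\tt\texon\t101\t200\t.\t+\t.\tgene_id \"g\";",
          "transcript_id \"T1\";")), gtf2)
  expect_identical(readGeneModels(gtf2)[["g"]]@txId, "T1")
  # non-coding transcript: empty CDS/UTR interval sets
  nc <- readGeneModels(gtf2)[["g"]]
  expect_length(nc@cds, 0L)
  expect_length(nc@utr5, 0L)
  expect_length(nc@utr3, 0L)
})

test_that("gene sequences are strand-aware transcript-oriented substrings", {
  genome <- Biostrings::DNAStringSet(c(chrT = "AAACGTTT"))
  plus <- new("GeneModel", geneId = "gp", chrom = "chrT", strand = "+",
              geneStart = 4L, geneEnd = 7L, txId = "t", txStart = 4L,
              txEnd = 7L, utr5 = IRanges::IRanges(), cds = IRanges::IRanges(),
              utr3 = IRanges::IRanges(), exons = IRanges::IRanges())
  expect_identical(as.character(geneSequence(plus, genome)), "CGTT")
  minus <- plus; minus@strand <- "-"
  expect_identical(as.character(geneSequence(minus, genome)), "AACG")
  beyond <- plus; beyond@txEnd <- 99L; beyond@geneEnd <- 99L
  expect_error(geneSequence(beyond, genome), "exceeds")
})

test_that("seed matching searches the reverse complement by default", {
  hits <- findSeed("AAACGTACGTAAA", "ACGUACG")
  expect_identical(hits, 4L)                  # revcomp(ACGUACG) = CGTACGT
  expect_identical(findSeed("ACGTACG", "ACGUACG", "literal"), 1L)
  expect_length(findSeed("AAAAAAAAA", "CCCCCCC"), 0L)
  # overlapping matches are all reported
  expect_identical(findSeed("GCGCGCGCG", "GCGCGCG", "literal"), c(1L, 3L))
})

test_that("coordinate round-trips are the identity on both strands", {
  f <- localFixture()
  for (g in c("TG1", "TG2")) {               # one + and one - strand gene
    m <- f$models[[g]]
    L <- m@txEnd - m@txStart + 1L
    pos <- c(1L, 7L, 350L, L)
    expect_identical(genomicToTranscript(m, transcriptToGenomic(m, pos)),
                     pos)
    gpos <- c(m@txStart, m@txStart + 5L, m@txEnd)
    expect_identical(transcriptToGenomic(m, genomicToTranscript(m, gpos)),
                     gpos)
  }
  expect_identical(f$models[["TG1"]]@strand, "+")
  expect_identical(f$models[["TG2"]]@strand, "-")
})

test_that("implanted seeds are found in exactly the planned regions", {
  f <- localFixture()
  regionCol <- c(`5putr` = "utr5", cds = "cds", `3putr` = "utr3")
  for (i in 1:4) {
    g <- f$implants$gene[i]
    seed <- extractSeed(f$mirSeqs[[f$implants$mirna[i]]])
    expect_identical(seed, f$implants$seed[i])
    hits <- findSeed(geneSequence(f$models[[g]], f$genome), seed)
    expect_gte(length(hits), 1L)
    fl <- classifyMatchRegions(f$models[[g]], hits)
    expect_true(fl[["anywhere"]])
    region <- f$implants$region[i]
    if (region == "intron") {
      expect_false(fl[["any_region"]])
    } else {
      want <- regionCol[[region]]
      for (r in c("utr5", "cds", "utr3"))
        expect_identical(unname(fl[[r]]), r == want)
    }
  }
})

test_that("sites only in a shorter transcript are invisible to the scan", {
  f <- localFixture()
  g <- f$implants$gene[5]                     # region = shortonly
  seed <- extractSeed(f$mirSeqs[[f$implants$mirna[5]]])
  hits <- findSeed(geneSequence(f$models[[g]], f$genome), seed)
  expect_length(hits, 0L)
})

test_that("the seed-presence summary aggregates region flags as percentages", {
  f <- localFixture()
  tab <- data.frame(gene = f$implants$gene[1:4],
                    mirna = f$implants$mirna[1:4],
                    stringsAsFactors = FALSE)
  s <- summarizeSeedPresence(tab, f$models, f$genome, f$mirSeqs)
  expect_identical(s$n_interactions, 4L)
  expect_equal(s$with_seed_anywhere, 100)
  expect_equal(s$in_5putr, 25)
  expect_equal(s$in_cds, 25)
  expect_equal(s$in_3putr, 25)
  expect_equal(s$in_any_annotated_region, 75)    # intron implant excluded
  expect_gte(s$with_seed_anywhere, max(s$in_5putr, s$in_3putr, s$in_cds))
  expect_lte(s$in_any_annotated_region, s$in_5putr + s$in_3putr + s$in_cds)

  # unknown features are skipped, empty tables yield absent percentages
  tab2 <- rbind(tab, data.frame(gene = "nope", mirna = "tmir1"))
  s2 <- suppressMessages(
    summarizeSeedPresence(tab2, f$models, f$genome, f$mirSeqs))
  expect_identical(s2$n_skipped, 1L)
  s0 <- summarizeSeedPresence(tab[0, ], f$models, f$genome, f$mirSeqs)
  expect_true(is.na(s0$with_seed_anywhere))
})
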