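#' Materialise a synthetic demo workspace on disk
#'
#' Writes everything \code{\link{runPipeline}} consumes: the three
#' expression matrices as TSV, a ground-truth table of planted pairs, a
#' feature-coordinates table (synthetic chromosomal positions for the
#' ordered heatmap), optionally a two-column target-pair database built
#' from the planted pairs (a synthetic stand-in for a curated database)
#' and the toy genome/GTF/miRNA-FASTA fixture with each planted pair's
#' seed implanted in its target's 3'UTR.
#'
#' @param dir output directory (created).
#' @param spec a \code{\link{synthSpec}}.
#' @param withGenome also write the seed-scan fixture (default TRUE).
#' @param withDatabase also write \code{db_planted.tsv} containing the
#'   planted pairs (default TRUE).
#' @return list of file paths plus the ground truth.
#' @export
simulateWorkspace <- function(dir, spec = synthSpec(), withGenome = TRUE,
                              withDatabase = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generateDataset(spec)
  paths <- list(
    mrna = file.path(dir, "mrna.tsv"),
    protein = file.path(dir, "protein.tsv"),
    mirna = file.path(dir, "mirna.tsv"),
    groundTruth = file.path(dir, "ground_truth.tsv"),
    coordinates = file.path(dir, "coordinates.tsv"))
  writeExpressionMatrix(ds$M, paths$mrna)
  writeExpressionMatrix(ds$P, paths$protein)
  writeExpressionMatrix(ds$MI, paths$mirna)
  write.table(ds$groundTruth$planted, paths$groundTruth, sep = "\t",
              quote = FALSE, row.names = FALSE)
  ## synthetic chromosomal positions: features dealt over chr1..chr5
  feats <- c(rownames(ds$M), rownames(ds$MI))
  coords <- data.frame(
    id = feats,
    chrom = paste0("chr", rep_len(1:5, length(feats))),
    start = 1000L * seq_along(feats), stringsAsFactors = FALSE)
  write.table(coords, paths$coordinates, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (withDatabase) {
    paths$database <- file.path(dir, "db_planted.tsv")
    write.table(ds$groundTruth$planted[, c("mirna", "gene")],
                paths$database, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = c("mirna", "gene"))
  }
  if (withGenome) {
    implants <- data.frame(gene = ds$groundTruth$planted$gene,
                           mirna = ds$groundTruth$planted$mirna,
                           seed = NA_character_, region = "3putr",
                           stringsAsFactors = FALSE)
    implants <- implants[!duplicated(implants$gene), , drop = FALSE]
    implants <- implants[!duplicated(implants$mirna), , drop = FALSE]
    seeds <- .randomSeeds(nrow(implants), spec$seed)
    implants$seed <- seeds
    extra <- setdiff(rownames(ds$MI), implants$mirna)
    extraSeqs <- if (length(extra))
      setNames(paste0("A", .randomSeeds(length(extra), spec$seed + 1L),
                      "ACAACAACAACAAC"), extra)
    fix <- generateGenomeFixture(file.path(dir, "genome"), implants,
                                 extraMirnas = extraSeqs)
    paths$genome <- fix$genome
    paths$gtf <- fix$gtf
    paths$mirnaFasta <- fix$mirnaFasta
    paths$implantPlan <- file.path(dir, "genome", "implant_plan.tsv")
    write.table(fix$plan, paths$implantPlan, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  c(paths, list(groundTruthData = ds$groundTruth))
}

## deterministic 7-mer RNA seeds, each containing at least one A or C
.randomSeeds <- function(n, seed) {
  if (!n) return(character())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    repeat {
      s <- paste(sample(c("A", "C", "G", "U"), 7L, replace = TRUE),
                 collapse = "")
      if (grepl("[AC]", s)) return(s)
    }
  }, character(1L))
}

#' Run the full target-prediction pipeline
#'
#' Stages: read inputs, preprocess (missingness filter, median imputation,
#' log2, top-variance proteins, alignment), compute the correlation grid,
#' select the top quartile of positive p-value improvements, annotate and
#' test enrichment against any loaded databases together with the two
#' bivariate baselines, optionally scan selected targets for miRNA seeds,
#' and render the chromosomally ordered heatmap.  Writes
#' \code{interactions.tsv}, \code{validation_summary.tsv},
#' \code{seed_summary.tsv} (when a genome is given),
#' \code{heatmap.png} + \code{heatmap_colors.tsv}, and
#' \code{manifest.yaml} (parameters, input checksums, package version) to
#' \code{outdir}.  A manifest file can be passed back as \code{config} to
#' reproduce a run bit-identically.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognised keys: paths \code{mrna}, \code{protein}, \code{mirna},
#'   \code{outdir}, optional \code{databases} (named list of pair files),
#'   \code{coordinates}, \code{genome}, \code{gtf}, \code{mirnaFasta};
#'   parameters \code{maxMissingFraction} (0.10), \code{keepFraction}
#'   (0.5), \code{pseudocount} (1), \code{quartile} (0.75), \code{alpha}
#'   (0.05), \code{matchMode} ("reverse_complement"),
#'   \code{topMirnaFraction} (1).
#' @param quiet suppress progress messages.
#' @return (invisibly) list with the interaction table, the grid, the
#'   validation summary, the seed summary (or NULL) and output paths.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(maxMissingFraction = 0.10, keepFraction = 0.5,
                   pseudocount = 1, quartile = 0.75, alpha = 0.05,
                   matchMode = "reverse_complement", topMirnaFraction = 1)
  config <- utils::modifyList(defaults, config)
  for (key in c("mrna", "protein", "mirna", "outdir"))
    if (is.null(config[[key]]))
      stop("config key '", key, "' is required")
  for (key in c("mrna", "protein", "mirna"))
    if (!file.exists(config[[key]]))
      stop("input for --", key, " not found: ", config[[key]])
  say <- function(...) if (!quiet) message("[", format(Sys.time(),
                                                       "%H:%M:%S"),
                                           "] ", ...)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  say("reading matrices")
  M <- readExpressionMatrix(config$mrna, "mrna")
  P <- readExpressionMatrix(config$protein, "protein")
  MI <- readExpressionMatrix(config$mirna, "mirna")

  say("preprocessing")
  ds <- preprocessDataset(M, P, MI,
                          maxMissingFraction = config$maxMissingFraction,
                          keepFraction = config$keepFraction,
                          pseudocount = config$pseudocount)

  say("computing correlation grid (", nrow(mrna(ds)), " genes x ",
      nrow(mirna(ds)), " miRNAs)")
  grid <- computeGrid(ds)
  table <- selectInteractions(grid, quartile = config$quartile)

  dbs <- list()
  for (nm in names(config$databases))
    dbs[[nm]] <- readTargetDatabase(config$databases[[nm]], nm)
  table <- annotateValidated(table, dbs)

  say("validation: ", nrow(table), " selected interactions")
  universe <- buildUniverse(grid)
  predicted <- pairKey(table$mirna, table$gene)
  ## the two comparator methods, run under the same conditions
  blM <- bivariateBaseline(mrna(ds), mirna(ds), alpha = config$alpha)
  blP <- bivariateBaseline(protein(ds), mirna(ds), alpha = config$alpha)
  enr <- function(keys) lapply(dbs, function(db)
    hypergeometricEnrichment(intersect(keys, universe), db, universe))
  fractions <- c("mRNA-miRNA bivariate" = blM$fraction,
                 "protein-miRNA bivariate" = blP$fraction,
                 "partial correlation" = length(predicted) /
                   length(universe))
  summary <- summarizeValidation(
    partial = enr(predicted), baselineMrna = enr(blM$pairs),
    baselineProtein = enr(blP$pairs), fractions = fractions)

  seedSummary <- NULL
  if (!is.null(config$genome)) {
    say("seed scanning")
    models <- readGeneModels(config$gtf, geneIds = unique(table$gene))
    genome <- Biostrings::readDNAStringSet(config$genome)
    names(genome) <- sub("\\s.*", "", names(genome))
    mirSeqs <- Biostrings::readRNAStringSet(config$mirnaFasta)
    names(mirSeqs) <- sub("\\s.*", "", names(mirSeqs))
    seedSummary <- summarizeSeedPresence(table, models, genome, mirSeqs,
                                         matchMode = config$matchMode)
  }

  say("rendering heatmap")
  ordRows <- genes(grid); ordCols <- mirnas(grid)
  if (!is.null(config$coordinates)) {
    coords <- read.delim(config$coordinates, stringsAsFactors = FALSE)
    ordRows <- chromosomalSort(genes(grid), coords)$ids
    ordCols <- chromosomalSort(mirnas(grid), coords)$ids
  }
  out <- list(
    interactions = file.path(config$outdir, "interactions.tsv"),
    validation = file.path(config$outdir, "validation_summary.tsv"),
    heatmap = file.path(config$outdir, "heatmap.png"),
    colorMatrix = file.path(config$outdir, "heatmap_colors.tsv"),
    manifest = file.path(config$outdir, "manifest.yaml"))
  writeInteractionTable(table, out$interactions)
  write.table(cbind(measure = rownames(summary), as.data.frame(summary)),
              out$validation, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(seedSummary)) {
    out$seedSummary <- file.path(config$outdir, "seed_summary.tsv")
    ss <- seedSummary[c("n_interactions", "with_seed_anywhere",
                        "in_5putr", "in_3putr", "in_cds",
                        "in_any_annotated_region")]
    write.table(data.frame(measure = names(ss),
                           value = unlist(ss, use.names = FALSE)),
                out$seedSummary, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  renderHeatmap(grid, table, out$heatmap, orderRows = ordRows,
                orderCols = ordCols, MI = mirna(ds),
                topMirnaFraction = config$topMirnaFraction,
                colorMatrixPath = out$colorMatrix)

  inputs <- config[c("mrna", "protein", "mirna", "coordinates", "genome",
                     "gtf", "mirnaFasta")]
  inputs <- inputs[!vapply(inputs, is.null, logical(1L))]
  manifest <- c(config,
                list(input_md5 = as.list(tools::md5sum(unlist(inputs))),
                     package_version =
                       as.character(utils::packageVersion("miRTarPC"))))
  yaml::write_yaml(manifest, out$manifest)
  say("done: ", nrow(table), " interactions written to ", out$interactions)
  invisible(list(table = table, grid = grid, summary = summary,
                 seedSummary = seedSummary, paths = out, dataset = ds))
}
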