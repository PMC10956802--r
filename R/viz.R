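#' Order features by chromosomal location
#'
#' Stable sort by (chromosome rank, start, ID), where chromosomes rank
#' 1..22, then X, Y, MT, then anything else lexicographically (a leading
#' \code{"chr"} prefix is ignored for ranking).  Features without
#' coordinates are appended in input order and flagged.
#'
#' @param ids character vector of feature IDs.
#' @param coordinates data.frame with rownames (or an \code{id} column)
#'   and columns \code{chrom} and \code{start}; may cover only part of
#'   \code{ids}.
#' @return list with \code{ids} (the ordered vector) and \code{missing}
#'   (IDs that had no coordinates).
#' @export
chromosomalSort <- function(ids, coordinates) {
  if (!is.null(coordinates$id)) rownames(coordinates) <- coordinates$id
  known <- ids[ids %in% rownames(coordinates)]
  unknown <- ids[!ids %in% rownames(coordinates)]
  if (!length(known))
    return(list(ids = ids, missing = unknown))
  chrom <- as.character(coordinates[known, "chrom"])
  start <- as.numeric(coordinates[known, "start"])
  ord <- order(.chromRank(chrom), start, known)
  list(ids = c(known[ord], unknown), missing = unknown)
}

.chromRank <- function(chrom) {
  base <- sub("^chr", "", chrom, ignore.case = TRUE)
  rank <- suppressWarnings(as.numeric(base))        # 1..22 numeric
  rank[base %in% c("X", "x")] <- 23
  rank[base %in% c("Y", "y")] <- 24
  rank[base %in% c("MT", "M", "mt")] <- 25
  other <- is.na(rank)
  if (any(other))
    rank[other] <- 25 + as.integer(factor(base[other],
                                          levels = sort(unique(base[other]))))
  rank
}

#' Cell colors for the summary heatmap
#'
#' Builds the color matrix the heatmap renders: background for
#' non-significant cells; a white-to-red ramp over the absolute partial
#' estimate for significant cells (intensity scaled within the significant
#' set; the stronger the conditioned correlation, the deeper the red); a
#' fixed dark green for cells both significant and validated in at least
#' one database.  "Significant" means exactly: present in the interaction
#' table.
#'
#' @param grid a \code{\linkS4class{CorrelationGrid}}.
#' @param table interaction data.frame (with \code{validated_any} if
#'   validation was run).
#' @param orderRows,orderCols optional ordered ID vectors (e.g. from
#'   \code{\link{chromosomalSort}}); default: grid order.
#' @param background background color.
#' @param rampN number of red ramp steps.
#' @return character matrix of colors (rows x cols as ordered).
#' @export
heatmapColorMatrix <- function(grid, table, orderRows = NULL,
                               orderCols = NULL, background = "grey95",
                               rampN = 100L) {
  orderRows <- if (is.null(orderRows)) genes(grid) else orderRows
  orderCols <- if (is.null(orderCols)) mirnas(grid) else orderCols
  stopifnot(all(orderRows %in% genes(grid)),
            all(orderCols %in% mirnas(grid)))
  cm <- matrix(background, length(orderRows), length(orderCols),
               dimnames = list(orderRows, orderCols))
  if (!nrow(table)) return(cm)
  ramp <- grDevices::colorRampPalette(c("#FFF5F0", "#67000D"))(rampN)
  est <- abs(table$partial_estimate)
  span <- max(est) - min(est)
  idx <- if (span > 0) 1L + floor((rampN - 1L) * (est - min(est)) / span)
         else rep(rampN, length(est))
  col <- ramp[idx]
  validated <- if (!is.null(table$validated_any)) table$validated_any
               else rep(FALSE, nrow(table))
  col[validated] <- "#006400"
  keep <- table$gene %in% orderRows & table$mirna %in% orderCols
  cm[cbind(match(table$gene[keep], orderRows),
           match(table$mirna[keep], orderCols))] <- col[keep]
  cm
}

#' Render the chromosomally ordered summary heatmap
#'
#' Genes on the rows and miRNAs on the columns, both typically ordered by
#' chromosomal location (pass orders from \code{\link{chromosomalSort}}).
#' Red marks significant pairs (intensity by partial estimate), dark green
#' pairs that are significant and validated; everything else is
#' background.  Optionally restricts the columns to the most expressed
#' miRNAs (highest mean expression in \code{MI}) for readability.
#'
#' Output format follows the file extension: \code{.png} or \code{.svg}.
#' A companion TSV dump of the color matrix is written when
#' \code{colorMatrixPath} is given; rendering is deterministic at the
#' color-matrix level.
#'
#' @param grid a \code{\linkS4class{CorrelationGrid}}.
#' @param table interaction data.frame.
#' @param outPath image path (.png or .svg).
#' @param orderRows,orderCols optional ordered ID vectors.
#' @param MI miRNA expression matrix, required when
#'   \code{topMirnaFraction < 1}.
#' @param topMirnaFraction fraction of most-expressed miRNAs to keep as
#'   columns (1 = all).
#' @param colorMatrixPath optional TSV path for the color matrix dump.
#' @return (invisibly) the color matrix.
#' @export
renderHeatmap <- function(grid, table, outPath, orderRows = NULL,
                          orderCols = NULL, MI = NULL,
                          topMirnaFraction = 1, colorMatrixPath = NULL) {
  orderCols <- if (is.null(orderCols)) mirnas(grid) else orderCols
  if (topMirnaFraction < 1) {
    if (is.null(MI))
      stop("MI is required to rank miRNAs by expression")
    k <- max(1L, floor(topMirnaFraction * length(orderCols)))
    mu <- rowMeans(MI)[orderCols]
    top <- orderCols[order(-mu, orderCols)][seq_len(k)]
    orderCols <- orderCols[orderCols %in% top]
  }
  cm <- heatmapColorMatrix(grid, table, orderRows, orderCols)
  if (!is.null(colorMatrixPath)) {
    write.table(cbind(id = rownames(cm), as.data.frame(cm)),
                colorMatrixPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  ext <- tolower(tools::file_ext(outPath))
  dev <- switch(ext,
    png = function() grDevices::png(outPath, width = 1200, height = 900),
    svg = function() grDevices::svg(outPath, width = 12, height = 9),
    stop("unsupported image format: ", ext))
  dev()
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(5, 5, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  pal <- unique(as.vector(cm))
  z <- matrix(match(cm, pal), nrow(cm), ncol(cm))
  ## image() draws row 1 at the bottom; flip so gene 1 is on top
  graphics::image(x = seq_len(ncol(cm)), y = seq_len(nrow(cm)),
                  z = t(z[rev(seq_len(nrow(z))), , drop = FALSE]),
                  col = pal, zlim = c(0.5, length(pal) + 0.5),
                  axes = FALSE,
                  xlab = "miRNAs (chromosomal order)",
                  ylab = "genes (chromosomal order)", useRaster = FALSE)
  graphics::box()
  invisible(cm)
}
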