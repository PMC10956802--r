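#' Drop features with too many missing values
#'
#' Keeps exactly the features whose missing fraction across samples is
#' strictly below \code{maxMissingFraction} (default 10\%); row order is
#' preserved.
#'
#' @param m numeric matrix, features x samples.
#' @param maxMissingFraction maximum tolerated missing fraction, in [0, 1].
#' @return the filtered matrix (possibly with zero rows, with a warning).
#' @export
filterByMissingness <- function(m, maxMissingFraction = 0.10) {
  stopifnot(is.matrix(m), maxMissingFraction >= 0, maxMissingFraction <= 1)
  frac <- rowMeans(is.na(m))
  keep <- frac < maxMissingFraction
  if (!any(keep)) warning("no feature passes the missingness filter")
  m[keep, , drop = FALSE]
}

#' Impute missing entries with the per-feature median
#'
#' Each missing entry is replaced by the median of that feature's observed
#' values across samples.  Features with no observed value at all are an
#' error; filter them out first.
#'
#' @param m numeric matrix, features x samples.
#' @return matrix with no missing entries.
#' @export
imputeMedian <- function(m) {
  stopifnot(is.matrix(m))
  allmiss <- rowSums(!is.na(m)) == 0L
  if (any(allmiss))
    stop("feature(s) with all values missing: ",
         paste(head(rownames(m)[allmiss], 3L), collapse = ", "))
  miss <- which(is.na(m), arr.ind = TRUE)
  if (nrow(miss)) {
    med <- apply(m, 1L, median, na.rm = TRUE)
    m[miss] <- med[miss[, 1L]]
  }
  m
}

#' log2-transform an expression matrix
#'
#' Applies \code{log2(x + pseudocount)} entrywise.  The default pseudocount
#' of 1 suits count-like non-negative values; use 0 for data already
#' strictly positive.
#'
#' @param m numeric matrix.
#' @param pseudocount non-negative offset added before the log.
#' @return transformed matrix.
#' @export
log2Transform <- function(m, pseudocount = 1) {
  stopifnot(is.matrix(m), pseudocount >= 0)
  if (any(m + pseudocount <= 0, na.rm = TRUE))
    stop("non-positive value(s) after adding pseudocount ", pseudocount)
  m2 <- log2(m + pseudocount)
  attr(m2, "layer") <- attr(m, "layer")
  m2
}

#' Keep the most variable features
#'
#' Retains the \code{ceiling(keepFraction * nrow(m))} features with the
#' largest sample variance (the method needs variance in the protein
#' profiles to detect conditioning effects).  Ties are broken by feature ID
#' (lexicographic); relative row order is preserved among survivors.
#'
#' @param m numeric matrix with rownames, no missing values.
#' @param keepFraction fraction of features to keep, in (0, 1].
#' @param stat dispersion statistic: \code{"variance"} (default),
#'   \code{"sd"} or \code{"mad"} (all rank features identically except
#'   \code{"mad"}).
#' @return filtered matrix.
#' @export
selectTopVariance <- function(m, keepFraction = 0.5,
                              stat = c("variance", "sd", "mad")) {
  stopifnot(is.matrix(m), keepFraction > 0, keepFraction <= 1)
  stat <- match.arg(stat)
  v <- switch(stat,
    variance = apply(m, 1L, var),
    sd = apply(m, 1L, stats::sd),
    mad = apply(m, 1L, stats::mad))
  k <- ceiling(keepFraction * nrow(m))
  ord <- order(-v, rownames(m))
  keep <- sort(ord[seq_len(k)])
  m[keep, , drop = FALSE]
}

#' Align mRNA, protein and miRNA matrices into an OmicsDataset
#'
#' Restricts all three matrices to their common samples (one canonical
#' sorted order applied to all) and mRNA/protein to their common genes.
#' Counts of discarded samples and genes are reported via \code{message}.
#' Matrices must already be imputed (no missing values).
#'
#' @param M,P,MI numeric matrices (mRNA, protein, miRNA; features x
#'   samples) with dimnames.
#' @return an \code{\linkS4class{OmicsDataset}}.
#' @export
alignDataset <- function(M, P, MI) {
  samp <- sort(intersect(intersect(colnames(M), colnames(P)), colnames(MI)))
  if (!length(samp)) stop("no sample shared by all three matrices")
  if (length(samp) < 4L)
    stop("fewer than 4 shared samples; partial correlation is undefined")
  genes <- intersect(rownames(M), rownames(P))
  if (!length(genes)) stop("no gene shared by mRNA and protein matrices")
  genes <- rownames(M)[rownames(M) %in% genes]   # keep M's order
  dropped <- c(mrna = nrow(M) - length(genes),
               protein = nrow(P) - length(genes),
               samples = max(ncol(M), ncol(P), ncol(MI)) - length(samp))
  if (any(dropped > 0))
    message("alignDataset: dropped ", dropped[["mrna"]], " mRNA / ",
            dropped[["protein"]], " protein rows outside the gene ",
            "intersection; up to ", dropped[["samples"]],
            " samples outside the common set")
  new("OmicsDataset",
      mrna = M[genes, samp, drop = FALSE],
      protein = P[genes, samp, drop = FALSE],
      mirna = MI[, samp, drop = FALSE])
}

#' Full preprocessing recipe
#'
#' Applies, in order: missingness filtering (protein and miRNA), median
#' imputation, log2 transform of the mRNA and miRNA matrices, top-variance
#' protein selection, and alignment.  The protein matrix is not
#' log-transformed by default (proteomic quantifications are typically
#' already ratio-scale); add \code{"protein"} to \code{log2Layers} to change
#' that.  The pipeline is idempotent: running it on its own output changes
#' nothing (given \code{pseudocount = 0}).
#'
#' @param M,P,MI raw matrices (mRNA, protein, miRNA; features x samples).
#' @param maxMissingFraction missingness threshold for protein and miRNA
#'   features (strict), default 0.10.
#' @param keepFraction fraction of most-variable proteins kept, default 0.5.
#' @param pseudocount offset for the log2 transform, default 1.
#' @param log2Layers layers to log2-transform.
#' @return an \code{\linkS4class{OmicsDataset}}.
#' @export
preprocessDataset <- function(M, P, MI, maxMissingFraction = 0.10,
                              keepFraction = 0.5, pseudocount = 1,
                              log2Layers = c("mrna", "mirna")) {
  P <- filterByMissingness(P, maxMissingFraction)
  MI <- filterByMissingness(MI, maxMissingFraction)
  M <- imputeMedian(M); P <- imputeMedian(P); MI <- imputeMedian(MI)
  if ("mrna" %in% log2Layers) M <- log2Transform(M, pseudocount)
  if ("mirna" %in% log2Layers) MI <- log2Transform(MI, pseudocount)
  if ("protein" %in% log2Layers) P <- log2Transform(P, pseudocount)
  P <- selectTopVariance(P, keepFraction)
  alignDataset(M, P, MI)
}
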