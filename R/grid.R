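#' Compute the full gene x miRNA correlation grid
#'
#' For every gene g and miRNA z: the partial correlation between the gene's
#' mRNA profile x and protein profile y conditioned on z, with its p-value
#' (t transform, n - 3 df); the bivariate mRNA-protein correlation per gene
#' (n - 2 df); and the improvement matrix
#' \code{bivariateP[g] - partialP[g, z]}.  Degenerate cells -- a constant
#' profile, or a conditioning correlation of magnitude 1, which would zero
#' the denominator of the partial-correlation formula -- are set to
#' \code{NA} and a count is reported.
#'
#' The computation is vectorised over the whole grid (three cross-profile
#' correlation matrices), so it matches \code{\link{partialWithP}} cell by
#' cell while scaling to thousands of genes.
#'
#' @param ds an \code{\linkS4class{OmicsDataset}}.
#' @return a \code{\linkS4class{CorrelationGrid}}.
#' @export
computeGrid <- function(ds) {
  stopifnot(is(ds, "OmicsDataset"))
  M <- mrna(ds); P <- protein(ds); MI <- mirna(ds)
  n <- ncol(M)
  constG <- apply(M, 1L, var) == 0 | apply(P, 1L, var) == 0
  constZ <- apply(MI, 1L, var) == 0

  ## per-gene bivariate r(y = protein, x = mRNA)
  ryx <- vapply(seq_len(nrow(M)), function(i)
    if (constG[i]) NA_real_ else min(1, max(-1, cor(P[i, ], M[i, ]))),
    numeric(1L))
  bivP <- .corP(ryx, df = n - 2L)

  ## cross correlations: genes x miRNAs
  tz <- t(MI)
  ryz <- suppressWarnings(cor(t(P), tz))   # protein vs miRNA
  rxz <- suppressWarnings(cor(t(M), tz))   # mRNA vs miRNA
  ryz[constG | is.na(ryz)] <- NA; rxz[constG | is.na(rxz)] <- NA
  ryz[, constZ] <- NA; rxz[, constZ] <- NA

  den <- sqrt(1 - ryz^2) * sqrt(1 - rxz^2)
  den[abs(ryz) >= 1 | abs(rxz) >= 1] <- NA    # |r| = 1 with the conditioner
  dm <- dim(ryz)
  pr <- matrix(pmin(1, pmax(-1, (ryx - ryz * rxz) / den)), dm[1L], dm[2L])
  pp <- matrix(.corP(as.vector(pr), df = n - 3L), dm[1L], dm[2L])
  pp[is.na(pr)] <- NA

  imp <- bivP - pp
  dimnames(pr) <- dimnames(pp) <- dimnames(imp) <-
    list(rownames(M), rownames(MI))
  ndeg <- sum(is.na(pp))
  if (ndeg) message("computeGrid: ", ndeg,
                    " degenerate cell(s) marked NA and excluded downstream")
  new("CorrelationGrid", genes = rownames(M), mirnas = rownames(MI),
      partialR = pr, partialP = pp,
      bivariateR = setNames(ryx, rownames(M)),
      bivariateP = setNames(bivP, rownames(M)),
      improvement = imp, nSamples = as.integer(n))
}

#' Select candidate interactions from the improvement distribution
#'
#' Candidate cells are those with strictly positive improvement (the
#' miRNA-conditioned p-value is lower than the bivariate one).  The
#' selection threshold is the \code{quartile}-th empirical quantile (linear
#' interpolation, quantile type 7) of the improvement values over the
#' candidate set; cells at or above the threshold are returned.  FDR
#' adjustment (Benjamini-Hochberg) is applied over the partial p-values of
#' \emph{all} non-degenerate grid cells -- every tested pair counts toward
#' multiplicity, not only the selected ones.
#'
#' @param grid a \code{\linkS4class{CorrelationGrid}}.
#' @param quartile quantile level defining "top of the distribution",
#'   default 0.75 (the upper quartile).
#' @return data.frame with columns \code{gene}, \code{mirna},
#'   \code{partial_estimate}, \code{partial_p}, \code{partial_p_fdr},
#'   \code{bivariate_p}, \code{improvement}, ordered by decreasing
#'   improvement (ties by gene then miRNA).
#' @export
selectInteractions <- function(grid, quartile = 0.75) {
  stopifnot(is(grid, "CorrelationGrid"), quartile > 0, quartile < 1)
  imp <- improvement(grid)
  pp <- partialP(grid)
  fdr <- pp
  fdr[] <- benjaminiHochberg(as.vector(pp))
  cand <- which(!is.na(imp) & imp > 0)
  empty <- data.frame(gene = character(), mirna = character(),
                      partial_estimate = numeric(), partial_p = numeric(),
                      partial_p_fdr = numeric(), bivariate_p = numeric(),
                      improvement = numeric(), stringsAsFactors = FALSE)
  if (!length(cand)) {
    warning("no pair with positive improvement; empty interaction table")
    return(empty)
  }
  thr <- quantile(imp[cand], probs = quartile, type = 7, names = FALSE)
  sel <- cand[imp[cand] >= thr]
  ij <- arrayInd(sel, dim(imp))
  out <- data.frame(
    gene = genes(grid)[ij[, 1L]],
    mirna = mirnas(grid)[ij[, 2L]],
    partial_estimate = partialR(grid)[sel],
    partial_p = pp[sel],
    partial_p_fdr = fdr[sel],
    bivariate_p = bivariateP(grid)[ij[, 1L]],
    improvement = imp[sel],
    stringsAsFactors = FALSE)
  out[order(-out$improvement, out$gene, out$mirna), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}
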