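#' Flag interactions found in target databases
#'
#' Adds one logical column per database (named \code{validated_<name>}) and
#' a \code{validated_any} column (their OR).  With an empty database list
#' the table is returned unchanged except that \code{validated_any} is all
#' \code{FALSE}.
#'
#' @param table interaction data.frame with \code{gene} and \code{mirna}
#'   columns.
#' @param dbs list of \code{\linkS4class{TargetDatabase}} objects.
#' @return the annotated data.frame.
#' @export
annotateValidated <- function(table, dbs = list()) {
  stopifnot(is.data.frame(table))
  any_ <- rep(FALSE, nrow(table))
  for (db in dbs) {
    flag <- hasPair(db, table$mirna, table$gene)
    table[[paste0("validated_", dbName(db))]] <- flag
    any_ <- any_ | flag
  }
  table$validated_any <- any_
  table
}

#' Universe of tested (gene, miRNA) pairs
#'
#' All non-degenerate cells of the grid, as a character vector of
#' \code{"mirna|gene"} keys.  This is the population the hypergeometric
#' enrichment draws from.
#'
#' @param grid a \code{\linkS4class{CorrelationGrid}}.
#' @return character vector of pair keys.
#' @export
buildUniverse <- function(grid) {
  ok <- which(!is.na(partialP(grid)))
  if (!length(ok)) return(character())
  ij <- arrayInd(ok, dim(partialP(grid)))
  pairKey(mirnas(grid)[ij[, 2L]], genes(grid)[ij[, 1L]])
}

#' Canonical pair key
#' @param mirna,gene identifier vectors.
#' @return character vector \code{"mirna|gene"}.
#' @export
pairKey <- function(mirna, gene) paste(mirna, gene, sep = "|")

#' Hypergeometric over-representation test of predictions in a database
#'
#' Database pairs are first intersected with the tested universe, then the
#' upper-tail inclusive probability \eqn{P(X \ge k)} is computed for
#' \eqn{X \sim} Hypergeometric(\eqn{N} = |universe|, \eqn{K} = |db in
#' universe|, \eqn{n} = |predicted|), where \eqn{k} is the observed overlap.
#'
#' @param predicted character vector of predicted pair keys (see
#'   \code{\link{pairKey}}); must be a subset of \code{universe}.
#' @param db a \code{\linkS4class{TargetDatabase}}.
#' @param universe character vector of tested pair keys.
#' @return list with \code{database_name}, \code{universe_size},
#'   \code{database_in_universe}, \code{predicted}, \code{overlap},
#'   \code{p_value}.
#' @export
hypergeometricEnrichment <- function(predicted, db, universe) {
  predicted <- unique(predicted); universe <- unique(universe)
  if (!all(predicted %in% universe))
    stop("predicted pairs must be a subset of the universe")
  dbk <- unique(pairKey(dbPairs(db)$mirna, dbPairs(db)$gene))
  K <- sum(dbk %in% universe)
  k <- sum(predicted %in% dbk)
  list(database_name = dbName(db),
       universe_size = length(universe),
       database_in_universe = K,
       predicted = length(predicted),
       overlap = k,
       p_value = hyperTailP(length(universe), K, length(predicted), k))
}

#' Upper-tail inclusive hypergeometric probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n): drawing n
#' items without replacement from N of which K are "successes".  Exact (via
#' \code{\link[stats]{phyper}}); \code{k = 0} gives 1.
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n draws.
#' @param k observed successes (may be a vector).
#' @return tail probability in [0, 1], vectorised over \code{k}.
#' @export
hyperTailP <- function(N, K, n, k) {
  stopifnot(K <= N, n <= N, all(k <= min(K, n)))
  p <- phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
  p[k <= 0] <- 1
  p
}

#' Bivariate correlation baseline for miRNA-target calling
#'
#' The comparator methods: call (feature, miRNA) pairs significant from the
#' direct Pearson correlation between an expression matrix (mRNA or
#' protein) and the miRNA matrix, Benjamini-Hochberg adjusted over all
#' tested pairs, selecting adjusted p strictly below \code{alpha}.
#'
#' @param expr numeric matrix (features x samples), no missing values.
#' @param MI miRNA matrix aligned on the same samples.
#' @param alpha FDR threshold, default 0.05.
#' @param negativeOnly if \code{TRUE}, additionally require a negative
#'   correlation estimate (repression-signed calling); default \code{FALSE},
#'   i.e. two-sided significance regardless of sign.
#' @return list with \code{pairs} (selected pair keys), \code{fraction}
#'   (selected / tested) and \code{tested} (pair count).
#' @export
bivariateBaseline <- function(expr, MI, alpha = 0.05, negativeOnly = FALSE) {
  stopifnot(identical(colnames(expr), colnames(MI)))
  n <- ncol(expr)
  r <- suppressWarnings(cor(t(expr), t(MI)))
  dm <- dim(r); dn <- dimnames(r)
  r <- matrix(pmin(1, pmax(-1, r)), dm[1L], dm[2L], dimnames = dn)
  p <- matrix(.corP(as.vector(r), df = n - 2L), dm[1L], dm[2L],
              dimnames = dn)
  p[is.na(r)] <- NA
  padj <- matrix(benjaminiHochberg(as.vector(p)), dm[1L], dm[2L],
                 dimnames = dn)
  sel <- which(!is.na(padj) & padj < alpha &
                 (!negativeOnly | r < 0))
  ij <- arrayInd(sel, dim(p))
  tested <- sum(!is.na(p))
  list(pairs = pairKey(rownames(MI)[ij[, 2L]], rownames(expr)[ij[, 1L]]),
       fraction = if (tested) length(sel) / tested else NA_real_,
       tested = tested)
}

#' Tabulate enrichment results against the baselines
#'
#' Builds the standard comparison table: one column per method (mRNA-miRNA
#' baseline, protein-miRNA baseline, partial-correlation method), one row
#' for the percentage of predicted pairs and one row of enrichment p-values
#' per database.  Percentages are formatted with 2 decimals in the
#' \code{print}ed form; the returned data.frame keeps full precision.
#'
#' @param partial list of enrichment results (one per database) for the
#'   partial-correlation method, plus its selected fraction.
#' @param baselineMrna,baselineProtein same-shaped lists for the two
#'   bivariate baselines (may be \code{NULL} to omit a column).
#' @param fractions named numeric vector of selected fractions (values in
#'   [0,1]) with names matching the column labels used.
#' @return data.frame, rows = "% of predicted miRNA-targets" then one
#'   "<db> enrichment" per database; columns = methods.
#' @export
summarizeValidation <- function(partial, baselineMrna = NULL,
                                baselineProtein = NULL, fractions) {
  cols <- list("mRNA-miRNA bivariate" = baselineMrna,
               "protein-miRNA bivariate" = baselineProtein,
               "partial correlation" = partial)
  cols <- cols[!vapply(cols, is.null, logical(1L))]
  dbsn <- if (length(partial)) vapply(partial, `[[`, character(1L),
                                   "database_name") else character()
  out <- data.frame(row.names = c("% of predicted miRNA-targets",
                                  if (length(dbsn))
                                    paste(dbsn, "enrichment")))
  for (lab in names(cols)) {
    enr <- cols[[lab]]
    pvals <- if (length(enr)) vapply(enr, `[[`, numeric(1L), "p_value")
             else numeric()
    out[[lab]] <- c(100 * unname(fractions[[lab]]), pvals)
  }
  class(out) <- c("validationSummary", class(out))
  out
}

#' @export
print.validationSummary <- function(x, ...) {
  m <- matrix("", nrow(x), ncol(x),
              dimnames = list(rownames(x), colnames(x)))
  for (j in seq_len(ncol(x))) {
    m[1L, j] <- sprintf("%.2f%%", as.numeric(x[1L, j]))
    if (nrow(x) > 1L)
      m[-1L, j] <- format(signif(as.numeric(x[-1L, j]), 3L))
  }
  print(as.data.frame(m), ...)
  invisible(x)
}
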