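#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers.  Empty cells and any string in \code{na} denote missing
#' values; they are returned as \code{NA}, never as zero.  Parsing is
#' locale-independent (decimal point).
#'
#' @param path path to a delimited text file.
#' @param layer label for the omic layer, one of \code{"mrna"},
#'   \code{"protein"}, \code{"mirna"}; stored as the \code{"layer"}
#'   attribute of the returned matrix.
#' @param sep field delimiter, default tab.
#' @param na strings treated as missing on input.
#' @return numeric matrix (features x samples) with rownames/colnames and a
#'   \code{"layer"} attribute.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\ts1\ts2", "g1\t1\t2", "g2\t3\tNA"), tf)
#' m <- readExpressionMatrix(tf, "mrna")
#' sum(is.na(m))  # 1
#' @export
readExpressionMatrix <- function(path, layer = c("mrna", "protein", "mirna"),
                                 sep = "\t", na = c("", "NA")) {
  layer <- match.arg(layer)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   na.strings = na, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a feature-ID column plus sample columns")
  ids <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(ids))
    stop("duplicate feature IDs: ", paste(unique(ids[duplicated(ids)]),
                                          collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample IDs in header")
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- is.na(vals) & !is.na(as.matrix(df[-1L]))
  if (any(bad))
    stop("non-numeric cell(s) that are not the missing sentinel, e.g. '",
         as.matrix(df[-1L])[which(bad)[1L]], "'")
  dimnames(vals) <- list(ids, samples)
  structure(vals, layer = layer)
}

#' Write an expression matrix as delimited text
#'
#' Inverse of \code{\link{readExpressionMatrix}}: missing values are written
#' as \code{"NA"}; finite values round-trip bit-identically (full precision).
#'
#' @param m numeric matrix with rownames and colnames.
#' @param path output path.
#' @param sep field delimiter.
#' @export
writeExpressionMatrix <- function(m, path, sep = "\t") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  chr <- format(m, digits = 17, trim = TRUE, scientific = FALSE)
  chr[is.na(m)] <- "NA"
  lines <- c(paste(c("id", colnames(m)), collapse = sep),
             paste(rownames(m), apply(chr, 1L, paste, collapse = sep),
                   sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column miRNA/gene pair database
#'
#' Accepts two-column delimited text (\code{mirna_id}, \code{gene_id}) with
#' an optional header line (detected when the first line's fields are
#' \code{"mirna"}/\code{"gene"}-like labels).  Duplicate pairs are dropped
#' with a message.  Native distribution formats of public databases are not
#' parsed; convert them to this pair format first.
#'
#' @param path path to the pair file.
#' @param name source label stored on the returned object.
#' @param sep field delimiter.
#' @return a \code{\linkS4class{TargetDatabase}}.
#' @export
readTargetDatabase <- function(path, name, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty target database file: ", path)
    return(TargetDatabase(character(), character(), name = name))
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("rows with fewer than two fields in ", path)
  first <- tolower(fields[[1L]])
  if (grepl("^mir", first[1L]) && grepl("^(gene|target)", first[2L]))
    fields <- fields[-1L]
  mi <- vapply(fields, `[`, character(1L), 1L)
  g <- vapply(fields, `[`, character(1L), 2L)
  TargetDatabase(mi, g, name = name)
}

#' Construct a TargetDatabase from pair vectors
#'
#' @param mirna,gene character vectors of equal length.
#' @param name source label.
#' @return a \code{\linkS4class{TargetDatabase}}; duplicates are dropped
#'   with a message reporting how many.
#' @export
TargetDatabase <- function(mirna, gene, name) {
  stopifnot(length(mirna) == length(gene))
  key <- paste(mirna, gene, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    message("dropped ", sum(dup), " duplicate pair(s) in database '",
            name, "'")
  new("TargetDatabase", name = name,
      pairs = data.frame(mirna = as.character(mirna[!dup]),
                         gene = as.character(gene[!dup]),
                         stringsAsFactors = FALSE))
}

#' Write an interaction table as TSV
#'
#' Columns: \code{gene}, \code{mirna}, \code{partial_estimate},
#' \code{partial_p}, \code{partial_p_fdr}, \code{bivariate_p},
#' \code{improvement}, then one logical column per annotated database plus
#' \code{validated_any} when validation flags are present.
#'
#' @param table interaction data.frame from \code{\link{selectInteractions}}
#'   (optionally passed through \code{\link{annotateValidated}}).
#' @param path output path.
#' @export
writeInteractionTable <- function(table, path) {
  stopifnot(is.data.frame(table))
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an interaction table written by \code{writeInteractionTable}
#' @param path path to the TSV.
#' @return data.frame.
#' @export
readInteractionTable <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
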