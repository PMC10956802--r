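#' Pearson correlation with a two-sided p-value
#'
#' The p-value comes from the classical t transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom.
#' Estimates are clamped to [-1, 1] against floating-point round-off.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with elements \code{r} and \code{p}.
#' @export
pearsonWithP <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch")
  if (n < 3L) stop("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0) stop("constant vector: correlation undefined")
  r <- min(1, max(-1, cor(x, y)))
  list(r = r, p = .corP(r, df = n - 2L))
}

## two-sided p for a correlation estimate at the given residual df
.corP <- function(r, df) {
  p <- 2 * pt(abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.xmin)),
              df = df, lower.tail = FALSE)
  pmin(p, 1)
}

#' First-order partial correlation from pairwise estimates
#'
#' \deqn{r_{yx.z} = \frac{r_{yx} - r_{yz} r_{xz}}
#'   {\sqrt{1 - r_{yz}^2}\sqrt{1 - r_{xz}^2}}}
#' i.e. the correlation between y and x after removing the linear effect of
#' the conditioning variable z.  The result is clamped to [-1, 1].
#'
#' @param ryx,ryz,rxz pairwise Pearson estimates; \code{|ryz|} and
#'   \code{|rxz|} must be < 1.
#' @return partial correlation estimate.
#' @export
partialCorrelation <- function(ryx, ryz, rxz) {
  if (any(abs(c(ryz, rxz)) >= 1))
    stop("conditioning correlation of magnitude 1: denominator is zero")
  r <- (ryx - ryz * rxz) / (sqrt(1 - ryz^2) * sqrt(1 - rxz^2))
  pmin(1, pmax(-1, r))
}

#' Partial correlation of two vectors given a third, with p-value
#'
#' Combines the three pairwise Pearson estimates via
#' \code{\link{partialCorrelation}}; the two-sided p-value uses
#' \eqn{t = r \sqrt{(n-3)/(1-r^2)}} on \eqn{n-3} degrees of freedom (one df
#' spent on the conditioning variable).
#'
#' @param x,y,z numeric vectors of equal length >= 4, none constant.
#' @return list with elements \code{r} and \code{p}.
#' @export
partialWithP <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("length mismatch")
  if (n < 4L) stop("need at least 4 observations (df = n - 3)")
  if (var(x) == 0 || var(y) == 0 || var(z) == 0)
    stop("constant vector: correlation undefined")
  r <- partialCorrelation(cor(y, x), cor(y, z), cor(x, z))
  list(r = r, p = .corP(r, df = n - 3L))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (delegates to
#' \code{\link[stats]{p.adjust}}), clipped to 1; \code{NA}s are preserved
#' and excluded from the multiplicity count.
#'
#' @param p numeric vector of raw p-values in [0, 1] (NAs allowed).
#' @return adjusted p-values, same length and order.
#' @export
benjaminiHochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
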