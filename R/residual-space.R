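#' Expected contact frequencies under independence
#'
#' For a contact frequency matrix with row totals r_i, column totals c_j
#' and grand total N, the expected count of cell (i, j) if contacts
#' occurred at random is e_ij = r_i * c_j / N.
#'
#' @param cfm a [ContactCounts-class] object or a non-negative count
#'   matrix.
#' @return Numeric matrix of expected counts with the input's dimnames.
#' @examples
#' m <- matrix(c(10, 0, 0, 10), 2, 2)
#' expectedFrequency(m)  # all cells 5
#' @export
expectedFrequency <- function(cfm) {
  o <- if (is(cfm, "ContactCounts")) contactMatrix(cfm) else as.matrix(cfm)
  N <- sum(o)
  if (N <= 0)
    stop("all-zero contact matrix: expected frequencies are undefined",
         call. = FALSE)
  outer(rowSums(o), colSums(o)) / N
}

#' Convert contact counts to the statistical residual space (SRV)
#'
#' Replaces each contact count o_ij by its adjusted standardized residual
#'
#' \deqn{d_{ij} = \frac{o_{ij} - e_{ij}}
#'   {\sqrt{e_{ij}\,(1 - r_i/N)\,(1 - c_j/N)}}}
#'
#' where e_ij = r_i c_j / N is the expectation under independence. Under
#' the null of random contacts each residual is approximately standard
#' normal, so |d| > 1.96 marks a 95%-level deviation. Cells with zero
#' expectation or zero residual variance are stored as 0 and flagged;
#' they never enter significance classes. With `adjusted = FALSE` the
#' plain standardized residual (o - e) / sqrt(e) is computed instead, for
#' sensitivity analysis.
#'
#' Each row of the resulting matrix is the r-vector of one residue type:
#' its profile of interaction deviations against all 20 types.
#'
#' @param cfm a [ContactCounts-class] (or bare count matrix with the
#'   canonical dimnames).
#' @param adjusted use the margin-adjusted denominator (default) or plain
#'   `sqrt(e)`.
#' @return A [ResidualSpace-class] object.
#' @seealso [classifySignificance()], [decomposeSRV()]
#' @export
statisticalResiduals <- function(cfm, adjusted = TRUE) {
  o <- if (is(cfm, "ContactCounts")) contactMatrix(cfm) else as.matrix(cfm)
  if (is.null(dimnames(o)) && all(dim(o) == 20L))
    dimnames(o) <- list(aminoAcidAlphabet(), aminoAcidAlphabet())
  N <- sum(o)
  if (N <= 0) stop("all-zero contact matrix", call. = FALSE)
  r <- rowSums(o); cs <- colSums(o)
  e <- outer(r, cs) / N
  v <- if (adjusted) e * outer(1 - r / N, 1 - cs / N) else e
  flagged <- v <= 0
  d <- matrix(0, nrow(o), ncol(o), dimnames = dimnames(o))
  d[!flagged] <- (o[!flagged] - e[!flagged]) / sqrt(v[!flagged])
  new("ResidualSpace", residuals = d, expected = e, rowTotals = r,
      colTotals = cs, grandTotal = N, flagged = flagged,
      adjusted = adjusted)
}

#' Classify residuals by statistical significance
#'
#' At the 95% confidence level a cell is positively significant when its
#' residual exceeds +z (default 1.96), negatively significant below -z,
#' and irrelevant (random) in between. The inequalities are strict, so a
#' residual of exactly 1.96 is irrelevant. Flagged zero-expectation cells
#' are always irrelevant.
#'
#' @param srv a [ResidualSpace-class] or a numeric matrix of residuals.
#' @param z significance threshold (standard-normal quantile).
#' @return Character matrix with entries `"positive_significant"`,
#'   `"negative_significant"` or `"irrelevant"`.
#' @examples
#' classifySignificance(matrix(c(15.35, 0.73, -2.5, 1.96), 2, 2))
#' @export
classifySignificance <- function(srv, z = 1.96) {
  if (is(srv, "ResidualSpace")) {
    d <- residualMatrix(srv)
    flagged <- flaggedCells(srv)
  } else {
    d <- as.matrix(srv)
    flagged <- matrix(FALSE, nrow(d), ncol(d))
  }
  cls <- matrix("irrelevant", nrow(d), ncol(d), dimnames = dimnames(d))
  cls[d > z] <- "positive_significant"
  cls[d < -z] <- "negative_significant"
  cls[flagged] <- "irrelevant"
  cls
}

#' Write / read a 20 x 20 matrix as labelled TSV
#'
#' Plain-text interchange for contact matrices, residual spaces and
#' RSRVs: a header row and first column of one-letter residue codes.
#' `writeSignificanceMask` encodes a classification matrix from
#' [classifySignificance()] with the symbols `+`, `-` and `.`.
#'
#' @param m matrix to write (or for reading, the file path).
#' @param path output file path.
#' @param mask character classification matrix.
#' @return `readResidueMatrix` returns a numeric matrix with dimnames;
#'   the writers return `path` invisibly.
#' @name residueMatrixIO
#' @export
writeResidueMatrix <- function(m, path) {
  if (is(m, "ContactCounts")) m <- contactMatrix(m)
  if (is(m, "ResidualSpace")) m <- residualMatrix(m)
  df <- data.frame(residue = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname residueMatrixIO
#' @export
readResidueMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname residueMatrixIO
#' @export
writeSignificanceMask <- function(mask, path) {
  sym <- matrix(".", nrow(mask), ncol(mask), dimnames = dimnames(mask))
  sym[mask == "positive_significant"] <- "+"
  sym[mask == "negative_significant"] <- "-"
  df <- data.frame(residue = rownames(sym), sym, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
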