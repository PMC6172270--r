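#' ComplexStructure: residue sites of a two-sided protein complex
#'
#' Holds one representative coordinate per standard residue of a parsed
#' complex structure, together with the two disjoint chain groups (side A
#' and side B) between which contacts are counted.
#'
#' @slot identifier single character, e.g. the structure file stem.
#' @slot sites data.frame with one row per residue: `chain`, `resno`
#'   (author numbering), `insert` (insertion code, `""` if none), `type`
#'   (one-letter code), `x`, `y`, `z` (representative-atom coordinate in
#'   angstrom) and `side` (`"A"` or `"B"`).
#' @slot sideA,sideB character vectors of chain identifiers.
#'
#' @seealso [parseStructure()], [extractLabeledPairs()]
#' @export
setClass("ComplexStructure",
  representation(identifier = "character", sites = "data.frame",
                 sideA = "character", sideB = "character"))

setValidity("ComplexStructure", function(object) {
  msg <- character()
  if (length(intersect(object@sideA, object@sideB)))
    msg <- c(msg, "chain groups must be disjoint")
  if (!length(object@sideA) || !length(object@sideB))
    msg <- c(msg, "both chain groups must be non-empty")
  need <- c("chain", "resno", "insert", "type", "x", "y", "z", "side")
  if (!all(need %in% names(object@sites)))
    msg <- c(msg, paste("sites must have columns", paste(need, collapse = ", ")))
  else {
    if (!all(object@sites$type %in% aminoAcidAlphabet()))
      msg <- c(msg, "site types must be standard one-letter codes")
    if (!all(is.finite(c(object@sites$x, object@sites$y, object@sites$z))))
      msg <- c(msg, "representative coordinates must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' ContactCounts: 20 x 20 residue-type contact frequency matrix
#'
#' Symmetric matrix of inter-chain contact counts between residue types,
#' indexed by the canonical alphabet of [aminoAcidAlphabet()]. Each
#' unordered contact between distinct types contributes one count to both
#' symmetric cells; a same-type contact contributes one count to the
#' diagonal.
#'
#' @slot counts integer-valued 20 x 20 symmetric matrix.
#'
#' @seealso [buildContactCounts()], [statisticalResiduals()]
#' @export
setClass("ContactCounts", representation(counts = "matrix"))

setValidity("ContactCounts", function(object) {
  msg <- .checkAlphabetMatrix(object@counts, "counts")
  if (is.null(msg)) {
    if (any(object@counts < 0)) msg <- "counts must be non-negative"
    else if (!isTRUE(all.equal(object@counts, t(object@counts))))
      msg <- "counts must be symmetric"
  }
  if (is.null(msg)) TRUE else msg
})

#' ResidualSpace: adjusted standardized residuals of a contact matrix
#'
#' The statistical residual vector space (SRV). Each cell holds the
#' adjusted standardized residual of the observed contact count against
#' the expectation under row/column independence; each row is the
#' r-vector of one residue type.
#'
#' @slot residuals 20 x 20 numeric matrix of residuals.
#' @slot expected 20 x 20 numeric matrix of expected counts
#'   `r_i * c_j / N`.
#' @slot rowTotals,colTotals numeric margin totals of the source counts.
#' @slot grandTotal total count N.
#' @slot flagged logical 20 x 20 matrix marking cells whose expectation or
#'   residual variance is zero; their residual is stored as 0 and they are
#'   excluded from significance classes.
#' @slot adjusted logical; `TRUE` for the margin-adjusted residual,
#'   `FALSE` for the plain standardized residual `(o - e) / sqrt(e)`.
#'
#' @seealso [statisticalResiduals()], [classifySignificance()],
#'   [decomposeSRV()]
#' @export
setClass("ResidualSpace",
  representation(residuals = "matrix", expected = "matrix",
                 rowTotals = "numeric", colTotals = "numeric",
                 grandTotal = "numeric", flagged = "matrix",
                 adjusted = "logical"))

setValidity("ResidualSpace", function(object) {
  msg <- .checkAlphabetMatrix(object@residuals, "residuals")
  if (is.null(msg)) msg <- .checkAlphabetMatrix(object@expected, "expected")
  if (is.null(msg) && !all(is.finite(object@residuals)))
    msg <- "residuals must be finite"
  if (is.null(msg) &&
      !isTRUE(all.equal(sum(object@rowTotals), object@grandTotal)))
    msg <- "row totals must sum to the grand total"
  if (is.null(msg)) TRUE else msg
})

#' ResiduePCA: principal-component model of a residual space
#'
#' Column-mean-centered covariance eigendecomposition of the SRV, rows
#' treated as observations. No variance scaling is applied: expressing
#' all cells as standardized residuals already places them on a common
#' scale. Eigenvector signs are fixed so the largest-magnitude loading of
#' each component is positive.
#'
#' @slot center numeric 20-vector of column means.
#' @slot rotation 20 x M matrix of eigenvectors (columns, orthonormal).
#' @slot eigenvalues all 20 eigenvalues, descending.
#' @slot varianceFractions eigenvalues divided by their sum.
#' @slot nComponents number of retained components M.
#'
#' @seealso [decomposeSRV()], [projectResidues()], [reprojectPC()]
#' @export
setClass("ResiduePCA",
  representation(center = "numeric", rotation = "matrix",
                 eigenvalues = "numeric", varianceFractions = "numeric",
                 nComponents = "integer"))

setValidity("ResiduePCA", function(object) {
  msg <- character()
  M <- object@nComponents
  if (ncol(object@rotation) != M)
    msg <- c(msg, "rotation must have nComponents columns")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be sorted descending")
  g <- crossprod(object@rotation)
  if (max(abs(g - diag(ncol(g)))) > 1e-8)
    msg <- c(msg, "eigenvectors must be orthonormal")
  if (sum(object@varianceFractions[seq_len(M)]) > 1 + 1e-8)
    msg <- c(msg, "variance fractions must sum to at most 1")
  if (length(msg)) msg else TRUE
})

#' RriPredictor: extremely randomized tree ensemble over pair features
#'
#' Wraps a fitted `ranger` probability forest (extra-trees splitting, no
#' bootstrap) together with the feature dimensionality it was trained on,
#' so scoring can validate its input.
#'
#' @slot forest fitted `ranger` object.
#' @slot featureDim expected feature-vector length.
#' @slot nTrees number of trees.
#' @slot seed integer seed the forest was grown with.
#'
#' @seealso [trainPredictor()], [scorePairs()]
#' @export
setClass("RriPredictor",
  representation(forest = "ANY", featureDim = "integer",
                 nTrees = "integer", seed = "integer"))

setMethod("show", "ComplexStructure", function(object) {
  cat("ComplexStructure", object@identifier, "\n",
      " side A chains:", paste(object@sideA, collapse = ","),
      sprintf("(%d residues)", sum(object@sites$side == "A")), "\n",
      " side B chains:", paste(object@sideB, collapse = ","),
      sprintf("(%d residues)", sum(object@sites$side == "B")), "\n")
})

setMethod("show", "ContactCounts", function(object) {
  cat("ContactCounts: 20 x 20 residue-type contact matrix\n",
      " total contacts:", contactTotal(object), "\n")
})

setMethod("show", "ResidualSpace", function(object) {
  kind <- if (object@adjusted) "adjusted standardized" else "standardized"
  cat("ResidualSpace (", kind, " residuals)\n",
      " grand total N = ", object@grandTotal, "\n",
      " residual range: [", sprintf("%.2f", min(object@residuals)), ", ",
      sprintf("%.2f", max(object@residuals)), "]\n", sep = "")
})

setMethod("show", "ResiduePCA", function(object) {
  vf <- object@varianceFractions[seq_len(object@nComponents)]
  cat("ResiduePCA with", object@nComponents, "components\n",
      " variance fractions:", paste(sprintf("%.1f%%", 100 * vf),
                                    collapse = " "), "\n")
})

setMethod("show", "RriPredictor", function(object) {
  cat("RriPredictor:", object@nTrees,
      "extremely randomized trees over", object@featureDim, "features\n")
})
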