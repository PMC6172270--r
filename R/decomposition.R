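#' Principal-component decomposition of the residual space
#'
#' Treats the rows of the residual matrix (the r-vectors) as
#' observations and the columns as variables, centers each column by its
#' mean, and eigendecomposes the sample covariance (divisor n - 1). No
#' variance scaling is applied: expressing all cells as standardized
#' residuals already puts them on a common scale, which is precisely why
#' the decomposition is run on the SRV rather than on raw counts.
#'
#' Each eigenvector sign is fixed so that its largest-magnitude loading
#' is positive; equal eigenvalues keep the stable order returned by
#' [eigen()]. Because eigenvalue order and the overall sign are the only
#' arbitrary choices, comparisons against externally printed projections
#' may require a global sign flip per component.
#'
#' @param srv a [ResidualSpace-class] or a numeric matrix whose rows are
#'   observations.
#' @param nComponents number of components M to retain (default 6, which
#'   on realistic contact data captures roughly 80% of the variance).
#' @return A [ResiduePCA-class] object.
#' @examples
#' pca <- decomposeSRV(toyTriadMatrix(), nComponents = 3)
#' varianceFractions(pca)
#' @seealso [projectResidues()], [reprojectPC()]
#' @export
decomposeSRV <- function(srv, nComponents = 6) {
  x <- if (is(srv, "ResidualSpace")) residualMatrix(srv) else as.matrix(srv)
  p <- ncol(x)
  if (nComponents < 1 || nComponents > p)
    stop("nComponents must be between 1 and ", p, call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  ev <- eigen(cov(xc), symmetric = TRUE)
  lambda <- pmax(ev$values, 0)      # clip tiny negative round-off
  rot <- ev$vectors[, seq_len(nComponents), drop = FALSE]
  for (m in seq_len(ncol(rot))) {   # sign: largest |loading| positive
    j <- which.max(abs(rot[, m]))
    if (rot[j, m] < 0) rot[, m] <- -rot[, m]
  }
  rownames(rot) <- colnames(x)
  colnames(rot) <- paste0("PC", seq_len(nComponents))
  new("ResiduePCA", center = mu, rotation = rot, eigenvalues = lambda,
      varianceFractions = lambda / sum(lambda),
      nComponents = as.integer(nComponents))
}

#' Project r-vectors onto principal components
#'
#' The score of observation i on component m is the inner product of the
#' column-centered row with the m-th eigenvector:
#' t_m\[i\] = (row_i - mu) . v_m. Scores on each component sum to zero
#' because the data are centered.
#'
#' @param srv the matrix (or [ResidualSpace-class]) that was decomposed.
#' @param model a [ResiduePCA-class] from [decomposeSRV()].
#' @param pc component index (or vector of indices); defaults to all
#'   retained components.
#' @return Numeric matrix of scores (rows = observations, one column per
#'   requested component); a single requested component is returned as a
#'   named vector.
#' @examples
#' pca <- decomposeSRV(toyTriadMatrix(), nComponents = 3)
#' projectResidues(toyTriadMatrix(), pca, pc = 1)
#' @export
projectResidues <- function(srv, model, pc = seq_len(nComponents(model))) {
  stopifnot(is(model, "ResiduePCA"))
  if (any(pc < 1) || any(pc > nComponents(model)))
    stop("component index out of range", call. = FALSE)
  x <- if (is(srv, "ResidualSpace")) residualMatrix(srv) else as.matrix(srv)
  sc <- sweep(x, 2, pcaCenter(model)) %*%
    pcaRotation(model)[, pc, drop = FALSE]
  if (length(pc) == 1L) sc[, 1L] else sc
}

#' Re-project component scores back onto residue coordinates (RSRV)
#'
#' Maps the projection scores of one component back into the original
#' residue basis as the rank-1 outer product scores %o% v_m. Column
#' means are deliberately not added back: the re-projection isolates the
#' residual structure captured by that single component, and its entries
#' are read as disentangled standardized residuals.
#'
#' @param scores score vector for component `pc` (from
#'   [projectResidues()]).
#' @param model a [ResiduePCA-class].
#' @param pc index of the component the scores belong to.
#' @return Rank-1 numeric matrix (observations x original variables).
#' @examples
#' pca <- decomposeSRV(toyTriadMatrix(), nComponents = 3)
#' sc <- projectResidues(toyTriadMatrix(), pca, pc = 1)
#' reprojectPC(sc, pca, pc = 1)
#' @export
reprojectPC <- function(scores, model, pc) {
  stopifnot(is(model, "ResiduePCA"), length(pc) == 1L)
  v <- pcaRotation(model)[, pc]
  if (length(scores) == 0L)
    stop("empty score vector", call. = FALSE)
  out <- outer(as.numeric(scores), v)
  rownames(out) <- names(scores)
  out
}

#' Correlate projection scores with an external residue property scale
#'
#' Pearson correlation (with the usual t-distributed two-sided p-value)
#' between per-residue projection scores and an independently published
#' residue property scale, e.g. a hydropathy index. Residues are matched
#' by name; at least 3 shared residues are required.
#'
#' @param scores named numeric vector of projection scores.
#' @param scale named numeric vector of property values.
#' @return List with elements `r` (Pearson correlation), `p` (two-sided
#'   p-value) and `n` (number of shared residues).
#' @examples
#' ex <- hydropathyProjectionExample()
#' correlateProjectionWithScale(ex$projection, ex$hydropathy)
#' @export
correlateProjectionWithScale <- function(scores, scale) {
  shared <- intersect(names(scores), names(scale))
  if (length(shared) < 3)
    stop("need at least 3 shared residues", call. = FALSE)
  x <- scores[shared]; y <- scale[shared]
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in scores or scale", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Serialize a principal-component model to JSON
#'
#' Writes (or reads back) the column means, eigenvalues, variance
#' fractions and loadings of a [ResiduePCA-class] as plain JSON, the
#' package's interchange format for the decomposition stage.
#'
#' @param model a [ResiduePCA-class].
#' @param path file path.
#' @return `readPCAModel` returns a [ResiduePCA-class]; `writePCAModel`
#'   returns `path` invisibly.
#' @name pcaModelIO
#' @export
writePCAModel <- function(model, path) {
  stopifnot(is(model, "ResiduePCA"))
  obj <- list(center = pcaCenter(model),
              eigenvalues = pcaEigenvalues(model),
              varianceFractions = varianceFractions(model),
              nComponents = nComponents(model),
              variables = rownames(pcaRotation(model)),
              rotation = unclass(as.data.frame(pcaRotation(model))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname pcaModelIO
#' @export
readPCAModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- as.matrix(as.data.frame(obj$rotation))
  rownames(rot) <- obj$variables
  new("ResiduePCA", center = setNames(obj$center, obj$variables),
      rotation = rot, eigenvalues = obj$eigenvalues,
      varianceFractions = obj$varianceFractions,
      nComponents = as.integer(obj$nComponents))
}
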