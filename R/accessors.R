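#' Accessors for deepSRV objects
#'
#' Small extraction helpers so user code never touches slots directly.
#'
#' @param object a deepSRV S4 object (see Details).
#'
#' @details
#' * `contactMatrix(x)` — the 20 x 20 count matrix of a [ContactCounts].
#' * `contactTotal(x)` — its grand total N.
#' * `residualMatrix(x)` — the 20 x 20 residual matrix of a
#'   [ResidualSpace]; rows are r-vectors.
#' * `expectedMatrix(x)` — the expected counts under independence.
#' * `flaggedCells(x)` — logical matrix of zero-expectation cells.
#' * `pcaCenter(x)`, `pcaRotation(x)`, `pcaEigenvalues(x)`,
#'   `varianceFractions(x)`, `nComponents(x)` — components of a
#'   [ResiduePCA].
#' * `complexSites(x)` — the residue-site data.frame of a
#'   [ComplexStructure].
#'
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("contactMatrix", function(object) standardGeneric("contactMatrix"))
#' @rdname accessors
#' @export
setMethod("contactMatrix", "ContactCounts", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("contactTotal", function(object) standardGeneric("contactTotal"))
#' @rdname accessors
#' @export
setMethod("contactTotal", "ContactCounts",
          function(object) sum(object@counts))

#' @rdname accessors
#' @export
setGeneric("residualMatrix", function(object) standardGeneric("residualMatrix"))
#' @rdname accessors
#' @export
setMethod("residualMatrix", "ResidualSpace", function(object) object@residuals)

#' @rdname accessors
#' @export
setGeneric("expectedMatrix", function(object) standardGeneric("expectedMatrix"))
#' @rdname accessors
#' @export
setMethod("expectedMatrix", "ResidualSpace", function(object) object@expected)

#' @rdname accessors
#' @export
setGeneric("flaggedCells", function(object) standardGeneric("flaggedCells"))
#' @rdname accessors
#' @export
setMethod("flaggedCells", "ResidualSpace", function(object) object@flagged)

#' @rdname accessors
#' @export
setGeneric("pcaCenter", function(object) standardGeneric("pcaCenter"))
#' @rdname accessors
#' @export
setMethod("pcaCenter", "ResiduePCA", function(object) object@center)

#' @rdname accessors
#' @export
setGeneric("pcaRotation", function(object) standardGeneric("pcaRotation"))
#' @rdname accessors
#' @export
setMethod("pcaRotation", "ResiduePCA", function(object) object@rotation)

#' @rdname accessors
#' @export
setGeneric("pcaEigenvalues", function(object) standardGeneric("pcaEigenvalues"))
#' @rdname accessors
#' @export
setMethod("pcaEigenvalues", "ResiduePCA", function(object) object@eigenvalues)

#' @rdname accessors
#' @export
setGeneric("varianceFractions",
           function(object) standardGeneric("varianceFractions"))
#' @rdname accessors
#' @export
setMethod("varianceFractions", "ResiduePCA",
          function(object) object@varianceFractions)

#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setMethod("nComponents", "ResiduePCA", function(object) object@nComponents)

#' @rdname accessors
#' @export
setGeneric("complexSites", function(object) standardGeneric("complexSites"))
#' @rdname accessors
#' @export
setMethod("complexSites", "ComplexStructure", function(object) object@sites)
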