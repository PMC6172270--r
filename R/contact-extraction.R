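#' Parse a protein complex structure into residue sites
#'
#' Reads PDB ATOM records (via \pkg{bio3d}), keeps one representative atom
#' per standard residue — the C-beta, or the C-alpha for glycine — and
#' groups the residues into two sides of the interface by chain
#' identifier. HETATM records and non-standard residues (including MSE)
#' are skipped; for alternate locations the highest-occupancy copy is
#' kept (ties broken by altLoc identifier order); only the first model of
#' a multi-model file is read.
#'
#' Standard residues whose representative atom is absent (a non-glycine
#' with no C-beta) are skipped with a warning rather than given an
#' invented coordinate.
#'
#' @param pdb path to a PDB file, or an object returned by
#'   [bio3d::read.pdb()].
#' @param sideA,sideB character vectors of chain identifiers forming the
#'   two disjoint sides of the interface.
#' @param identifier label stored on the result; defaults to the file
#'   stem.
#' @return A [ComplexStructure-class] object.
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writeLines(generatePdbFixture(data.frame(
#'   chain = c("A", "B"), resno = 1:2, restype = c("A", "G"),
#'   x = c(0, 3), y = 0, z = 0)), f)
#' parseStructure(f, sideA = "A", sideB = "B")
#' @seealso [extractLabeledPairs()], [generatePdbFixture()]
#' @export
parseStructure <- function(pdb, sideA, sideB, identifier = NULL) {
  if (is.character(pdb)) {
    if (is.null(identifier))
      identifier <- sub("\\.[^.]*$", "", basename(pdb))
    pdb <- tryCatch(bio3d::read.pdb(pdb, multi = FALSE, rm.alt = FALSE,
                                    verbose = FALSE),
                    error = function(e)
                      stop("cannot parse PDB file: ", conditionMessage(e),
                           call. = FALSE))
  }
  if (is.null(identifier)) identifier <- "complex"
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("no parsable ATOM records in input", call. = FALSE)
  for (grp in list(c("A", sideA), c("B", sideB))) {
    missing <- setdiff(grp[-1], unique(atoms$chain))
    if (length(missing))
      stop("chain group ", grp[1], ": chain(s) ",
           paste(missing, collapse = ", "), " not present in structure",
           call. = FALSE)
  }
  atoms <- atoms[atoms$chain %in% c(sideA, sideB) &
                 atoms$resid %in% .AA3, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("no standard residues found on the requested chains",
         call. = FALSE)
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1

  type1 <- aminoAcidAlphabet()[match(atoms$resid, .AA3)]
  target <- ifelse(type1 == "G", "CA", "CB")
  rep_rows <- atoms[atoms$elety == target, , drop = FALSE]
  # keep highest occupancy per residue; ties by altLoc identifier order
  ord <- order(rep_rows$chain, rep_rows$resno, rep_rows$insert,
               -rep_rows$o, rep_rows$alt)
  rep_rows <- rep_rows[ord, , drop = FALSE]
  key <- paste(rep_rows$chain, rep_rows$resno, rep_rows$insert)
  rep_rows <- rep_rows[!duplicated(key), , drop = FALSE]

  all_key <- unique(paste(atoms$chain, atoms$resno, atoms$insert))
  dropped <- setdiff(all_key, paste(rep_rows$chain, rep_rows$resno,
                                    rep_rows$insert))
  if (length(dropped))
    warning(length(dropped), " residue(s) lacking a representative atom ",
            "were skipped: ", paste(head(dropped, 5), collapse = "; "),
            if (length(dropped) > 5) " ..." else "", call. = FALSE)

  sites <- data.frame(
    chain = rep_rows$chain, resno = rep_rows$resno,
    insert = rep_rows$insert,
    type = aminoAcidAlphabet()[match(rep_rows$resid, .AA3)],
    x = rep_rows$x, y = rep_rows$y, z = rep_rows$z,
    side = ifelse(rep_rows$chain %in% sideA, "A", "B"),
    stringsAsFactors = FALSE)
  sites <- sites[order(match(sites$chain, c(sideA, sideB)), sites$resno,
                       sites$insert), , drop = FALSE]
  rownames(sites) <- NULL
  new("ComplexStructure", identifier = identifier, sites = sites,
      sideA = sideA, sideB = sideB)
}

#' Representative coordinate of one residue
#'
#' C-beta for every residue type except glycine, whose side chain has no
#' beta carbon; glycine uses the C-alpha.
#'
#' @param atoms named list (or named-row matrix) of 3-vector coordinates,
#'   names being atom names such as `"CA"`, `"CB"`.
#' @param residueType one-letter residue code.
#' @return Numeric 3-vector, or `NULL` (with a warning) when the required
#'   atom is absent, which signals the caller to skip the residue.
#' @examples
#' representativeCoordinate(list(CA = c(0, 0, 0), CB = c(1, 2, 3)), "A")
#' representativeCoordinate(list(CA = c(0, 0, 0)), "G")
#' @export
representativeCoordinate <- function(atoms, residueType) {
  stopifnot(residueType %in% aminoAcidAlphabet())
  if (is.matrix(atoms))
    atoms <- setNames(lapply(seq_len(nrow(atoms)),
                             function(i) atoms[i, ]), rownames(atoms))
  target <- if (residueType == "G") "CA" else "CB"
  if (!target %in% names(atoms)) {
    warning("residue of type ", residueType, " lacks atom ", target,
            "; skipping", call. = FALSE)
    return(NULL)
  }
  as.numeric(atoms[[target]])
}

#' Label all inter-side residue pairs of a complex
#'
#' Forms every pair of residues with one member on each side of the
#' interface and labels it `positive` when the Euclidean distance between
#' the representative atoms is strictly below `threshold` (default 6
#' angstrom), `negative` otherwise. A pair at exactly the threshold is
#' negative.
#'
#' @param complex a [ComplexStructure-class].
#' @param threshold contact distance cutoff in angstrom.
#' @return data.frame with one row per pair: `chain_a`, `resno_a`,
#'   `icode_a`, `type_a`, `chain_b`, `resno_b`, `icode_b`, `type_b`,
#'   `distance`, `label` (factor, levels `positive`/`negative`). Rows are
#'   ordered side-A residue outer, side-B residue inner.
#' @seealso [buildContactCounts()]
#' @export
extractLabeledPairs <- function(complex, threshold = 6.0) {
  stopifnot(is(complex, "ComplexStructure"), threshold > 0)
  s <- complex@sites
  a <- s[s$side == "A", , drop = FALSE]
  b <- s[s$side == "B", , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("both sides of the interface must contain residues",
         call. = FALSE)
  ia <- rep(seq_len(nrow(a)), each = nrow(b))
  ib <- rep(seq_len(nrow(b)), times = nrow(a))
  d <- sqrt((a$x[ia] - b$x[ib])^2 + (a$y[ia] - b$y[ib])^2 +
            (a$z[ia] - b$z[ib])^2)
  data.frame(
    chain_a = a$chain[ia], resno_a = a$resno[ia], icode_a = a$insert[ia],
    type_a = a$type[ia],
    chain_b = b$chain[ib], resno_b = b$resno[ib], icode_b = b$insert[ib],
    type_b = b$type[ib],
    distance = d,
    label = factor(ifelse(d < threshold, "positive", "negative"),
                   levels = c("positive", "negative")),
    stringsAsFactors = FALSE)
}

#' Accumulate the residue-type contact frequency matrix
#'
#' Counts the residue-type composition of positive (contact) pairs from
#' one or more complexes into a symmetric 20 x 20 matrix. By default each
#' unordered contact between distinct types adds 1 to both symmetric
#' cells and a same-type contact adds 1 to the diagonal; with
#' `diagonalDouble = TRUE` same-type contacts add 2 instead, so every row
#' sum counts residue participations (the other common contingency-table
#' convention).
#'
#' @param pairs data.frame with columns `type_a` and `type_b`; if a
#'   `label` column is present, all rows must be `positive`.
#' @param diagonalDouble count same-type contacts twice on the diagonal.
#' @return A [ContactCounts-class] object. An empty input yields the zero
#'   matrix.
#' @examples
#' p <- data.frame(type_a = c("R", "D"), type_b = c("D", "R"))
#' contactMatrix(buildContactCounts(p))["R", "D"]
#' @export
buildContactCounts <- function(pairs, diagonalDouble = FALSE) {
  if (!is.null(pairs$label) && any(pairs$label != "positive"))
    stop("contact counting expects positive (contact) pairs only",
         call. = FALSE)
  aa <- aminoAcidAlphabet()
  stopifnot(all(pairs$type_a %in% aa), all(pairs$type_b %in% aa))
  counts <- .emptyCountMatrix()
  if (nrow(pairs)) {
    tab <- table(factor(pairs$type_a, levels = aa),
                 factor(pairs$type_b, levels = aa))
    m <- matrix(as.integer(tab), 20L, 20L, dimnames = list(aa, aa))
    counts <- m + t(m)          # mirrors off-diagonal; doubles diagonal
    if (!diagonalDouble) diag(counts) <- diag(counts) / 2L
    storage.mode(counts) <- "integer"
  }
  new("ContactCounts", counts = counts)
}
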