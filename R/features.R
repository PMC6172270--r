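#' Extract the windowed sequence context of a residue pair
#'
#' Cuts a window of `2k + 1` letters centered on position `i` of
#' sequence A and on position `j` of sequence B. Positions past either
#' terminus are filled with the pad symbol `"-"`, which contributes
#' all-zero features downstream. Letters outside the 20-letter alphabet
#' (e.g. `X`) are replaced by the pad symbol with a warning.
#'
#' @param seqA,seqB residue strings (plain character scalars).
#' @param i,j 1-based center positions on A and B.
#' @param k number of neighbours on each side (k >= 0).
#' @return List with elements `windowA`, `windowB` (character vectors of
#'   length 2k + 1), `i`, `j`, `k`.
#' @examples
#' extractContext("PVKAAFV", 4, "ITLVAFE", 4, k = 3)$windowA
#' @export
extractContext <- function(seqA, i, seqB, j, k = 3) {
  stopifnot(k >= 0)
  la <- strsplit(seqA, "")[[1]]
  lb <- strsplit(seqB, "")[[1]]
  if (i < 1 || i > length(la) || j < 1 || j > length(lb))
    stop("center position out of sequence bounds", call. = FALSE)
  win <- function(letters, center) {
    pos <- center + (-k:k)
    w <- rep(.PAD, 2 * k + 1)
    ok <- pos >= 1 & pos <= length(letters)
    w[ok] <- letters[pos[ok]]
    bad <- ok & !w %in% c(aminoAcidAlphabet(), .PAD)
    if (any(bad)) {
      warning("non-standard letter(s) ",
              paste(unique(w[bad]), collapse = ","),
              " treated as pad", call. = FALSE)
      w[bad] <- .PAD
    }
    w
  }
  list(windowA = win(la, i), windowB = win(lb, j), i = i, j = j, k = k)
}

#' Bundle the deep-knowledge statistics needed for feature construction
#'
#' Convenience wrapper running [decomposeSRV()], [projectResidues()] and
#' [reprojectPC()] on a residual space: the per-residue projection
#' scores on the top components and the per-component re-projected
#' residual matrices (RSRVs) are exactly the quantities the feature
#' encoder consumes.
#'
#' @param srv a [ResidualSpace-class].
#' @param nComponents number of components (default 6).
#' @return List with elements `model` ([ResiduePCA-class]), `scores`
#'   (20 x M matrix) and `rsrvs` (list of M rank-1 20 x 20 matrices).
#' @export
deepKnowledge <- function(srv, nComponents = 6) {
  model <- decomposeSRV(srv, nComponents = nComponents)
  scores <- projectResidues(srv, model)
  if (is.null(dim(scores)))
    scores <- matrix(scores, ncol = 1,
                     dimnames = list(names(scores), "PC1"))
  rsrvs <- lapply(seq_len(nComponents), function(m)
    reprojectPC(scores[, m], model, m))
  list(model = model, scores = scores, rsrvs = rsrvs)
}

# augmented lookup tables: row/col 21 is the pad symbol, all zeros
.augScores <- function(scores) {
  rbind(scores, matrix(0, 1, ncol(scores)))
}

.augPairTable <- function(rsrv, symmetricAverage = TRUE) {
  s <- if (symmetricAverage) (rsrv + t(rsrv)) / 2 else rsrv
  out <- matrix(0, 21, 21)
  out[1:20, 1:20] <- s
  out
}

.letterIndex <- function(letters) {
  idx <- match(letters, aminoAcidAlphabet())
  idx[is.na(idx)] <- 21L
  idx
}

#' Assemble the feature vector of one residue-pair context
#'
#' Encodes a windowed residue pair as a numeric vector of length
#' `18 (2k + 1)` (with 6 components): first, for every window residue
#' (side A left to right, then side B left to right), its projection
#' score on each component; second, for each of the `2k + 1` aligned
#' residue pairs, the averaged re-projected residual on each component.
#' Aligned pairs run window A left-to-right against window B
#' right-to-left, so the two centers always pair with each other and
#' neighbours pair across the interface the way two chain segments face
#' one another. Pad positions contribute zeros.
#'
#' By default the re-projected residual of a pair (a, b) is the
#' symmetric average `(RSRV[a,b] + RSRV[b,a]) / 2`, since re-projected
#' matrices are not exactly symmetric after centering;
#' `symmetricAverage = FALSE` uses the ordered entry `RSRV[a,b]` with a
#' on side A.
#'
#' @param context a context from [extractContext()].
#' @param knowledge deep-knowledge bundle from [deepKnowledge()] (or a
#'   list with elements `scores` and `rsrvs`).
#' @param symmetricAverage see Details.
#' @return Named numeric vector of length `3 M (2k + 1)`.
#' @examples
#' cfm <- buildContactCounts(data.frame(type_a = "R", type_b = "D"))
#' @export
assembleFeatureVector <- function(context, knowledge,
                                  symmetricAverage = TRUE) {
  scores <- knowledge$scores
  rsrvs <- knowledge$rsrvs
  M <- ncol(scores)
  if (length(rsrvs) < M)
    stop("re-projected matrices must cover all ", M, " components",
         call. = FALSE)
  w <- 2 * context$k + 1
  sA <- .augScores(scores)
  pairTabs <- lapply(rsrvs[seq_len(M)], .augPairTable,
                     symmetricAverage = symmetricAverage)
  ia <- .letterIndex(context$windowA)
  ib <- .letterIndex(context$windowB)
  blockRes <- function(idx, side) {
    vals <- as.numeric(t(sA[idx, , drop = FALSE]))  # residue-major
    names(vals) <- paste0(side, rep(seq_len(w), each = M),
                          "_PC", rep(seq_len(M), w))
    vals
  }
  # aligned pairs: A position p against B position w + 1 - p
  pairVals <- numeric(w * M)
  for (p in seq_len(w)) {
    a <- ia[p]; b <- ib[w + 1 - p]
    pairVals[(p - 1) * M + seq_len(M)] <-
      vapply(pairTabs, function(tab) tab[a, b], numeric(1))
  }
  names(pairVals) <- paste0("pair", rep(seq_len(w), each = M),
                            "_PC", rep(seq_len(M), w))
  c(blockRes(ia, "A"), blockRes(ib, "B"), pairVals)
}

#' Enumerate all candidate residue pairs between two sequences
#'
#' Every position of sequence A paired with every position of sequence
#' B, in row-major order (A position outer, B position inner) — the
#' order in which predictions are reported.
#'
#' @param seqA,seqB residue strings.
#' @param k neighbour count carried along for feature construction.
#' @return data.frame with columns `i`, `j`, `type_a`, `type_b` and
#'   attribute `k`.
#' @examples
#' nrow(enumerateCandidates("ACD", "WXYZ"))  # 12
#' @export
enumerateCandidates <- function(seqA, seqB, k = 3) {
  la <- strsplit(seqA, "")[[1]]
  lb <- strsplit(seqB, "")[[1]]
  if (!length(la) || !length(lb))
    stop("sequences must be non-empty", call. = FALSE)
  out <- data.frame(
    i = rep(seq_along(la), each = length(lb)),
    j = rep(seq_along(lb), times = length(la)))
  out$type_a <- la[out$i]
  out$type_b <- lb[out$j]
  attr(out, "k") <- k
  out
}

#' Encode many residue pairs as a feature matrix
#'
#' Vectorized equivalent of calling [extractContext()] +
#' [assembleFeatureVector()] for each pair; identical output, orders of
#' magnitude faster for the |A| x |B| candidate sets of whole-chain
#' prediction.
#'
#' @param seqA,seqB residue strings.
#' @param pairs data.frame with columns `i` and `j` (defaults to all
#'   pairs from [enumerateCandidates()]).
#' @param knowledge deep-knowledge bundle from [deepKnowledge()].
#' @param k neighbours per side.
#' @param symmetricAverage see [assembleFeatureVector()].
#' @return Numeric matrix, one row per pair, `3 M (2k + 1)` columns.
#' @export
featurizePairs <- function(seqA, seqB, pairs = NULL, knowledge, k = 3,
                           symmetricAverage = TRUE) {
  if (is.null(pairs)) pairs <- enumerateCandidates(seqA, seqB, k)
  la <- strsplit(seqA, "")[[1]]
  lb <- strsplit(seqB, "")[[1]]
  scores <- knowledge$scores
  M <- ncol(scores)
  w <- 2L * k + 1L
  sA <- .augScores(scores)
  pairTabs <- lapply(knowledge$rsrvs[seq_len(M)], .augPairTable,
                     symmetricAverage = symmetricAverage)
  # window letter-index matrices: row = position, col = window slot
  winIdx <- function(letters) {
    pos <- outer(seq_along(letters), -k:k, "+")
    idx <- matrix(21L, nrow(pos), ncol(pos))
    ok <- pos >= 1 & pos <= length(letters)
    idx[ok] <- .letterIndex(letters[pos[ok]])
    idx
  }
  IA <- winIdx(la); IB <- winIdx(lb)
  n <- nrow(pairs)
  d <- 3L * M * w
  out <- matrix(0, n, d)
  ii <- pairs$i; jj <- pairs$j
  for (p in seq_len(w)) {
    colsA <- (p - 1L) * M + seq_len(M)
    colsB <- M * w + colsA
    colsP <- 2L * M * w + colsA
    out[, colsA] <- sA[IA[ii, p], , drop = FALSE]
    out[, colsB] <- sA[IB[jj, p], , drop = FALSE]
    aIdx <- IA[ii, p]
    bIdx <- IB[jj, w + 1L - p]
    for (m in seq_len(M))
      out[, colsP[m]] <- pairTabs[[m]][cbind(aIdx, bIdx)]
  }
  colnames(out) <- c(
    paste0("A", rep(seq_len(w), each = M), "_PC", rep(seq_len(M), w)),
    paste0("B", rep(seq_len(w), each = M), "_PC", rep(seq_len(M), w)),
    paste0("pair", rep(seq_len(w), each = M), "_PC", rep(seq_len(M), w)))
  out
}
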