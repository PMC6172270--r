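#' Three-point worked-example matrix
#'
#' A symmetric 3 x 3 matrix whose rows s1, s2, s3 are three points in a
#' 3-dimensional space. It is small enough to follow the whole
#' projection / re-projection machinery by hand: decomposing it with
#' [decomposeSRV()] and projecting with [projectResidues()] gives PC1
#' scores (4.16, 3.19, -7.35) and re-projecting gives s3 coordinates
#' (5.30, 3.62, -3.58) (2 decimals, sign fixed so s1's score is
#' positive).
#'
#' @return Symmetric numeric 3 x 3 matrix with dimnames s1..s3.
#' @examples
#' A <- toyTriadMatrix()
#' pca <- decomposeSRV(A, nComponents = 3)
#' round(projectResidues(A, pca, pc = 1), 2)
#' @export
toyTriadMatrix <- function() {
  m <- rbind(c(-2.47, -3.72, 4.98),
             c(-3.72, -2.69, 2.19),
             c(4.98, 2.19, -1.64))
  dimnames(m) <- list(c("s1", "s2", "s3"), c("s1", "s2", "s3"))
  m
}

#' Hydropathy versus PC1 projection example
#'
#' Ten residues with their Kyte-Doolittle hydropathy index alongside
#' first-component projection scores obtained from a large residue
#' contact analysis. The strong negative correlation between the two is
#' the canonical sanity check that the leading component of a contact
#' residual space captures hydrophobicity.
#'
#' @return List with named numeric vectors `hydropathy` and
#'   `projection`.
#' @examples
#' ex <- hydropathyProjectionExample()
#' correlateProjectionWithScale(ex$projection, ex$hydropathy)
#' @export
hydropathyProjectionExample <- function() {
  res <- c("I", "V", "L", "F", "M", "A", "T", "S", "D", "N")
  list(
    hydropathy = setNames(
      c(4.5, 4.2, 3.8, 2.8, 1.9, 1.8, -0.7, -0.8, -3.5, -3.5), res),
    projection = setNames(
      c(-6.77, -7.89, -10.07, -6.21, -5.69, -4.47,
        6.91, 7.91, 10.08, 8.20), res))
}

#' Planted residue-type interaction preference model
#'
#' A synthetic generative model of interfaces: each candidate residue
#' pair (a, b) is a contact with probability
#' `min(1, baseRate * factor[a, b])`, where the symmetric factor matrix
#' plants multiplicative preferences between residue types. The default
#' factors emulate the broad structure seen in real contact statistics:
#' enriched pairings within the hydrophobic group (L, V, I, F, M, A),
#' within the polar group (S, T, N, D), across opposite charges
#' ((R, K) x (D, E)) and for C-C disulfide-like contacts, and depleted
#' same-charge pairings.
#'
#' @param factors optional symmetric 20 x 20 matrix of enrichment
#'   factors; defaults as described.
#' @param baseRate baseline contact probability per candidate pair.
#' @param enrich,deplete factor values used when building the default
#'   matrix.
#' @return List of class `PlantedPreferenceModel` with elements
#'   `factors` and `baseRate`.
#' @seealso [generateComplex()], [sampleContacts()]
#' @export
plantedPreferenceModel <- function(factors = NULL, baseRate = 0.02,
                                   enrich = 8, deplete = 0.1) {
  aa <- aminoAcidAlphabet()
  if (is.null(factors)) {
    factors <- matrix(1, 20, 20, dimnames = list(aa, aa))
    hydrophobic <- c("L", "V", "I", "F", "M", "A")
    polar <- c("S", "T", "N", "D")
    posCharged <- c("R", "K"); negCharged <- c("D", "E")
    factors[hydrophobic, hydrophobic] <- enrich
    factors[polar, polar] <- enrich
    factors[posCharged, negCharged] <- enrich
    factors[negCharged, posCharged] <- enrich
    factors["C", "C"] <- enrich
    factors[posCharged, posCharged] <- deplete
  }
  stopifnot(isTRUE(all.equal(factors, t(factors))),
            all(is.finite(factors)), all(factors >= 0),
            baseRate > 0, baseRate <= 1)
  structure(list(factors = factors, baseRate = baseRate),
            class = "PlantedPreferenceModel")
}

#' Draw contact type-pairs directly from a preference model
#'
#' Samples `n` unordered residue-type contacts with probability
#' proportional to the model's factor matrix (uniform type marginals
#' otherwise). This bypasses sequences and geometry entirely — it is the
#' fast path for studying how many contacts the residual space needs
#' before planted preferences become statistically significant.
#'
#' @param model a [plantedPreferenceModel()].
#' @param n number of contacts.
#' @param seed integer seed.
#' @return data.frame with columns `type_a`, `type_b`, ready for
#'   [buildContactCounts()].
#' @export
sampleContacts <- function(model, n, seed = 1) {
  stopifnot(inherits(model, "PlantedPreferenceModel"))
  aa <- aminoAcidAlphabet()
  w <- model$factors / sum(model$factors)
  set.seed(seed)
  cell <- sample.int(400L, n, replace = TRUE, prob = as.numeric(w))
  data.frame(type_a = aa[(cell - 1L) %% 20L + 1L],
             type_b = aa[(cell - 1L) %/% 20L + 1L],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic two-chain complex with planted preferences
#'
#' Draws two random sequences and labels every cross-chain residue pair
#' positive with probability `baseRate * factor[a, b]` (clipped to
#' \[0, 1\], with a message when clipping occurs). In the default
#' label mode, labels are assigned directly, which is fast and makes the
#' planted signal exact; `geometric = TRUE` instead places the residues
#' in 3-D (side A on a jittered grid near the origin, side B on a
#' jittered grid offset so that roughly `baseRate` of pairs fall below
#' the distance threshold) and derives labels from distances, which
#' exercises the contact-extraction code end to end (factors are
#' ignored in that mode).
#'
#' @param nA,nB chain lengths.
#' @param model a [plantedPreferenceModel()].
#' @param seed integer seed; identical seeds give identical complexes.
#' @param geometric derive labels from 3-D coordinates instead of
#'   planted probabilities.
#' @param threshold contact threshold used in geometric mode.
#' @return List with `seqA`, `seqB`, `pairs` (data.frame `i`, `j`,
#'   `type_a`, `type_b`, `distance` (NA in label mode), `label`) and
#'   `id`.
#' @export
generateComplex <- function(nA, nB, model = plantedPreferenceModel(),
                            seed = 1, geometric = FALSE,
                            threshold = 6.0) {
  stopifnot(nA >= 1, nB >= 1,
            inherits(model, "PlantedPreferenceModel"))
  aa <- aminoAcidAlphabet()
  set.seed(seed)
  la <- sample(aa, nA, replace = TRUE)
  lb <- sample(aa, nB, replace = TRUE)
  pairs <- data.frame(
    i = rep(seq_len(nA), each = nB),
    j = rep(seq_len(nB), times = nA))
  pairs$type_a <- la[pairs$i]
  pairs$type_b <- lb[pairs$j]
  if (geometric) {
    sites <- data.frame(
      chain = rep(c("A", "B"), c(nA, nB)),
      resno = c(seq_len(nA), seq_len(nB)),
      insert = "",
      type = c(la, lb),
      x = c(3 * seq_len(nA), 3 * seq_len(nB)) + runif(nA + nB, -1, 1),
      y = c(rep(0, nA), rep(4, nB)) + runif(nA + nB, -1, 1),
      z = runif(nA + nB, -1, 1),
      side = rep(c("A", "B"), c(nA, nB)),
      stringsAsFactors = FALSE)
    cx <- new("ComplexStructure", identifier = paste0("synth", seed),
              sites = sites, sideA = "A", sideB = "B")
    lp <- extractLabeledPairs(cx, threshold = threshold)
    pairs$distance <- lp$distance
    pairs$label <- lp$label
  } else {
    pr <- model$baseRate * model$factors[cbind(pairs$type_a,
                                               pairs$type_b)]
    if (any(pr > 1)) {
      message(sum(pr > 1), " pair probabilities clipped to 1")
      pr <- pmin(pr, 1)
    }
    pairs$distance <- NA_real_
    pairs$label <- factor(
      ifelse(rbinom(nrow(pairs), 1L, pr) == 1L, "positive", "negative"),
      levels = c("positive", "negative"))
  }
  list(seqA = paste(la, collapse = ""), seqB = paste(lb, collapse = ""),
       pairs = pairs, id = paste0("synth", seed))
}

#' Emit a minimal PDB fixture with specified representative atoms
#'
#' Writes fixed-column ATOM records placing one representative atom per
#' residue — a C-beta, or a C-alpha for glycine — at the stated
#' coordinates, so the geometry of the resulting file is known exactly.
#' The text round-trips through [parseStructure()] losslessly to the
#' 0.001-angstrom precision of the PDB coordinate columns.
#'
#' @param sites data.frame with columns `chain`, `resno`, `restype`
#'   (one-letter), `x`, `y`, `z`, and optionally `icode`, `occupancy`,
#'   `altLoc`.
#' @return Character vector of PDB lines (including `END`).
#' @examples
#' generatePdbFixture(data.frame(chain = "A", resno = 1, restype = "G",
#'                               x = 0, y = 0, z = 0))
#' @export
generatePdbFixture <- function(sites) {
  stopifnot(all(c("chain", "resno", "restype", "x", "y", "z") %in%
                names(sites)),
            all(sites$restype %in% aminoAcidAlphabet()),
            all(is.finite(c(sites$x, sites$y, sites$z))))
  icode <- if (is.null(sites$icode)) rep("", nrow(sites)) else sites$icode
  occ <- if (is.null(sites$occupancy)) rep(1, nrow(sites)) else
    sites$occupancy
  alt <- if (is.null(sites$altLoc)) rep("", nrow(sites)) else sites$altLoc
  res3 <- .AA3[match(sites$restype, aminoAcidAlphabet())]
  atom <- ifelse(sites$restype == "G", "CA", "CB")
  lines <- sprintf(
    "ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(sites)), atom, alt, res3, sites$chain, sites$resno,
    icode, sites$x, sites$y, sites$z, occ, 0)
  c(lines, "END")
}
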