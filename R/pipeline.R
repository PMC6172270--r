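#' Read one protein sequence from a FASTA file
#'
#' @param path FASTA file; the first record is used (a message notes
#'   when more are present).
#' @return Character scalar sequence.
#' @export
readFastaSequence <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  if (length(s) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  if (length(s) > 1L)
    message(path, ": ", length(s), " records; using the first")
  as.character(s[[1]])
}

#' Write labelled residue pairs as TSV
#'
#' @param pairs data.frame from [extractLabeledPairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLabeledPairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with defaults matching the
#' method's standard settings: 3 neighbours per side, 6 principal
#' components, 1000 trees, 6-angstrom contact threshold and the 1.96
#' significance level. Validation reports every offending field at
#' once.
#'
#' @param neighbors window neighbours per side (k).
#' @param nComponents retained principal components (M).
#' @param nTrees trees in the ensemble.
#' @param seed master integer seed.
#' @param threshold contact distance cutoff, angstrom.
#' @param z significance threshold on residuals.
#' @param paths named list of stage paths (`complexList`, `outDir`,
#'   `modelDir`, `fastaA`, `fastaB`, `outFile`, `top` as used by the
#'   stage being run).
#' @return List of class `RunConfig`.
#' @seealso [runPipeline()]
#' @export
runConfig <- function(neighbors = 3, nComponents = 6, nTrees = 1000,
                      seed = 1, threshold = 6.0, z = 1.96,
                      paths = list()) {
  cfg <- list(neighbors = neighbors, nComponents = nComponents,
              nTrees = nTrees, seed = seed, threshold = threshold,
              z = z, paths = paths)
  bad <- character()
  chk <- function(ok, msg) if (!ok) bad <<- c(bad, msg)
  chk(is.numeric(neighbors) && neighbors >= 0 &&
        neighbors == round(neighbors), "neighbors: non-negative integer")
  chk(is.numeric(nComponents) && nComponents >= 1 && nComponents <= 20,
      "nComponents: integer in [1, 20]")
  chk(is.numeric(nTrees) && nTrees >= 1, "nTrees: positive integer")
  chk(is.numeric(seed) && seed == round(seed), "seed: integer")
  chk(is.numeric(threshold) && threshold > 0, "threshold: positive")
  chk(is.numeric(z) && z > 0, "z: positive")
  chk(is.list(paths), "paths: named list")
  if (length(bad))
    stop("invalid configuration: ", paste(bad, collapse = "; "),
         call. = FALSE)
  structure(cfg, class = "RunConfig")
}

#' @export
print.RunConfig <- function(x, ...) {
  cat(sprintf(
    "RunConfig: k=%d, M=%d, trees=%d, seed=%d, threshold=%.1f A, z=%.2f\n",
    x$neighbors, x$nComponents, x$nTrees, x$seed, x$threshold, x$z))
  invisible(x)
}

.configHash <- function(config) {
  core <- config[c("neighbors", "nComponents", "nTrees", "seed",
                   "threshold", "z")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(core, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.writeManifest <- function(config, command, dir, artifacts) {
  manifest <- list(command = command,
                   configHash = .configHash(config),
                   seed = config$seed,
                   parameters = config[c("neighbors", "nComponents",
                                         "nTrees", "threshold", "z")],
                   artifacts = artifacts)
  path <- file.path(dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

.checkManifest <- function(dir, command, config) {
  path <- file.path(dir, paste0("manifest_", command, ".json"))
  if (!file.exists(path)) return(invisible(NULL))
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(manifest$configHash, unname(.configHash(config))))
    warning("artifacts in ", dir, " were produced under a different ",
            "configuration (stale cache)", call. = FALSE)
  invisible(manifest)
}

.readComplexList <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pdb", "sideA", "sideB")
  if (!all(need %in% names(df)))
    stop("complex list must have columns pdb, sideA, sideB",
         call. = FALSE)
  base <- dirname(path)
  df$pdb <- ifelse(file.exists(df$pdb), df$pdb, file.path(base, df$pdb))
  missing <- df$pdb[!file.exists(df$pdb)]
  if (length(missing))
    stop("missing structure file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}

# turn a parsed complex into the per-complex unit used for training and
# evaluation: side sequences in site order plus labelled (i, j) pairs
.complexToUnit <- function(cx, threshold) {
  s <- complexSites(cx)
  a <- s[s$side == "A", , drop = FALSE]
  b <- s[s$side == "B", , drop = FALSE]
  lp <- extractLabeledPairs(cx, threshold = threshold)
  keyA <- paste(a$chain, a$resno, a$insert)
  keyB <- paste(b$chain, b$resno, b$insert)
  pairs <- data.frame(
    i = match(paste(lp$chain_a, lp$resno_a, lp$icode_a), keyA),
    j = match(paste(lp$chain_b, lp$resno_b, lp$icode_b), keyB),
    type_a = lp$type_a, type_b = lp$type_b,
    distance = lp$distance, label = lp$label,
    stringsAsFactors = FALSE)
  list(seqA = paste(a$type, collapse = ""),
       seqB = paste(b$type, collapse = ""),
       pairs = pairs, id = cx@identifier)
}

#' Run one pipeline stage
#'
#' Wires the package's stages into reproducible commands. Every stage
#' writes its artifacts plus a manifest recording the configuration
#' hash and seed; a stage that consumes another stage's directory warns
#' when the hashes disagree (stale cache).
#'
#' Stages:
#' \describe{
#'   \item{`build-matrix`}{parse the complexes listed in
#'     `paths$complexList` (TSV: `pdb`, `sideA`, `sideB`; multi-chain
#'     sides separated by `+`), label all inter-side pairs, and write
#'     the pooled labelled pairs and the contact frequency matrix to
#'     `paths$outDir`.}
#'   \item{`decompose`}{read `paths$outDir/cfm.tsv` (or a matrix given
#'     as `paths$cfm`), write the residual space, significance mask,
#'     principal-component model (JSON), projection table and one RSRV
#'     TSV per component.}
#'   \item{`train`}{build deep knowledge and pair features from all
#'     listed complexes and fit the tree ensemble; model and knowledge
#'     are stored under `paths$outDir`.}
#'   \item{`predict`}{score all residue pairs between `paths$fastaA`
#'     and `paths$fastaB` with the model in `paths$modelDir` and write
#'     the top `paths$top` predictions (TSV: `pos_a`, `res_a`, `pos_b`,
#'     `res_b`, `score`, `rank`) to `paths$outFile`.}
#'   \item{`evaluate`}{leave-one-complex-out evaluation over the listed
#'     complexes; the per-complex AUC table and summary are written to
#'     `paths$outDir`.}
#' }
#'
#' @param config a [runConfig()].
#' @param command one of `"build-matrix"`, `"decompose"`, `"train"`,
#'   `"predict"`, `"evaluate"`.
#' @return Invisibly, a list of produced artifact paths (and for
#'   `evaluate`, the report).
#' @export
runPipeline <- function(config,
                        command = c("build-matrix", "decompose",
                                    "train", "predict", "evaluate")) {
  stopifnot(inherits(config, "RunConfig"))
  command <- match.arg(command)
  p <- config$paths
  needPath <- function(field) {
    if (is.null(p[[field]]))
      stop("config paths$", field, " is required for ", command,
           call. = FALSE)
    p[[field]]
  }
  splitChains <- function(x) strsplit(x, "+", fixed = TRUE)[[1]]

  if (command %in% c("build-matrix", "train", "evaluate")) {
    lst <- .readComplexList(needPath("complexList"))
    units <- lapply(seq_len(nrow(lst)), function(r) {
      cx <- parseStructure(lst$pdb[r], splitChains(lst$sideA[r]),
                           splitChains(lst$sideB[r]))
      .complexToUnit(cx, threshold = config$threshold)
    })
  }

  if (command == "build-matrix") {
    out <- needPath("outDir")
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    allPairs <- do.call(rbind, lapply(units, function(u)
      cbind(id = u$id, u$pairs)))
    cfm <- buildContactCounts(
      allPairs[allPairs$label == "positive", c("type_a", "type_b")])
    art <- list(pairs = file.path(out, "pairs.tsv"),
                cfm = file.path(out, "cfm.tsv"))
    writeLabeledPairs(allPairs, art$pairs)
    writeResidueMatrix(cfm, art$cfm)
    art$manifest <- .writeManifest(config, command, out, art)
    return(invisible(art))
  }

  if (command == "decompose") {
    out <- needPath("outDir")
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    cfmPath <- if (!is.null(p$cfm)) p$cfm else file.path(out, "cfm.tsv")
    .checkManifest(out, "build-matrix", config)
    m <- readResidueMatrix(cfmPath)
    isToy <- !identical(rownames(m), aminoAcidAlphabet())
    srv <- if (isToy) m else statisticalResiduals(m)
    M <- min(config$nComponents, ncol(m))
    kn <- deepKnowledge(srv, nComponents = M)
    art <- list(model = file.path(out, "model.json"),
                projections = file.path(out, "projections.tsv"))
    if (!isToy) {
      art$srv <- writeResidueMatrix(srv, file.path(out, "srv.tsv"))
      art$mask <- writeSignificanceMask(
        classifySignificance(srv, z = config$z),
        file.path(out, "mask.tsv"))
    }
    writePCAModel(kn$model, art$model)
    dfp <- data.frame(residue = rownames(kn$scores), kn$scores,
                      check.names = FALSE)
    write.table(dfp, art$projections, sep = "\t", quote = FALSE,
                row.names = FALSE)
    for (m_i in seq_len(M)) {
      f <- file.path(out, sprintf("rsrv_PC%d.tsv", m_i))
      rs <- kn$rsrvs[[m_i]]
      write.table(data.frame(residue = rownames(kn$scores), rs,
                             check.names = FALSE),
                  f, sep = "\t", quote = FALSE, row.names = FALSE)
      art[[sprintf("rsrv_PC%d", m_i)]] <- f
    }
    art$manifest <- .writeManifest(config, command, out, art)
    return(invisible(art))
  }

  if (command == "train") {
    out <- needPath("outDir")
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    posTypes <- do.call(rbind, lapply(units, function(u)
      u$pairs[u$pairs$label == "positive", c("type_a", "type_b")]))
    cfm <- buildContactCounts(posTypes)
    kn <- deepKnowledge(statisticalResiduals(cfm),
                        nComponents = config$nComponents)
    xs <- lapply(units, function(u)
      featurizePairs(u$seqA, u$seqB, u$pairs, kn, k = config$neighbors))
    ys <- unlist(lapply(units, function(u) as.character(u$pairs$label)))
    model <- trainPredictor(do.call(rbind, xs), ys,
                            nTrees = config$nTrees, seed = config$seed)
    art <- list(cfm = writeResidueMatrix(cfm, file.path(out, "cfm.tsv")),
                modelJson = writePCAModel(kn$model,
                                          file.path(out, "model.json")),
                predictor = file.path(out, "predictor.rds"),
                knowledge = file.path(out, "knowledge.rds"))
    saveRDS(model, art$predictor)
    saveRDS(kn, art$knowledge)
    art$manifest <- .writeManifest(config, command, out, art)
    return(invisible(art))
  }

  if (command == "predict") {
    modelDir <- needPath("modelDir")
    .checkManifest(modelDir, "train", config)
    model <- readRDS(file.path(modelDir, "predictor.rds"))
    kn <- readRDS(file.path(modelDir, "knowledge.rds"))
    seqA <- readFastaSequence(needPath("fastaA"))
    seqB <- readFastaSequence(needPath("fastaB"))
    top <- if (is.null(p$top)) 5L else as.integer(p$top)
    cand <- enumerateCandidates(seqA, seqB, k = config$neighbors)
    x <- featurizePairs(seqA, seqB, cand, kn, k = config$neighbors)
    sc <- scorePairs(model, x)
    keep <- rankTopN(sc, top)
    pred <- data.frame(pos_a = cand$i, res_a = cand$type_a,
                       pos_b = cand$j, res_b = cand$type_b,
                       score = sc)[keep, , drop = FALSE]
    pred <- pred[order(-pred$score), , drop = FALSE]
    pred$rank <- seq_len(nrow(pred))
    outFile <- needPath("outFile")
    write.table(pred, outFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(list(predictions = outFile)))
  }

  # evaluate
  out <- needPath("outDir")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- leaveOneComplexOut(units, k = config$neighbors,
                               nComponents = config$nComponents,
                               nTrees = config$nTrees,
                               seed = config$seed)
  art <- list(perComplex = file.path(out, "loco_auc.tsv"))
  write.table(report$perComplex, art$perComplex, sep = "\t",
              quote = FALSE, row.names = FALSE)
  summaryPath <- file.path(out, "loco_summary.json")
  jsonlite::write_json(list(meanAUC = report$meanAUC,
                            sdAUC = report$sdAUC, seAUC = report$seAUC),
                       summaryPath, auto_unbox = TRUE, digits = NA)
  art$summary <- summaryPath
  art$manifest <- .writeManifest(config, command, out, art)
  invisible(c(art, list(report = report)))
}
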