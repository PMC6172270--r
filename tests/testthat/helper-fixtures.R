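# shared fixtures and independent oracles

# independent adjusted-residual oracle: explicit cell-by-cell arithmetic,
# no shared code with statisticalResiduals()
adjResidualOracle <- function(o) {
  N <- sum(o)
  r <- rowSums(o)
  cs <- colSums(o)
  d <- matrix(0, nrow(o), ncol(o), dimnames = dimnames(o))
  for (i in seq_len(nrow(o))) {
    for (j in seq_len(ncol(o))) {
      e <- r[i] * cs[j] / N
      v <- e * (1 - r[i] / N) * (1 - cs[j] / N)
      if (v > 0) d[i, j] <- (o[i, j] - e) / sqrt(v)
    }
  }
  d
}

# independent PCA oracle: singular-value decomposition of the centered
# matrix (decomposeSRV uses eigen of the covariance instead)
svdOracle <- function(x, nComponents = ncol(x)) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  list(eigenvalues = sv$d^2 / (nrow(x) - 1),
       rotation = sv$v[, seq_len(nComponents), drop = FALSE],
       scores = (sv$u %*% diag(sv$d, length(sv$d)))[,
         seq_len(nComponents), drop = FALSE])
}

# random symmetric 20 x 20 matrix with canonical dimnames
randomSRVMatrix <- function(seed = 1) {
  aa <- aminoAcidAlphabet()
  set.seed(seed)
  m <- matrix(rnorm(400), 20, 20)
  m <- (m + t(m)) / 2
  dimnames(m) <- list(aa, aa)
  m
}

# random symmetric count matrix (as a plausible contact table)
randomCountMatrix <- function(seed = 1, lambda = 8) {
  aa <- aminoAcidAlphabet()
  set.seed(seed)
  m <- matrix(rpois(400, lambda), 20, 20)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  dimnames(m) <- list(aa, aa)
  m
}

# geometric mini-complex written to a temp PDB file; returns the path
# and the site table used to build it
makeGeometricFixture <- function(nA = 3, nB = 3, seed = 1,
                                 spread = 10) {
  set.seed(seed)
  aa <- aminoAcidAlphabet()
  sites <- data.frame(
    chain = rep(c("A", "B"), c(nA, nB)),
    resno = c(seq_len(nA), seq_len(nB)),
    restype = sample(aa, nA + nB, replace = TRUE),
    x = runif(nA + nB, 0, spread),
    y = runif(nA + nB, 0, spread),
    z = runif(nA + nB, 0, spread))
  path <- tempfile(fileext = ".pdb")
  writeLines(generatePdbFixture(sites), path)
  list(path = path, sites = sites)
}

# 10-complex planted world under the package's default study conditions
makePlantedWorld <- function(nComplexes = 10, nA = 25, nB = 25,
                             seedBase = 100) {
  lapply(seq_len(nComplexes), function(s)
    generateComplex(nA, nB, seed = seedBase + s))
}
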