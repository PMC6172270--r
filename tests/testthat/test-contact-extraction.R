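test_that("a generated fixture parses back to its sites and coordinates", {
  fx <- makeGeometricFixture(nA = 3, nB = 3, seed = 7)
  cx <- parseStructure(fx$path, sideA = "A", sideB = "B")
  s <- complexSites(cx)
  expect_equal(nrow(s), 6)
  expect_equal(sort(unique(s$chain)), c("A", "B"))
  # independent line scan of the file
  lines <- readLines(fx$path)
  expect_equal(sum(startsWith(lines, "ATOM")), 6)
  # coordinates round-trip to PDB column precision
  ord <- order(s$chain, s$resno)
  expect_equal(s$x[ord], fx$sites$x, tolerance = 1e-3)
  expect_equal(s$y[ord], fx$sites$y, tolerance = 1e-3)
  expect_equal(s$z[ord], fx$sites$z, tolerance = 1e-3)
  expect_equal(s$type[ord], fx$sites$restype)
})

test_that("glycine uses CA and other residues use CB", {
  expect_equal(representativeCoordinate(list(CA = c(0, 0, 0),
                                             CB = c(1, 2, 3)), "A"),
               c(1, 2, 3))
  expect_equal(representativeCoordinate(list(CA = c(0, 0, 0)), "G"),
               c(0, 0, 0))
  expect_warning(out <- representativeCoordinate(list(CA = c(1, 1, 1)),
                                                 "L"),
                 "lacks atom CB")
  expect_null(out)
  # through the parser: a Gly site is present with its CA coordinate
  f <- tempfile(fileext = ".pdb")
  writeLines(generatePdbFixture(data.frame(
    chain = c("A", "B"), resno = 1:2, restype = c("G", "A"),
    x = c(1.5, 4), y = 0, z = 0)), f)
  s <- complexSites(parseStructure(f, "A", "B"))
  expect_equal(s$x[s$type == "G"], 1.5)
})

test_that("parser skips residues without a representative atom, with warning", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  LEU A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   2       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ARG B   1       3.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  expect_warning(cx <- parseStructure(f, "A", "B"), "skipped")
  expect_equal(nrow(complexSites(cx)), 2)  # the CA-only Leu is dropped
})

test_that("parser rejects degenerate inputs with informative errors", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  expect_error(parseStructure(f, "A", "B"), "no parsable ATOM")
  f2 <- tempfile(fileext = ".pdb")
  writeLines(generatePdbFixture(data.frame(
    chain = c("A", "B"), resno = 1:2, restype = c("A", "C"),
    x = c(0, 3), y = 0, z = 0)), f2)
  expect_error(parseStructure(f2, "A", "X"), "chain\\(s\\) X")
})

test_that("alternate locations keep the highest occupancy copy", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CB AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CB BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB  ARG B   1       9.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  s <- complexSites(parseStructure(f, "A", "B"))
  expect_equal(s$x[s$chain == "A"], 2)  # occupancy 0.60 wins
})

test_that("pair labelling is exhaustive with a strict 6-angstrom boundary", {
  f <- tempfile(fileext = ".pdb")
  writeLines(generatePdbFixture(data.frame(
    chain = c("A", "A", "B", "B"), resno = c(1, 2, 1, 2),
    restype = c("A", "C", "D", "E"),
    x = c(0, 0, 5.9, 6.0), y = c(0, 10, 0, 10), z = 0)), f)
  lp <- extractLabeledPairs(parseStructure(f, "A", "B"))
  expect_equal(nrow(lp), 4)  # |A| x |B|
  at <- function(ra, rb) lp$label[lp$resno_a == ra & lp$resno_b == rb]
  expect_equal(as.character(at(1, 1)), "positive")   # 5.9 A
  expect_equal(as.character(at(2, 2)), "negative")   # exactly 6.0 A
  expect_equal(sum(lp$label == "positive") + sum(lp$label == "negative"),
               nrow(lp))
})

test_that("labels agree with a brute-force distance oracle", {
  fx <- makeGeometricFixture(nA = 25, nB = 25, seed = 11, spread = 12)
  cx <- parseStructure(fx$path, "A", "B")
  lp <- extractLabeledPairs(cx)
  expect_equal(nrow(lp), 625)
  s <- fx$sites
  for (r in sample(nrow(lp), 200)) {
    a <- s[s$chain == "A" & s$resno == lp$resno_a[r], ]
    b <- s[s$chain == "B" & s$resno == lp$resno_b[r], ]
    d <- sqrt(sum((c(a$x, a$y, a$z) - c(b$x, b$y, b$z))^2))
    expect_equal(lp$distance[r], d, tolerance = 2e-3)
    expect_equal(as.character(lp$label[r]),
                 if (d < 6) "positive" else "negative")
  }
})

test_that("contact counting is symmetric and conserves totals", {
  p <- data.frame(type_a = c("R", "D"), type_b = c("D", "R"))
  m <- contactMatrix(buildContactCounts(p))
  expect_equal(m["R", "D"], 2L)
  expect_equal(m["D", "R"], 2L)
  m2 <- contactMatrix(buildContactCounts(
    data.frame(type_a = "C", type_b = "C")))
  expect_equal(m2["C", "C"], 1L)
  # conservation on 100 random contacts
  set.seed(3)
  aa <- aminoAcidAlphabet()
  p3 <- data.frame(type_a = sample(aa, 100, TRUE),
                   type_b = sample(aa, 100, TRUE))
  m3 <- contactMatrix(buildContactCounts(p3))
  expect_true(isTRUE(all.equal(m3, t(m3))))
  expect_equal(sum(m3[upper.tri(m3)]) + sum(diag(m3)), 100)
  # the doubled-diagonal convention counts participations
  m4 <- contactMatrix(buildContactCounts(p3, diagonalDouble = TRUE))
  expect_equal(sum(m4), 200)
  # empty input: zero matrix; negatives are refused
  expect_equal(sum(contactMatrix(buildContactCounts(p3[0, ]))), 0)
  expect_error(buildContactCounts(
    data.frame(type_a = "A", type_b = "C", label = "negative")),
    "positive")
})
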