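# random deep-knowledge bundle for feature tests
randomKnowledge <- function(seed = 1, M = 6) {
  srv <- statisticalResiduals(randomCountMatrix(seed = seed))
  deepKnowledge(srv, nComponents = M)
}

test_that("context windows cut 2k+1 letters with terminus padding", {
  ctx <- extractContext("PVKAAFV", 4, "ITLVAFE", 4, k = 3)
  expect_equal(ctx$windowA, strsplit("PVKAAFV", "")[[1]])
  expect_equal(ctx$windowB, strsplit("ITLVAFE", "")[[1]])
  lead <- extractContext("ACDEF", 1, "ACDEF", 5, k = 3)
  expect_equal(lead$windowA, c("-", "-", "-", "A", "C", "D", "E"))
  expect_equal(lead$windowB, c("C", "D", "E", "F", "-", "-", "-"))
  k0 <- extractContext("ACD", 2, "WY", 1, k = 0)
  expect_equal(k0$windowA, "C")
  expect_equal(k0$windowB, "W")
  expect_error(extractContext("ACD", 4, "WY", 1, k = 1), "out of")
  expect_warning(x <- extractContext("AXC", 2, "WY", 1, k = 1),
                 "treated as pad")
  expect_equal(x$windowA[2], "-")
})

test_that("feature length is 18(2k+1) for six components", {
  kn <- randomKnowledge(seed = 2)
  for (k in 0:3) {
    ctx <- extractContext("PVKAAFVAA", 5, "ITLVAFEAA", 5, k = k)
    expect_length(assembleFeatureVector(ctx, kn), 18 * (2 * k + 1))
  }
})

test_that("pair features look up the anti-aligned windows symmetrically", {
  kn <- randomKnowledge(seed = 3)
  ctx <- extractContext("PVKAAFV", 4, "ITLVAFE", 4, k = 3)
  fv <- assembleFeatureVector(ctx, kn)
  # the seven aligned pairs of this context, A left-to-right against
  # B right-to-left
  pairs <- list(c("P", "E"), c("V", "F"), c("K", "A"), c("A", "V"),
                c("A", "L"), c("F", "T"), c("V", "I"))
  for (p in seq_along(pairs)) {
    a <- pairs[[p]][1]; b <- pairs[[p]][2]
    for (m in 1:6) {
      want <- (kn$rsrvs[[m]][a, b] + kn$rsrvs[[m]][b, a]) / 2
      expect_equal(unname(fv[84 + (p - 1) * 6 + m]), want)
    }
  }
  # ordered variant uses the (side A, side B) entry directly
  fvo <- assembleFeatureVector(ctx, kn, symmetricAverage = FALSE)
  expect_equal(unname(fvo[84 + 1]), kn$rsrvs[[1]]["P", "E"])
})

test_that("residue-block features are the window residues' projections", {
  kn <- randomKnowledge(seed = 4)
  ctx <- extractContext("PVKAAFV", 4, "ITLVAFE", 4, k = 3)
  fv <- assembleFeatureVector(ctx, kn)
  expect_equal(unname(fv[1:6]), unname(kn$scores["P", ]))    # A window 1
  expect_equal(unname(fv[43:48]), unname(kn$scores["I", ]))  # B window 1
  # pad positions contribute zeros in all their slots
  edge <- extractContext("AC", 1, "WY", 2, k = 2)
  fve <- assembleFeatureVector(edge, kn)
  expect_equal(unname(fve[1:12]), rep(0, 12))  # two pad slots on A side
})

test_that("k = 0 features are the two centre projections plus pair terms", {
  kn <- randomKnowledge(seed = 5)
  ctx <- extractContext("A", 1, "C", 1, k = 0)
  fv <- assembleFeatureVector(ctx, kn)
  expect_length(fv, 18)
  expect_equal(unname(fv[1:6]), unname(kn$scores["A", ]))
  expect_equal(unname(fv[7:12]), unname(kn$scores["C", ]))
  want <- vapply(kn$rsrvs, function(r) (r["A", "C"] + r["C", "A"]) / 2,
                 numeric(1))
  expect_equal(unname(fv[13:18]), want)
})

test_that("permuting components permutes feature slots consistently", {
  kn <- randomKnowledge(seed = 6)
  knSwap <- kn
  perm <- c(2, 1, 3, 4, 5, 6)
  knSwap$scores <- kn$scores[, perm]
  knSwap$rsrvs <- kn$rsrvs[perm]
  ctx <- extractContext("PVKAAFV", 4, "ITLVAFE", 4, k = 1)
  fv <- assembleFeatureVector(ctx, kn)
  fvSwap <- assembleFeatureVector(ctx, knSwap)
  slotPerm <- as.vector(vapply(seq_len(9), function(slot)
    (slot - 1) * 6 + perm, numeric(6)))
  expect_equal(unname(fvSwap), unname(fv[slotPerm]))
})

test_that("candidate enumeration is the row-major Cartesian product", {
  cand <- enumerateCandidates("ACD", "WYEV")
  expect_equal(nrow(cand), 12)
  expect_equal(cand$i[1:4], rep(1, 4))
  expect_equal(cand$j[1:4], 1:4)
  expect_equal(nrow(enumerateCandidates("A", "C")), 1)
  expect_error(enumerateCandidates("", "C"), "non-empty")
})

test_that("vectorized featurization equals the per-pair reference path", {
  kn <- randomKnowledge(seed = 7)
  seqA <- "PVKAAFVWY"; seqB <- "ITLVAFEGH"
  cand <- enumerateCandidates(seqA, seqB, k = 2)
  X <- featurizePairs(seqA, seqB, cand, kn, k = 2)
  expect_equal(dim(X), c(81, 90))
  set.seed(1)
  for (r in sample(nrow(cand), 20)) {
    ctx <- extractContext(seqA, cand$i[r], seqB, cand$j[r], k = 2)
    expect_equal(unname(X[r, ]),
                 unname(assembleFeatureVector(ctx, kn)))
  }
})
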