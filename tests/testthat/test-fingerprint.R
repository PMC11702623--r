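test_that("vanilla LCM: self-correlation 1, affine antisymmetry, direct value", {
  m <- makeIcosphere(2)
  set.seed(3)
  a <- vertexMap(runif(nVertices(m)), "lgm", 2)
  self <- computeLcm(a, a, m)
  expect_equal(as.numeric(self), rep(1, nVertices(m)))
  flip <- vertexMap(1 - mapValues(a), "lgm", 2)
  anti <- computeLcm(a, flip, m)
  expect_equal(as.numeric(anti), rep(-1, nVertices(m)))
  # frozen direct Pearson value for a 7-point patch vs its squares
  p <- seq(0.1, 0.7, by = 0.1)
  expect_equal(cor(p, p^2), 0.9774, tolerance = 1e-4)
  # constant patch flagged and zeroed
  const <- vertexMap(rep(0.5, nVertices(m)), "lgm", 2)
  lc <- computeLcm(a, const, m)
  expect_true(all(attr(lc, "flags")))
  expect_equal(as.numeric(lc), rep(0, nVertices(m)))
})

test_that("deformable candidates: 1 vanilla + 2 rotations + 6 translations at hexagons", {
  m <- makeIcosphere(2)
  deg <- lengths(neighborRings(m))
  hexv <- which(deg == 6L)[1]
  pentv <- which(deg == 5L)[1]
  ch <- deformableCandidates(m, hexv)
  expect_identical(ch[["rotation"]], 2L)
  expect_identical(ch[["translation"]], 6L)
  expect_identical(ch[["total"]], 9L)
  cp <- deformableCandidates(m, pentv)
  expect_identical(cp[["translation"]], 5L)
  expect_identical(cp[["total"]], 8L)
})

test_that("deformable LCM dominates vanilla pointwise and recovers ring rotations", {
  m <- makeIcosphere(2)
  V <- nVertices(m)
  set.seed(5)
  for (k in seq_len(10)) {
    a <- vertexMap(runif(V), "lgm", 2)
    b <- vertexMap(runif(V), "lgm", 2)
    d <- deformableLcm(a, b, m)
    expect_true(all(d >= attr(d, "vanilla") - 1e-12))
    expect_true(all(abs(d) <= 1 + 1e-12))
  }
  # a base map whose ring at one centre is the target ring rotated one step:
  # the rotation candidate recovers correlation 1 where vanilla < 1
  deg <- lengths(neighborRings(m))
  hexv <- which(deg == 6L)[1]
  ring <- rotateRing(m, hexv, 0)
  av <- runif(V)
  bv <- av
  bv[ring] <- av[rotateRing(m, hexv, 1)]
  d <- deformableLcm(vertexMap(av, "lgm", 2), vertexMap(bv, "lgm", 2), m,
                     centers = hexv)
  expect_lt(attr(d, "vanilla")[1], 1 - 1e-6)
  expect_equal(as.numeric(d)[1], 1, tolerance = 1e-12)
})

test_that("tensor construction: shapes, role symmetry, deformable dominance", {
  m <- makeIcosphere(2)
  set.seed(9)
  mk <- function() vertexMap(runif(nVertices(m)), "lgm", 2)
  targets <- list(s1 = mk(), s2 = mk())
  bases <- list(s1 = mk(), s2 = mk(), s3 = mk())
  tz <- buildLcmTensor(targets, bases, m)
  expect_identical(dim(tz@values), c(2L, 3L, nVertices(m)))
  # single pair
  t1 <- buildLcmTensor(targets[1], bases[1], m)
  expect_identical(dim(t1@values), c(1L, 1L, nVertices(m)))
  # swapping roles transposes (vanilla LCM is symmetric in its arguments)
  rev <- buildLcmTensor(bases, targets, m)
  expect_equal(rev@values[3, 2, ], tz@values[2, 3, ], tolerance = 1e-12)
  # deformable never lowers an entry
  td <- buildLcmTensor(targets, bases, m, deformable = TRUE)
  expect_true(all(td@values >= tz@values - 1e-12))
  expect_error(buildLcmTensor(list(mk(), mk()), bases, m), "named")
  expect_error(buildLcmTensor(list(s1 = mk(), s1 = mk())[1:2], bases, m),
               "unique|named")
})

test_that("vertex-wise voting: argmax votes, fractions sum to 1, tie handling", {
  vals <- array(0, c(1, 2, 3))
  vals[1, 1, ] <- c(0.9, 0.2, 0.8)
  vals[1, 2, ] <- c(0.5, 0.6, 0.1)
  tz <- new("LcmTensor", values = vals, centers = 1:3, r = 1L,
            deformable = FALSE, targetIds = "s1", baseIds = c("s1", "s2"),
            flags = array(FALSE, c(1, 2, 3)))
  rep <- identifyVertexwise(tz)
  expect_identical(predictedIds(rep), "s1")
  expect_equal(rep@voteFractions[1, ], c(s1 = 2 / 3, s2 = 1 / 3))
  expect_equal(sum(rep@voteFractions[1, ]), 1)
  expect_identical(ratePercent(rep), 100)
  # all-equal entries: lowest-index subject wins with a tie flag
  tie <- new("LcmTensor", values = array(0.5, c(1, 2, 3)), centers = 1:3,
             r = 1L, deformable = FALSE, targetIds = "s2",
             baseIds = c("s1", "s2"), flags = array(FALSE, c(1, 2, 3)))
  trep <- identifyVertexwise(tie)
  expect_identical(predictedIds(trep), "s1")
  expect_true(trep@tieFlags[1])
  expect_error(identifyVertexwise(tz, mask = rep(FALSE, 3)), "no centres")
})

test_that("average-based identification and the procedures-disagree fixture", {
  vals <- array(0, c(1, 2, 3))
  vals[1, 1, ] <- c(0.9, 0.2, 0.8)   # mean 0.633
  vals[1, 2, ] <- c(0.5, 0.6, 0.1)   # mean 0.4
  tz <- new("LcmTensor", values = vals, centers = 1:3, r = 1L,
            deformable = FALSE, targetIds = "s1", baseIds = c("s1", "s2"),
            flags = array(FALSE, c(1, 2, 3)))
  arep <- identifyAverage(tz)
  expect_identical(predictedIds(arep), "s1")
  expect_equal(unname(arep@voteFractions[1, ]), c(0.6333333, 0.4),
               tolerance = 1e-6)
  # vertex-wise favours subject 1 (2 of 3 centres) but subject 2 wins on mean
  vals2 <- array(0, c(1, 2, 3))
  vals2[1, 1, ] <- c(0.51, 0.52, 0.0)
  vals2[1, 2, ] <- c(0.50, 0.50, 0.9)
  tz2 <- new("LcmTensor", values = vals2, centers = 1:3, r = 1L,
             deformable = FALSE, targetIds = "s1", baseIds = c("s1", "s2"),
             flags = array(FALSE, c(1, 2, 3)))
  expect_identical(predictedIds(identifyVertexwise(tz2)), "s1")
  expect_identical(predictedIds(identifyAverage(tz2)), "s2")
})

test_that("identification rate reproduces printed percentages, half-up", {
  expect_identical(identificationRate(103, 103), 100)
  expect_identical(identificationRate(101, 103), 98.1)
  expect_identical(identificationRate(102, 103), 99)
  expect_identical(identificationRate(0, 10), 0)
  expect_identical(identificationRate(1, 16), 6.3)  # 6.25 rounds half-up
  expect_error(identificationRate(1, 0), "total")
  expect_error(identificationRate(5, 3), "<=")
})

test_that("vote fractions are invariant to monotone transforms of a target row", {
  tz <- randomTensor(3, 4, 50, seed = 23)
  rep1 <- identifyVertexwise(tz)
  tz2 <- tz
  tz2@values[2, , ] <- tanh(3 * tz2@values[2, , ]) + 0.1
  rep2 <- identifyVertexwise(tz2)
  expect_equal(rep1@voteFractions[2, ], rep2@voteFractions[2, ])
})

test_that("network-restricted identification recombines to the global vote", {
  tz <- randomTensor(2, 3, 40, seed = 31)
  labels <- rep(c(1L, 2L), each = 20)  # per-vertex labels over the 40 centres
  full <- identifyVertexwise(tz)
  n1 <- identifyByNetwork(tz, labels, 1)
  n2 <- identifyByNetwork(tz, labels, 2)
  recomb <- (n1@voteFractions * 20 + n2@voteFractions * 20) / 40
  expect_equal(recomb, full@voteFractions)
  expect_error(identifyByNetwork(tz, labels, 7), "no sampled centres")
  # mask covering everything reduces to the global vote
  expect_equal(identifyVertexwise(tz, rep(TRUE, 40))@voteFractions,
               full@voteFractions)
})

test_that("connectome vectors: length, vertex-permutation invariance", {
  m <- makeIcosphere(2)
  lab <- simulateParcellation(m, 3, seed = 2)
  bold <- simulateBold(m, lab, T = 50, snr = 2, seed = 4)
  v <- connectomeVector(bold, lab)
  expect_length(v, 3L)
  lab36 <- simulateParcellation(m, 36, seed = 6)
  expect_length(connectomeVector(bold, lab36), 36 * 35 / 2)
  expect_identical(360 * 359 / 2, 64620)
  # permuting vertices within ROIs leaves ROI means unchanged
  perm <- order(lab, sample(seq_len(nVertices(m))))
  expect_equal(connectomeVector(bold@values[perm, ], lab[perm]), v)
  f <- factor(lab, levels = 1:4)
  expect_error(connectomeVector(bold, f), "zero vertices")
})

test_that("connectome identification: argmax correlation, constant vectors never win", {
  tv <- rbind(s1 = c(1, 2, 3))
  bv <- rbind(s1 = c(1, 2, 3.1), s2 = c(3, 2, 1))
  rep <- identifyConnectome(tv, bv)
  expect_identical(predictedIds(rep), "s1")
  expect_identical(ratePercent(rep), 100)
  # exact copy among noise distractors
  set.seed(8)
  base <- matrix(rnorm(30), 3, 10,
                 dimnames = list(c("a", "b", "c"), NULL))
  targ <- base["b", , drop = FALSE] + rnorm(10, sd = 1e-6)
  rownames(targ) <- "b"
  expect_identical(predictedIds(identifyConnectome(targ, base)), "b")
  # identical base vectors tie to the lowest index with a flag
  same <- rbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3))
  tierep <- identifyConnectome(tv, same)
  expect_identical(predictedIds(tierep), "s1")
  expect_true(tierep@tieFlags[1])
})

test_that("noiseless cohorts identify perfectly; exact copy gets full votes", {
  m <- makeIcosphere(2)
  spec <- cohortSpec(nSubjects = 4, meshLevel = 2, nParcels = 6,
                     subjectJitterHops = 2, sessionNoiseSigma = 0,
                     masterSeed = 19)
  co <- simulateLgmCohort(spec)
  tz <- buildLcmTensor(cohortLgmSet(co, 1), cohortLgmSet(co, 2), m)
  rep <- identifyVertexwise(tz)
  expect_identical(ratePercent(rep), 100)
})
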