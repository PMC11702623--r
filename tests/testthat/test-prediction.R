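test_that("boundary atlas: interface masks, dilation monotonicity, degenerate input", {
  m <- makeIcosphere(3)
  # two regions split by the equator
  lab <- ifelse(vertexCoords(m)[, 3] >= 0, 1L, 2L)
  atlas0 <- buildBoundaryAtlas(lab, m, dilationIters = 0)
  expect_identical(names(atlas0@boundaryMasks), "1_2")
  # undilated mask = all vertices with a cross-label neighbour
  edges <- lgmprint:::meshEdges(m)
  cross <- unique(edges[lab[edges[, 1]] != lab[edges[, 2]], 1])
  expect_setequal(which(atlas0@boundaryMasks[["1_2"]]), cross)
  atlas3 <- buildBoundaryAtlas(lab, m, dilationIters = 3)
  expect_true(all(atlas0@boundaryMasks[["1_2"]] <= atlas3@boundaryMasks[["1_2"]]))
  expect_error(buildBoundaryAtlas(rep(1L, nVertices(m)), m), "2 regions")
})

test_that("boundary features are masked means", {
  m <- makeIcosphere(2)
  lab <- simulateParcellation(m, 5, seed = 3)
  atlas <- buildBoundaryAtlas(lab, m, dilationIters = 1)
  V <- nVertices(m)
  # constant map: every feature equals the constant
  expect_true(all(abs(boundaryFeatures(rep(0.4, V), atlas) - 0.4) < 1e-12))
  # indicator of one mask: that boundary 1, any disjoint boundary 0
  id1 <- names(atlas@boundaryMasks)[1]
  ind <- as.numeric(atlas@boundaryMasks[[id1]])
  f <- boundaryFeatures(ind, atlas)
  expect_equal(unname(f[id1]), 1)
  overlaps <- vapply(atlas@boundaryMasks, function(mm)
    any(mm & atlas@boundaryMasks[[id1]]), TRUE)
  if (any(!overlaps)) expect_equal(unname(f[which(!overlaps)[1]]), 0)
  # random map: masked-mean oracle
  set.seed(5)
  v <- runif(V)
  f2 <- boundaryFeatures(v, atlas)
  for (id in names(atlas@boundaryMasks)) {
    expect_equal(unname(f2[id]), mean(v[atlas@boundaryMasks[[id]]]))
  }
})

test_that("directional selection uses the two-sided t test on Pearson r", {
  set.seed(7)
  n <- 40
  scores <- rnorm(n)
  feats <- cbind(
    hit = scores + rnorm(n, sd = 0.1),
    anti = -scores + rnorm(n, sd = 0.1),
    noise = rnorm(n),
    flat = rep(1, n)
  )
  sel <- selectBoundaries(feats, scores)
  expect_true("hit" %in% sel$positive)
  expect_true("anti" %in% sel$negative)
  expect_identical(sel$excluded, "flat")
  expect_false("noise" %in% c(sel$positive, sel$negative))
  # n = 20, r = 0.3 -> t = 1.334, p ~ 0.199: not selected at 0.01
  r <- 0.3; nn <- 20
  tstat <- r * sqrt((nn - 2) / (1 - r^2))
  expect_equal(tstat, 1.334, tolerance = 1e-3)
  expect_equal(2 * pt(-tstat, nn - 2), 0.199, tolerance = 1e-2)
  # p-values agree with cor.test
  ct <- cor.test(feats[, "noise"], scores)
  expect_equal(sel$stats$p[sel$stats$boundary == "noise"], ct$p.value,
               tolerance = 1e-12)
  expect_error(selectBoundaries(feats, rep(1, n)), "variance")
})

test_that("two-dimensional sum feature adds each selected set", {
  feats <- rbind(c(a = 0.2, b = 0.3, c = 0.1), c(a = 0.5, b = 0, c = 0.4))
  x2 <- twoDimFeature(feats, c("a", "b"), "c")
  expect_equal(unname(x2[, "sumPos"]), c(0.5, 0.5))
  expect_equal(unname(x2[, "sumNeg"]), c(0.1, 0.4))
  # single positive boundary, no negatives
  x1 <- twoDimFeature(feats[1, , drop = FALSE], "a", character())
  expect_equal(unname(x1[1, ]), c(0.2, 0))
  # order of ids does not matter
  expect_equal(twoDimFeature(feats, c("b", "a"), "c"), x2)
})

test_that("cross-validation never leaks held-out rows and covers each scan once", {
  set.seed(11)
  feats <- matrix(runif(60 * 5), 60, 5,
                  dimnames = list(NULL, paste0("b", 1:5)))
  scores <- feats[, 1] * 3 + rnorm(60, sd = 0.3)
  cv <- rfCvPredict(feats, scores, iterations = 3, folds = 5, seed = 19)
  for (it in cv@selections) {
    held <- sort(unlist(lapply(it, `[[`, "test")))
    expect_identical(held, 1:60)  # every scan held out exactly once
    for (k in seq_along(it)) {
      for (l in seq_along(it)) {
        if (k < l) expect_length(intersect(it[[k]]$test, it[[l]]$test), 0)
      }
    }
  }
  expect_error(rfCvPredict(feats[1:4, ], scores[1:4], folds = 10), "folds")
  expect_error(rfCvPredict(feats, rep(1, 60)), "constant")
})

test_that("cross-validated prediction is deterministic and recovers a direct signal", {
  set.seed(13)
  feats <- matrix(runif(140 * 6), 140, 6,
                  dimnames = list(NULL, paste0("b", 1:6)))
  scores <- feats[, 2]           # scores exactly equal one boundary feature
  cv1 <- rfCvPredict(feats, scores, seed = 23)
  cv2 <- rfCvPredict(feats, scores, seed = 23)
  expect_identical(cv1@predictions, cv2@predictions)
  expect_identical(cv1@selections, cv2@selections)
  expect_gte(rValue(cv1), 0.95)
  # permuted scores: no positive signal. The average is in fact negative:
  # under the null most folds select nothing, the training-mean fallback
  # predicts the leave-out mean, and leave-out means anticorrelate with the
  # held-out scores (the usual cross-validation mean-regression artifact).
  rs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    rValue(rfCvPredict(feats, sample(scores), seed = s))
  }, 0)
  expect_lt(mean(rs), 0.1)
  expect_lt(max(rs), 0.3)
})

test_that("empty selections fall back to the training-mean prediction", {
  set.seed(17)
  feats <- matrix(runif(30 * 3), 30, 3,
                  dimnames = list(NULL, paste0("b", 1:3)))
  scores <- rnorm(30)  # unrelated: selections will often be empty
  cv <- rfCvPredict(feats, scores, iterations = 2, folds = 3, seed = 29)
  fallbacks <- unlist(lapply(cv@selections, function(it)
    lapply(it, function(fd) isTRUE(fd$fallback))))
  expect_true(any(fallbacks))
  expect_true(all(is.finite(cv@predictions)))
})

test_that("network contributions normalize per network and count shared boundaries twice", {
  m <- makeIcosphere(2)
  lab <- simulateParcellation(m, 6, seed = 31)
  regions <- sort(unique(lab))
  netOf <- stats::setNames(rep(1:2, length.out = length(regions)), regions)
  atlas <- buildBoundaryAtlas(lab, m, networkOfRegion = netOf,
                              dilationIters = 1)
  ids <- names(atlas@boundaryMasks)
  fake <- new("CvResult",
    predictions = rep(0, 4), observed = rep(c(0, 1), 2), rValue = 0,
    selections = list(list(list(test = 1:2, positive = ids, negative = ids))),
    seed = 1L, params = list(iterations = 1, folds = 1, trees = 20,
                             minLeaf = 5, pThreshold = 0.01))
  nc <- networkContribution(fake, atlas)
  expect_equal(nc$positive, rep(1, nrow(nc)))  # all selected -> 1 everywhere
  expect_equal(nc$negative, rep(1, nrow(nc)))
  none <- fake
  none@selections <- list(list(list(test = 1:2, positive = character(),
                                    negative = character())))
  nc0 <- networkContribution(none, atlas)
  expect_equal(nc0$positive, rep(0, nrow(nc0)))
  # one inter-network boundary contributes its vertex count to both networks
  bnets <- lgmprint:::boundaryNetworks(atlas)
  k <- which(lengths(bnets) == 2)[1]
  one <- fake
  one@selections <- list(list(list(test = 1:2, positive = ids[k],
                                   negative = character())))
  nc1 <- networkContribution(one, atlas)
  expect_true(all(nc1$positive > 0))  # both networks got the count
})

test_that("values of network contributions stay within [0, 1]", {
  m <- makeIcosphere(2)
  lab <- simulateParcellation(m, 8, seed = 37)
  regions <- sort(unique(lab))
  netOf <- stats::setNames(rep(1:3, length.out = length(regions)), regions)
  atlas <- buildBoundaryAtlas(lab, m, networkOfRegion = netOf,
                              dilationIters = 2)
  feats <- t(vapply(1:25, function(i) {
    set.seed(300 + i)
    boundaryFeatures(runif(nVertices(m)), atlas)
  }, numeric(length(atlas@boundaryMasks))))
  set.seed(41)
  scores <- feats[, 1] - feats[, 2] + rnorm(25, sd = 0.05)
  cv <- rfCvPredict(feats, scores, iterations = 2, folds = 5, seed = 43)
  nc <- networkContribution(cv, atlas)
  expect_true(all(nc$positive >= 0 & nc$positive <= 1))
  expect_true(all(nc$negative >= 0 & nc$negative <= 1))
})

test_that("leave-one-network-out drops accuracy only for the causal network", {
  study <- simulatePredictionStudy(nSubjects = 40, masterSeed = 47,
                                   scoreSeed = 49)
  cv <- rfCvPredict(study$features, study$scores, iterations = 3,
                    folds = 10, seed = 51)
  rFull <- rValue(cv)
  rCausal <- leaveOneNetworkOut(study$features, study$scores, study$atlas,
                                study$causalNetwork, iterations = 3,
                                folds = 10, seed = 51)
  rOther <- leaveOneNetworkOut(study$features, study$scores, study$atlas,
                               5, iterations = 3, folds = 10, seed = 51)
  expect_lt(rCausal, rFull - 0.1)
  expect_gt(rOther, rCausal)
  expect_error(leaveOneNetworkOut(study$features, study$scores, study$atlas,
                                  99), "not in atlas")
})
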