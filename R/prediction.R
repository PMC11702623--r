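## Cognitive score prediction from parcellation-boundary LGM features:
## boundary atlas construction, directional feature selection, the
## two-dimensional sum feature, random-forest cross-validation, network
## contributions and leave-one-network-out importance.

#' Build a boundary atlas from a parcellation
#'
#' For every adjacent unordered region pair, the mask of vertices on the
#' pair's interface (vertices carrying one of the two labels with a 1-ring
#' neighbour carrying the other), dilated `dilationIters` times for
#' robustness to residual misalignment between the parcellation and
#' individual maps. A vertex may belong to several masks.
#'
#' @param labels integer region id per vertex
#' @param mesh a [SphericalMesh-class]
#' @param networkOfRegion named integer vector mapping region id to network
#'   id (names are region ids); defaults to a single network
#' @param dilationIters dilation count (default 3)
#' @return a [BoundaryAtlas-class]
#' @export
buildBoundaryAtlas <- function(labels, mesh, networkOfRegion = NULL,
                               dilationIters = 3) {
  labels <- as.integer(labels)
  if (length(labels) != nVertices(mesh)) stop("labels length != vertex count")
  regions <- sort(unique(labels))
  if (length(regions) < 2) stop("need at least 2 regions")
  if (is.null(networkOfRegion)) {
    networkOfRegion <- stats::setNames(rep(1L, length(regions)), regions)
  }
  networkOfRegion <- stats::setNames(as.integer(networkOfRegion),
                                     names(networkOfRegion))
  edges <- meshEdges(mesh)
  la <- labels[edges[, 1]]
  lb <- labels[edges[, 2]]
  cross <- la != lb
  pa <- pmin(la[cross], lb[cross])
  pb <- pmax(la[cross], lb[cross])
  vtx <- edges[cross, 1]
  key <- paste0(pa, "_", pb)
  pairs <- sort(unique(key))
  masks <- vector("list", length(pairs))
  names(masks) <- pairs
  V <- nVertices(mesh)
  for (k in seq_along(pairs)) {
    m <- logical(V)
    m[vtx[key == pairs[k]]] <- TRUE
    masks[[k]] <- dilateMask(mesh, m, dilationIters)
  }
  pr <- do.call(rbind, strsplit(pairs, "_", fixed = TRUE))
  storage.mode(pr) <- "integer"
  new("BoundaryAtlas",
      regionLabels = labels, networkOfRegion = networkOfRegion,
      boundaryMasks = masks, boundaryRegions = pr,
      dilationIters = as.integer(dilationIters))
}

#' Boundary-mean LGM features of one scan
#'
#' The LGM values within each boundary mask, averaged: one feature per
#' region-pair boundary.
#'
#' @param lgm a per-vertex map ([VertexMap-class] or numeric)
#' @param atlas a [BoundaryAtlas-class]
#' @return named numeric vector, one value per boundary
#' @export
boundaryFeatures <- function(lgm, atlas) {
  v <- asMapValues(lgm)
  if (length(v) != length(atlas@regionLabels))
    stop("map length does not match the atlas")
  sizes <- vapply(atlas@boundaryMasks, sum, 0L)
  if (any(sizes == 0)) {
    warning("dropping ", sum(sizes == 0), " empty boundary mask(s)")
  }
  keep <- sizes > 0
  vapply(atlas@boundaryMasks[keep], function(m) mean(v[m]), 0)
}

#' Directional boundary selection on a training set
#'
#' Pearson-correlates each boundary feature with the scores and keeps
#' boundaries significant at `pThreshold` (two-sided t test on r with n - 2
#' degrees of freedom, no multiple-testing correction), split by correlation
#' sign into a positive and a negative set. Constant feature columns are
#' excluded and flagged.
#'
#' @param features scans x boundaries numeric matrix with boundary-id
#'   column names
#' @param scores per-scan scores (length `nrow(features)`, variance > 0)
#' @param pThreshold significance threshold (default 0.01)
#' @return list with `positive` and `negative` boundary-id vectors,
#'   `stats` (r, t, p per boundary) and `excluded`
#' @export
selectBoundaries <- function(features, scores, pThreshold = 0.01) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3) stop("need at least 3 training scans")
  if (stats::sd(scores) == 0) stop("scores have zero variance")
  sds <- apply(features, 2, stats::sd)
  excluded <- colnames(features)[sds == 0]
  ok <- sds > 0
  r <- rep(NA_real_, ncol(features))
  r[ok] <- as.numeric(stats::cor(features[, ok, drop = FALSE], scores))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  sig <- ok & !is.na(p) & p < pThreshold
  list(
    positive = colnames(features)[sig & r > 0],
    negative = colnames(features)[sig & r < 0],
    stats = data.frame(boundary = colnames(features), r = r, t = tstat, p = p),
    excluded = excluded
  )
}

#' Two-dimensional sum feature
#'
#' Per scan, the sum of the selected positively correlated boundary features
#' and the sum of the negatively correlated ones; an empty set contributes 0.
#'
#' @param features scans x boundaries matrix
#' @param positive,negative selected boundary ids
#' @return scans x 2 matrix with columns `sumPos`, `sumNeg`
#' @export
twoDimFeature <- function(features, positive, negative) {
  features <- as.matrix(features)
  sumSet <- function(ids) {
    if (!length(ids)) return(numeric(nrow(features)))
    rowSums(features[, ids, drop = FALSE])
  }
  cbind(sumPos = sumSet(positive), sumNeg = sumSet(negative))
}

#' Random-forest cross-validated score prediction
#'
#' Runs `iterations` repeats of `folds`-fold cross-validation. In each fold,
#' boundary selection ([selectBoundaries()]) and the two-dimensional sum
#' feature ([twoDimFeature()]) are computed on the training rows only; a
#' regression random forest (`trees` trees, minimum `minLeaf` observations
#' per leaf, both features tried at each split) is fitted on the training
#' 2-D features and predicts the held-out rows. When a fold selects no
#' boundary at all, its predictions fall back to the training mean score.
#' The final per-scan prediction is the mean over iterations; accuracy is
#' the Pearson correlation between averaged predictions and observed scores.
#'
#' A master `seed` deterministically spawns per-iteration shuffle seeds and
#' per-fold forest seeds, so results are bit-reproducible.
#'
#' @param features scans x boundaries matrix (boundary ids as column names)
#' @param scores per-scan observed scores
#' @param iterations,folds cross-validation layout (default 10 x 10-fold)
#' @param trees,minLeaf forest hyperparameters (default 20 trees, leaf 5)
#' @param pThreshold selection threshold (default 0.01)
#' @param seed master seed
#' @return a [CvResult-class]
#' @export
rfCvPredict <- function(features, scores, iterations = 10, folds = 10,
                        trees = 20, minLeaf = 5, pThreshold = 0.01,
                        seed = 1) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (folds > n) stop("more folds than scans")
  if (stats::sd(scores) == 0) stop("constant observed scores: r undefined")
  set.seed(as.integer(seed))
  iterSeeds <- sample.int(.Machine$integer.max, iterations)
  predMat <- matrix(NA_real_, iterations, n)
  selections <- vector("list", iterations)

  for (it in seq_len(iterations)) {
    set.seed(iterSeeds[it])
    perm <- sample.int(n)
    foldId <- rep_len(seq_len(folds), n)[order(perm)]
    foldSeeds <- sample.int(.Machine$integer.max, folds)
    selections[[it]] <- vector("list", folds)
    for (fd in seq_len(folds)) {
      test <- which(foldId == fd)
      train <- which(foldId != fd)
      sel <- selectBoundaries(features[train, , drop = FALSE], scores[train],
                              pThreshold)
      selections[[it]][[fd]] <- list(
        test = test, positive = sel$positive, negative = sel$negative
      )
      if (!length(sel$positive) && !length(sel$negative)) {
        predMat[it, test] <- mean(scores[train])
        selections[[it]][[fd]]$fallback <- TRUE
        next
      }
      x2 <- twoDimFeature(features, sel$positive, sel$negative)
      set.seed(foldSeeds[fd])
      rf <- randomForest::randomForest(
        x = x2[train, , drop = FALSE], y = scores[train],
        ntree = trees, nodesize = minLeaf, mtry = 2
      )
      predMat[it, test] <- stats::predict(rf, x2[test, , drop = FALSE])
    }
  }
  preds <- colMeans(predMat)
  new("CvResult",
      predictions = preds, observed = as.numeric(scores),
      rValue = stats::cor(preds, scores),
      selections = selections, seed = as.integer(seed),
      params = list(iterations = iterations, folds = folds, trees = trees,
                    minLeaf = minLeaf, pThreshold = pThreshold))
}

# networks touched by each boundary of an atlas (1- or 2-element vectors)
boundaryNetworks <- function(atlas) {
  netOf <- atlas@networkOfRegion
  apply(atlas@boundaryRegions, 1, function(ab) {
    unique(netOf[as.character(ab)])
  }, simplify = FALSE)
}

#' Per-network contribution to prediction
#'
#' For every network: the mean, over all folds of all iterations, of the
#' number of vertices in selected boundary masks touching the network,
#' normalized by the network's total boundary-mask vertex count. A boundary
#' between two networks counts for both. Positive and negative selections
#' are summarized separately.
#'
#' @param cv a [CvResult-class] from [rfCvPredict()]
#' @param atlas the [BoundaryAtlas-class] the features came from
#' @return data.frame with columns `network`, `positive`, `negative`
#'   (values in \[0, 1\]); networks with no boundary vertices are absent
#' @export
networkContribution <- function(cv, atlas) {
  ids <- names(atlas@boundaryMasks)
  sizes <- vapply(atlas@boundaryMasks, sum, 0L)
  bnets <- boundaryNetworks(atlas)
  nets <- sort(unique(unlist(bnets)))
  totals <- vapply(nets, function(g) {
    sum(sizes[vapply(bnets, function(b) g %in% b, TRUE)])
  }, 0)
  keep <- totals > 0
  nets <- nets[keep]; totals <- totals[keep]

  fracOf <- function(selIds) {
    vapply(seq_along(nets), function(k) {
      touch <- vapply(bnets, function(b) nets[k] %in% b, TRUE)
      sum(sizes[ids %in% selIds & touch]) / totals[k]
    }, 0)
  }
  posAcc <- negAcc <- numeric(length(nets))
  nFold <- 0L
  for (it in cv@selections) for (fd in it) {
    posAcc <- posAcc + fracOf(fd$positive)
    negAcc <- negAcc + fracOf(fd$negative)
    nFold <- nFold + 1L
  }
  data.frame(network = nets, positive = posAcc / nFold,
             negative = negAcc / nFold)
}

#' Leave-one-network-out prediction
#'
#' Reruns the cross-validated prediction with every boundary touching the
#' held-out network removed from the candidate set. A lower resulting r
#' marks a more important network.
#'
#' @param features scans x boundaries matrix
#' @param scores per-scan scores
#' @param atlas the [BoundaryAtlas-class]
#' @param heldOutNetwork network id to remove
#' @param ... further arguments to [rfCvPredict()]
#' @return the resulting Pearson r between predictions and scores
#' @export
leaveOneNetworkOut <- function(features, scores, atlas, heldOutNetwork, ...) {
  nets <- unique(atlas@networkOfRegion)
  if (!heldOutNetwork %in% nets) stop("held-out network not in atlas")
  bnets <- boundaryNetworks(atlas)
  keep <- !vapply(bnets, function(b) heldOutNetwork %in% b, TRUE)
  ids <- names(atlas@boundaryMasks)[keep]
  ids <- intersect(ids, colnames(features))
  if (!length(ids)) stop("removal empties the candidate boundary set")
  cv <- rfCvPredict(as.matrix(features)[, ids, drop = FALSE], scores, ...)
  cv@rValue
}
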