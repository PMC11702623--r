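## Local correlation maps between LGM pairs (vanilla and deformable),
## vertex-wise / average-based / network-restricted identification, and the
## connectome-based baseline.

.patchCache <- new.env(parent = emptyenv())

# ragged list of r-ring patch index vectors for the given centres
patchIndices <- function(mesh, centers, r) {
  V <- nVertices(mesh)
  full <- length(centers) == V && all(centers == seq_len(V))
  key <- sprintf("%d:%d", mesh@level, r)
  if (full && !is.null(.patchCache[[key]])) return(.patchCache[[key]])
  out <- lapply(centers, function(v) rRingIndices(mesh, v, r))
  if (full) .patchCache[[key]] <- out
  out
}

# row-wise Pearson between two matrices of patch values; constant rows -> 0
rowCorrFlag <- function(A, B) {
  Am <- A - rowMeans(A)
  Bm <- B - rowMeans(B)
  num <- rowSums(Am * Bm)
  da <- rowSums(Am^2)
  db <- rowSums(Bm^2)
  bad <- da <= 0 | db <= 0
  r <- numeric(nrow(A))
  ok <- !bad
  r[ok] <- pmin(pmax(num[ok] / sqrt(da[ok] * db[ok]), -1), 1)
  list(r = r, flags = bad)
}

#' Local correlation map between two LGMs
#'
#' At each sampled centre, the Pearson correlation between the two r-ring
#' patch vectors (ordered by [rRingIndices()]): the vertex-wise local
#' similarity of the two fingerprints. A constant patch on either side makes
#' the correlation undefined; such centres get value 0 and a flag.
#'
#' @param lgmT,lgmB per-vertex maps ([VertexMap-class] or numeric), same mesh
#' @param mesh a [SphericalMesh-class]
#' @param centers sampled centre vertex indices (default: all vertices)
#' @param r patch ring radius, 1..7
#' @return numeric per-centre correlations with logical `attr(, "flags")`
#' @export
computeLcm <- function(lgmT, lgmB, mesh, centers = seq_len(nVertices(mesh)),
                       r = 1) {
  a <- asMapValues(lgmT)
  b <- asMapValues(lgmB)
  V <- nVertices(mesh)
  if (length(a) != V || length(b) != V)
    stop("map length does not match the mesh (level mismatch?)")
  patches <- patchIndices(mesh, centers, r)
  lens <- lengths(patches)
  out <- numeric(length(centers))
  flags <- logical(length(centers))
  for (L in unique(lens)) {
    sel <- which(lens == L)
    idx <- matrix(unlist(patches[sel], use.names = FALSE),
                  nrow = length(sel), byrow = TRUE)
    rc <- rowCorrFlag(
      matrix(a[idx], nrow = length(sel)),
      matrix(b[idx], nrow = length(sel))
    )
    out[sel] <- rc$r
    flags[sel] <- rc$flags
  }
  attr(out, "flags") <- flags
  out
}

#' Deformable local correlation map (1-ring patches)
#'
#' Augments the vanilla patch comparison with up to eight deformed base
#' patches per centre — the base ring rotated by one cyclic step in either
#' direction (a 60-degree rotation at hexagonal vertices) and the base patch
#' slid to each of the centre's ring neighbours (six directions at hexagons,
#' five at pentagons) — and takes the pointwise maximum correlation. By
#' construction the result is never below the vanilla value, which is
#' returned alongside in `attr(, "vanilla")`.
#'
#' @inheritParams computeLcm
#' @param r must be 1; the deformable strategy is defined for 1-ring patches
#' @return numeric per-centre correlations with `attr(, "vanilla")` and
#'   `attr(, "flags")`
#' @export
deformableLcm <- function(lgmT, lgmB, mesh, centers = seq_len(nVertices(mesh)),
                          r = 1) {
  if (r != 1) stop("deformable strategy requires r = 1")
  a <- asMapValues(lgmT)
  b <- asMapValues(lgmB)
  V <- nVertices(mesh)
  if (length(a) != V || length(b) != V)
    stop("map length does not match the mesh (level mismatch?)")
  ops <- meshOps(mesh)
  res <- deformable_lcm_cpp(a, b, as.integer(centers), ops$ringStarts,
                            ops$ringIdx)
  out <- res$values
  attr(out, "vanilla") <- res$vanilla
  attr(out, "flags") <- res$flags
  out
}

#' Candidate count of the deformable strategy at a centre
#'
#' One vanilla candidate, two ring rotations, and one translation per ring
#' neighbour: 9 candidates at hexagonal centres, 8 at the 12 pentagons.
#'
#' @param mesh a [SphericalMesh-class]
#' @param center vertex index
#' @return named integer vector with components `vanilla`, `rotation`,
#'   `translation` and `total`
#' @export
deformableCandidates <- function(mesh, center) {
  deg <- length(mesh@rings[[center]])
  c(vanilla = 1L, rotation = 2L, translation = deg,
    total = 3L + deg)
}

#' Build a local-correlation tensor from target and base LGM sets
#'
#' `values[i, j, v]` holds the (deformable) local correlation between target
#' map i and base map j at centre v. Sets are named lists of LGMs, names
#' being subject ids (unique within a set; the same ids may appear in both
#' sets — same subjects, different sessions).
#'
#' @param targets,bases named lists of per-vertex maps
#' @param mesh a [SphericalMesh-class]
#' @param centers sampled centre indices (default all)
#' @param r patch ring radius
#' @param deformable logical; use [deformableLcm()] instead of [computeLcm()]
#' @return an [LcmTensor-class]
#' @export
buildLcmTensor <- function(targets, bases, mesh,
                           centers = seq_len(nVertices(mesh)), r = 1,
                           deformable = FALSE) {
  if (!length(targets) || !length(bases)) stop("both sets must be nonempty")
  tids <- names(targets)
  bids <- names(bases)
  if (is.null(tids) || is.null(bids) || anyDuplicated(tids) || anyDuplicated(bids))
    stop("sets must be named lists with unique subject ids")
  centers <- as.integer(centers)
  nT <- length(targets); nB <- length(bases); nC <- length(centers)
  vals <- array(0, dim = c(nT, nB, nC))
  flg <- array(FALSE, dim = c(nT, nB, nC))
  for (i in seq_len(nT)) {
    for (j in seq_len(nB)) {
      lc <- if (deformable)
        deformableLcm(targets[[i]], bases[[j]], mesh, centers, r)
      else computeLcm(targets[[i]], bases[[j]], mesh, centers, r)
      vals[i, j, ] <- lc
      flg[i, j, ] <- attr(lc, "flags")
    }
  }
  new("LcmTensor", values = vals, centers = centers, r = as.integer(r),
      deformable = deformable, targetIds = tids, baseIds = bids, flags = flg)
}

makeReport <- function(predicted, voteFractions, targetIds, baseIds,
                       tieFlags, method) {
  correct <- predicted == targetIds
  total <- length(targetIds)
  rate <- identificationRate(sum(correct), total)
  rownames(voteFractions) <- targetIds
  colnames(voteFractions) <- baseIds
  new("IdentificationReport",
      predicted = predicted, voteFractions = voteFractions,
      correct = correct, ratePercent = rate, tieFlags = tieFlags,
      method = method)
}

#' Vertex-wise majority-voting identification
#'
#' At every sampled centre each target votes for the base subject with the
#' highest local correlation (per-centre ties split the vote equally); the
#' predicted identity is the subject with the most votes. A global vote tie
#' resolves to the lowest base-subject index and raises a tie flag.
#'
#' @param tensor an [LcmTensor-class]
#' @param mask optional logical over centres, selecting the voting centres
#'   (used e.g. for network-restricted identification)
#' @return an [IdentificationReport-class]; vote-fraction rows sum to 1
#' @export
identifyVertexwise <- function(tensor, mask = NULL) {
  d <- dim(tensor@values)
  sel <- if (is.null(mask)) seq_len(d[3]) else which(mask)
  if (!length(sel)) stop("mask selects no centres")
  nT <- d[1]; nB <- d[2]
  votes <- matrix(0, nT, nB)
  for (i in seq_len(nT)) {
    M <- matrix(tensor@values[i, , sel], nrow = nB)
    cmax <- apply(M, 2, max)
    ismax <- M == rep(cmax, each = nB)
    share <- 1 / colSums(ismax)
    votes[i, ] <- as.numeric(ismax %*% share)
  }
  frac <- votes / length(sel)
  pickLowest(frac, tensor, "vertex")
}

pickLowest <- function(scores, tensor, method) {
  nT <- nrow(scores)
  pred <- character(nT)
  tie <- logical(nT)
  for (i in seq_len(nT)) {
    mx <- max(scores[i, ])
    w <- which(scores[i, ] == mx)
    pred[i] <- tensor@baseIds[w[1]]
    tie[i] <- length(w) > 1
  }
  makeReport(pred, scores, tensor@targetIds, tensor@baseIds, tie, method)
}

#' Average-based identification
#'
#' Reduces every local correlation map to its mean over centres and picks
#' the base subject with the highest mean: the global (single-similarity)
#' alternative to the vertex-wise vote.
#'
#' @inheritParams identifyVertexwise
#' @return an [IdentificationReport-class]; the rows of `voteFractions`
#'   carry the mean similarities (not vote shares)
#' @export
identifyAverage <- function(tensor, mask = NULL) {
  d <- dim(tensor@values)
  sel <- if (is.null(mask)) seq_len(d[3]) else which(mask)
  if (!length(sel)) stop("mask selects no centres")
  means <- apply(tensor@values[, , sel, drop = FALSE], c(1, 2), mean)
  pickLowest(means, tensor, "average")
}

#' Identification rate in percent
#'
#' Rounded half-up to one decimal, the convention of the printed rates
#' (e.g. 101 correct out of 103 is 98.1).
#'
#' @param correct number of correctly identified targets
#' @param total number of targets (> 0)
#' @return percentage with one decimal
#' @examples
#' identificationRate(103, 103) # 100
#' identificationRate(101, 103) # 98.1
#' @export
identificationRate <- function(correct, total) {
  if (total <= 0) stop("total must be > 0")
  if (correct < 0 || correct > total) stop("need 0 <= correct <= total")
  floor(1000 * correct / total + 0.5) / 10
}

#' Network-restricted identification
#'
#' Vertex-wise identification using only the centres whose vertex belongs to
#' one functional network; the per-network rate measures that network's
#' discriminability.
#'
#' @param tensor an [LcmTensor-class]
#' @param labels per-vertex network ids (full mesh length)
#' @param network the network id to restrict to
#' @return an [IdentificationReport-class]
#' @export
identifyByNetwork <- function(tensor, labels, network) {
  mask <- labels[tensor@centers] == network
  if (!any(mask)) stop("network has no sampled centres")
  identifyVertexwise(tensor, mask)
}

#' Flattened upper-triangle functional connectome
#'
#' ROI-mean time series, ROI x ROI Pearson matrix, strict upper triangle
#' flattened row-major: the classic atlas-based fingerprint vector of length
#' m(m-1)/2.
#'
#' @param bold a [BoldMatrix-class] or vertices x timepoints matrix
#' @param roiLabels per-vertex region ids (factor or integer); every declared
#'   region must contain at least one vertex
#' @return numeric vector of length m(m-1)/2
#' @export
connectomeVector <- function(bold, roiLabels) {
  x <- if (is(bold, "BoldMatrix")) bold@values else as.matrix(bold)
  f <- if (is.factor(roiLabels)) roiLabels else factor(roiLabels)
  if (any(table(f) == 0)) stop("region with zero vertices")
  m <- nlevels(f)
  if (m < 2) stop("need at least 2 regions")
  roiTs <- rowsum(x, f) / as.vector(table(f))
  C <- stats::cor(t(roiTs))
  t(C)[lower.tri(C)]
}

#' Connectome-based identification
#'
#' Each target vector is matched to the base vector with the highest Pearson
#' correlation. Constant vectors are never selected (flagged); ties resolve
#' to the lowest base index with a flag.
#'
#' @param targetVecs,baseVecs matrices with one connectome vector per row
#'   (rownames are subject ids) or named lists of vectors
#' @return an [IdentificationReport-class]; `voteFractions` rows carry the
#'   correlations
#' @export
identifyConnectome <- function(targetVecs, baseVecs) {
  asMat <- function(x) if (is.list(x)) do.call(rbind, x) else as.matrix(x)
  TT <- asMat(targetVecs)
  BB <- asMat(baseVecs)
  if (ncol(TT) != ncol(BB)) stop("vector lengths differ")
  tids <- rownames(TT); bids <- rownames(BB)
  if (is.null(tids) || is.null(bids)) stop("subject ids (rownames/names) required")
  sims <- matrix(-Inf, nrow(TT), nrow(BB))
  sdT <- apply(TT, 1, stats::sd)
  sdB <- apply(BB, 1, stats::sd)
  ok <- sdB > 0
  for (i in seq_len(nrow(TT))) {
    if (sdT[i] > 0 && any(ok))
      sims[i, ok] <- as.numeric(stats::cor(TT[i, ], t(BB[ok, , drop = FALSE])))
  }
  fakeTensor <- new("LcmTensor",
    values = array(0, c(nrow(TT), nrow(BB), 1)),
    centers = 1L, r = 1L, deformable = FALSE,
    targetIds = tids, baseIds = bids,
    flags = array(FALSE, c(nrow(TT), nrow(BB), 1))
  )
  rep <- pickLowest(sims, fakeTensor, "connectome")
  rep
}
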