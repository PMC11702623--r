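## Ground-truthed synthetic cohorts on spherical meshes: geodesic Voronoi
## parcellations with per-subject seed jitter, parcel-driven BOLD, boundary
## templates with session (and phase-encoding) noise, and scores linearly
## coupled to chosen boundary features. Every generator is a deterministic
## function of its seed.

#' Cohort specification
#'
#' Bundles the generator parameters with their defaults: a two-session
#' cohort whose subjects share a group parcellation up to a per-subject
#' seed jitter (individuality), with additive Gaussian session noise on the
#' LGM amplitude (session gap), and optional parcel-driven BOLD.
#'
#' @param nSubjects number of subjects
#' @param sessionsPerSubject sessions per subject (>= 2)
#' @param meshLevel icosphere subdivision level
#' @param nParcels number of Voronoi parcels k
#' @param subjectJitterHops per-subject seed-vertex perturbation radius
#'   (hops; 0 = identical parcellations)
#' @param sessionNoiseSigma additive Gaussian noise sd on the LGM template
#'   (dimensionless, template amplitude is 1)
#' @param pedNoiseSigma extra per-acquisition noise sd; when > 0 each
#'   session yields an AP and a PA map instead of a single one
#' @param boldTimepoints timepoints T for generated BOLD
#' @param boldSnr BOLD signal-to-noise ratio (noise sd = 1/snr; may be `Inf`)
#' @param masterSeed master RNG seed
#' @return a validated list of class `"CohortSpec"`
#' @export
cohortSpec <- function(nSubjects = 20, sessionsPerSubject = 2, meshLevel = 3,
                       nParcels = 6, subjectJitterHops = 2,
                       sessionNoiseSigma = 0.1, pedNoiseSigma = 0,
                       boldTimepoints = 200, boldSnr = 5, masterSeed = 1) {
  spec <- list(
    nSubjects = as.integer(nSubjects),
    sessionsPerSubject = as.integer(sessionsPerSubject),
    meshLevel = as.integer(meshLevel), nParcels = as.integer(nParcels),
    subjectJitterHops = as.integer(subjectJitterHops),
    sessionNoiseSigma = sessionNoiseSigma, pedNoiseSigma = pedNoiseSigma,
    boldTimepoints = as.integer(boldTimepoints), boldSnr = boldSnr,
    masterSeed = as.integer(masterSeed)
  )
  stopifnot(
    spec$nSubjects >= 1, spec$sessionsPerSubject >= 2, spec$meshLevel >= 0,
    spec$nParcels >= 2, spec$subjectJitterHops >= 0,
    spec$sessionNoiseSigma >= 0, spec$pedNoiseSigma >= 0,
    spec$boldTimepoints >= 10, spec$boldSnr > 0
  )
  class(spec) <- "CohortSpec"
  spec
}

#' Geodesic Voronoi parcellation of a mesh
#'
#' Grows k regions by multi-source breadth-first search (hop-distance
#' Voronoi) from k seed vertices drawn without replacement; equidistant
#' vertices go to the lowest seed index. With `jitterHops > 0` each given
#' base seed is first moved uniformly within its `jitterHops`-ring
#' neighbourhood (per-subject individuality).
#'
#' @param mesh a [SphericalMesh-class]
#' @param k number of parcels (2 <= k <= vertex count)
#' @param seed RNG seed
#' @param jitterHops seed perturbation radius in hops
#' @param baseSeeds optional fixed seed vertices to jitter (length k); drawn
#'   at random when NULL
#' @return integer region labels per vertex (1..k), with the seed vertices
#'   in `attr(, "seeds")`
#' @export
simulateParcellation <- function(mesh, k, seed, jitterHops = 0,
                                 baseSeeds = NULL) {
  V <- nVertices(mesh)
  if (k < 2 || k > V) stop("need 2 <= k <= vertex count")
  set.seed(as.integer(seed))
  if (is.null(baseSeeds)) baseSeeds <- sample.int(V, k)
  seeds <- integer(k)
  taken <- logical(V)
  for (i in seq_len(k)) {
    if (jitterHops > 0) {
      cand <- rRingIndices(mesh, baseSeeds[i], jitterHops)
    } else {
      cand <- baseSeeds[i]
    }
    cand <- cand[!taken[cand]]
    seeds[i] <- if (length(cand) == 1) cand else sample(cand, 1)
    taken[seeds[i]] <- TRUE
  }
  labels <- rep.int(NA_integer_, V)
  labels[seeds] <- seq_len(k)
  frontier <- seeds
  rings <- mesh@rings
  while (length(frontier)) {
    cand_v <- integer(0)
    cand_l <- integer(0)
    for (u in frontier) {
      nb <- rings[[u]]
      nb <- nb[is.na(labels[nb])]
      if (length(nb)) {
        cand_v <- c(cand_v, nb)
        cand_l <- c(cand_l, rep.int(labels[u], length(nb)))
      }
    }
    if (!length(cand_v)) break
    ord <- order(cand_v, cand_l)   # ties resolved to the lowest seed index
    cand_v <- cand_v[ord]; cand_l <- cand_l[ord]
    first <- !duplicated(cand_v)
    labels[cand_v[first]] <- cand_l[first]
    frontier <- cand_v[first]
  }
  attr(labels, "seeds") <- seeds
  labels
}

#' Parcel-driven synthetic BOLD
#'
#' Each parcel gets an independent standard-Gaussian latent time series;
#' every vertex observes its parcel's series plus Gaussian noise of sd
#' 1/snr. `snr = Inf` gives noiseless parcel signals.
#'
#' @param mesh a [SphericalMesh-class]
#' @param labels integer parcel label per vertex
#' @param T timepoints (>= 10)
#' @param snr signal-to-noise ratio (> 0)
#' @param seed RNG seed
#' @param subjectId,sessionId,ped scan identity passed to the result
#' @return a [BoldMatrix-class]
#' @export
simulateBold <- function(mesh, labels, T, snr, seed,
                         subjectId = "s1", sessionId = "ses1", ped = "NA") {
  if (T < 10) stop("need T >= 10")
  if (!(snr > 0)) stop("snr must be > 0")
  V <- nVertices(mesh)
  if (length(labels) != V) stop("labels length != vertex count")
  set.seed(as.integer(seed))
  k <- max(labels)
  latent <- matrix(stats::rnorm(k * T), k, T)
  noise <- if (is.finite(snr))
    matrix(stats::rnorm(V * T, sd = 1 / snr), V, T)
  else matrix(0, V, T)
  boldMatrix(latent[labels, , drop = FALSE] + noise,
             subjectId = subjectId, sessionId = sessionId, ped = ped)
}

# indicator of vertices with a differently-labeled 1-ring neighbour
borderIndicator <- function(mesh, labels) {
  edges <- meshEdges(mesh)
  out <- logical(nVertices(mesh))
  out[edges[labels[edges[, 1]] != labels[edges[, 2]], 1]] <- TRUE
  as.numeric(out)
}

# iterated 1-ring mean filter (centre included)
smoothMap <- function(mesh, x, passes) {
  ops <- meshOps(mesh)
  for (p in seq_len(passes)) {
    x <- (x + rowsum(x[ops$u], ops$v, reorder = FALSE)[, 1]) / (ops$deg + 1)
  }
  x
}

#' Simulate an LGM cohort with ground truth
#'
#' Per subject: a jittered Voronoi parcellation, whose parcel-border
#' indicator smoothed by two passes of 1-ring mean filtering and rescaled to
#' \[0, 1\] is the subject's LGM template. Per session, the observed LGM is
#' the template plus Gaussian session noise, clipped to \[0, 1\] (two maps
#' tagged AP/PA with extra acquisition noise when `pedNoiseSigma > 0`).
#' With `generateBold = TRUE` each session also carries a parcel-driven
#' BOLD matrix with a session-specific noise seed.
#'
#' @param spec a [cohortSpec()]
#' @param generateBold also generate per-session BOLD matrices
#' @return list of class `"SimulatedCohort"`: `spec`, `mesh`, `groupLabels`
#'   (jitter-free group parcellation), per-subject entries with `labels`,
#'   `template` ([VertexMap-class]), per-session `lgm` maps (and `bold`),
#'   and a `truth` manifest of all seeds
#' @export
simulateLgmCohort <- function(spec, generateBold = FALSE) {
  stopifnot(inherits(spec, "CohortSpec"))
  mesh <- makeIcosphere(spec$meshLevel)
  V <- nVertices(mesh)
  set.seed(spec$masterSeed)
  baseSeeds <- sample.int(V, spec$nParcels)
  subSeeds <- sample.int(.Machine$integer.max, spec$nSubjects)
  noiseSeeds <- matrix(
    sample.int(.Machine$integer.max, spec$nSubjects * spec$sessionsPerSubject),
    spec$nSubjects, spec$sessionsPerSubject
  )
  boldSeeds <- matrix(
    sample.int(.Machine$integer.max, spec$nSubjects * spec$sessionsPerSubject),
    spec$nSubjects, spec$sessionsPerSubject
  )
  groupLabels <- simulateParcellation(mesh, spec$nParcels, spec$masterSeed,
                                      jitterHops = 0, baseSeeds = baseSeeds)
  subjects <- vector("list", spec$nSubjects)
  names(subjects) <- sprintf("sub%03d", seq_len(spec$nSubjects))
  for (i in seq_len(spec$nSubjects)) {
    labels <- simulateParcellation(mesh, spec$nParcels, subSeeds[i],
                                   jitterHops = spec$subjectJitterHops,
                                   baseSeeds = baseSeeds)
    tmpl <- smoothMap(mesh, borderIndicator(mesh, labels), 2)
    if (max(tmpl) > 0) tmpl <- tmpl / max(tmpl)
    sessions <- vector("list", spec$sessionsPerSubject)
    names(sessions) <- sprintf("ses%d", seq_len(spec$sessionsPerSubject))
    bold <- if (generateBold) sessions else NULL
    for (s in seq_len(spec$sessionsPerSubject)) {
      set.seed(noiseSeeds[i, s])
      base <- tmpl + stats::rnorm(V, 0, spec$sessionNoiseSigma)
      if (spec$pedNoiseSigma > 0) {
        ap <- pmin(pmax(base + stats::rnorm(V, 0, spec$pedNoiseSigma), 0), 1)
        pa <- pmin(pmax(base + stats::rnorm(V, 0, spec$pedNoiseSigma), 0), 1)
        sessions[[s]] <- list(
          AP = vertexMap(ap, "lgm", spec$meshLevel),
          PA = vertexMap(pa, "lgm", spec$meshLevel)
        )
      } else {
        sessions[[s]] <- vertexMap(pmin(pmax(base, 0), 1), "lgm",
                                   spec$meshLevel)
      }
      if (generateBold) {
        bold[[s]] <- simulateBold(
          mesh, labels, spec$boldTimepoints, spec$boldSnr, boldSeeds[i, s],
          subjectId = names(subjects)[i], sessionId = names(sessions)[s]
        )
      }
    }
    subjects[[i]] <- list(
      labels = labels, border = borderIndicator(mesh, labels),
      template = vertexMap(tmpl, "lgm", spec$meshLevel),
      sessions = sessions, bold = bold
    )
  }
  structure(
    list(spec = spec, mesh = mesh, groupLabels = groupLabels,
         subjects = subjects,
         truth = list(baseSeeds = baseSeeds, subjectSeeds = subSeeds,
                      noiseSeeds = noiseSeeds, boldSeeds = boldSeeds)),
    class = "SimulatedCohort"
  )
}

#' Extract a session's LGM set from a simulated cohort
#'
#' @param cohort a `SimulatedCohort`
#' @param session session index
#' @param ped which acquisition to take when the cohort has AP/PA maps:
#'   `"AP"`, `"PA"` or `"mean"`
#' @return named list of [VertexMap-class]s keyed by subject id
#' @export
cohortLgmSet <- function(cohort, session, ped = "mean") {
  lapply(cohort$subjects, function(su) {
    m <- su$sessions[[session]]
    if (is.list(m)) {
      switch(ped, AP = m$AP, PA = m$PA, mean = averageSessionLgm(m$AP, m$PA))
    } else m
  })
}

#' Scores linearly coupled to causal boundary features
#'
#' `score = a * (sum of causal positive features) - a * (sum of causal
#' negative features) + Gaussian noise`. When `noiseSd` is NULL it is
#' derived from `targetR2`: the noise sd that makes the linear signal
#' explain the requested fraction of score variance
#' (`noiseSd = sd(signal) * sqrt((1 - R2) / R2)`).
#'
#' @param features scans x boundaries matrix (boundary-id column names)
#' @param causalPositive,causalNegative causal boundary ids (must exist in
#'   `colnames(features)`)
#' @param effect linear effect size a
#' @param noiseSd Gaussian noise sd (overrides `targetR2` when given)
#' @param targetR2 population fraction of variance explained by the signal
#' @param seed RNG seed
#' @return list with `scores` and a `truth` record (causal sets, effect,
#'   noiseSd, seed)
#' @export
simulateScores <- function(features, causalPositive, causalNegative = character(),
                           effect = 1, noiseSd = NULL, targetR2 = 0.36,
                           seed = 1) {
  features <- as.matrix(features)
  unknown <- setdiff(c(causalPositive, causalNegative), colnames(features))
  if (length(unknown)) stop("unknown boundary id(s): ",
                            paste(unknown, collapse = ", "))
  signal <- effect * rowSums(features[, causalPositive, drop = FALSE]) -
    effect * rowSums(features[, causalNegative, drop = FALSE])
  if (is.null(noiseSd)) {
    if (is.null(targetR2) || targetR2 <= 0 || targetR2 > 1)
      stop("targetR2 must be in (0, 1] when noiseSd is NULL")
    noiseSd <- stats::sd(signal) * sqrt((1 - targetR2) / targetR2)
  }
  set.seed(as.integer(seed))
  scores <- signal + stats::rnorm(length(signal), 0, noiseSd)
  list(scores = scores,
       truth = list(causalPositive = causalPositive,
                    causalNegative = causalNegative, effect = effect,
                    noiseSd = noiseSd, seed = as.integer(seed)))
}

#' Simulate a full boundary-feature prediction study
#'
#' Builds a two-session LGM cohort, a boundary atlas on the group
#' parcellation with a ten-network assignment, per-scan boundary features,
#' and scores causally coupled to two boundaries. The causal boundaries are
#' two disjoint adjacent region pairs with maximally separated (dilated)
#' masks, both assigned to network 1 — one drives the score positively, the
#' other negatively — so exactly one network carries the causal signal and
#' leave-one-network-out analyses have a known answer. Remaining regions
#' are dealt round-robin to networks 2..10.
#'
#' @param nSubjects subjects (two sessions each; scans = 2 x subjects)
#' @param meshLevel,nParcels,subjectJitterHops,sessionNoiseSigma cohort
#'   parameters, see [cohortSpec()]
#' @param dilationIters boundary dilation (default 3)
#' @param targetR2 population fraction of score variance explained by the
#'   causal signal
#' @param masterSeed cohort seed
#' @param scoreSeed score-noise seed
#' @return list with `cohort`, `atlas`, `features` (scans x boundaries),
#'   `scores`, `causalPositive`, `causalNegative`, `causalNetwork` (1),
#'   `scanIds`
#' @export
simulatePredictionStudy <- function(nSubjects = 70, meshLevel = 3,
                                    nParcels = 18, subjectJitterHops = 2,
                                    sessionNoiseSigma = 0.1,
                                    dilationIters = 3, targetR2 = 0.36,
                                    masterSeed = 1, scoreSeed = 1) {
  spec <- cohortSpec(
    nSubjects = nSubjects, meshLevel = meshLevel, nParcels = nParcels,
    subjectJitterHops = subjectJitterHops,
    sessionNoiseSigma = sessionNoiseSigma, masterSeed = masterSeed
  )
  cohort <- simulateLgmCohort(spec)
  mesh <- cohort$mesh
  lab <- cohort$groupLabels
  base <- buildBoundaryAtlas(lab, mesh, dilationIters = dilationIters)
  pairs <- base@boundaryRegions
  cent <- t(vapply(base@boundaryMasks, function(mm)
    colMeans(mesh@coords[mm, , drop = FALSE]), numeric(3)))
  best <- c(1L, 2L)
  bd <- -Inf
  for (i in seq_len(nrow(pairs))) {
    for (j in seq_len(nrow(pairs))) {
      if (length(intersect(pairs[i, ], pairs[j, ]))) next
      d <- sum((cent[i, ] - cent[j, ])^2)
      if (d > bd) { bd <- d; best <- c(i, j) }
    }
  }
  p1 <- pairs[best[1], ]
  p2 <- pairs[best[2], ]
  regions <- sort(unique(lab))
  netOf <- stats::setNames(integer(length(regions)), regions)
  netOf[as.character(c(p1, p2))] <- 1L
  rest <- setdiff(regions, c(p1, p2))
  netOf[as.character(rest)] <- rep(2:10, length.out = length(rest))
  atlas <- buildBoundaryAtlas(lab, mesh, networkOfRegion = netOf,
                              dilationIters = dilationIters)
  features <- do.call(rbind, lapply(cohort$subjects, function(su)
    do.call(rbind, lapply(su$sessions, boundaryFeatures, atlas = atlas))))
  scanIds <- as.vector(t(outer(names(cohort$subjects),
                               names(cohort$subjects[[1]]$sessions),
                               paste, sep = "_")))
  rownames(features) <- scanIds
  causalPositive <- paste0(p1[1], "_", p1[2])
  causalNegative <- paste0(p2[1], "_", p2[2])
  sc <- simulateScores(features, causalPositive, causalNegative,
                       effect = 10, targetR2 = targetR2, seed = scoreSeed)
  list(cohort = cohort, atlas = atlas, features = features,
       scores = sc$scores, causalPositive = causalPositive,
       causalNegative = causalNegative, causalNetwork = 1L,
       scanIds = scanIds, truth = sc$truth)
}

#' Resample a vertex map under a global rotation
#'
#' Rotates the sphere by `angleDeg` about `axis` and resamples the map by
#' nearest vertex: the rotated map's value at v is the original value at the
#' vertex nearest to the pulled-back position of v. Emulates a residual
#' registration misalignment between sessions; an angle near one edge length
#' displaces every vertex by roughly one ring step.
#'
#' @param map per-vertex values
#' @param mesh a [SphericalMesh-class]
#' @param angleDeg rotation angle in degrees
#' @param axis rotation axis (3-vector, need not be unit)
#' @return a [VertexMap-class] with the same kind
#' @export
rotateLgmMap <- function(map, mesh, angleDeg, axis = c(0, 0, 1)) {
  v <- asMapValues(map)
  kind <- if (is(map, "VertexMap")) map@kind else "generic"
  a <- axis / sqrt(sum(axis^2))
  th <- -angleDeg * pi / 180   # pull-back rotation
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  pulled <- mesh@coords %*% t(R)
  nearest <- max.col(pulled %*% t(mesh@coords), ties.method = "first")
  vertexMap(v[nearest], kind = kind, meshLevel = mesh@level)
}
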