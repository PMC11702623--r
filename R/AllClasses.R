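#' @import methods
NULL

#' Icosahedral spherical triangle mesh
#'
#' A unit-sphere triangle mesh obtained by repeated midpoint subdivision of
#' the regular icosahedron. The mesh at level \eqn{L} has \eqn{10 \cdot 4^L + 2}
#' vertices, of which exactly 12 (the original icosahedron vertices) have five
#' neighbours and the rest have six. Vertices of level \eqn{L-1} occupy the
#' first \eqn{10 \cdot 4^{L-1} + 2} indices of level \eqn{L}, so coarser
#' meshes are nested index prefixes of finer ones.
#'
#' @slot coords numeric matrix, one unit-norm xyz row per vertex.
#' @slot triangles integer matrix, one outward-oriented vertex triple per row.
#' @slot rings list of integer vectors: for each vertex its 1-hop neighbours in
#'   cyclic order (induced by the outward triangle fans), starting at the
#'   lowest-index neighbour.
#' @slot level integer subdivision depth (0 = icosahedron).
#'
#' @seealso [makeIcosphere()], [rRingIndices()], [neighborRings()]
#' @export
setClass("SphericalMesh",
  representation(
    coords    = "matrix",
    triangles = "matrix",
    rings     = "list",
    level     = "integer"
  )
)

setValidity("SphericalMesh", function(object) {
  msg <- character()
  V <- nrow(object@coords)
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be a V x 3 matrix")
  if (V != 10L * 4L^object@level + 2L)
    msg <- c(msg, sprintf("vertex count %d != 10*4^%d + 2", V, object@level))
  nrm <- sqrt(rowSums(object@coords^2))
  if (any(abs(nrm - 1) > 1e-9)) msg <- c(msg, "vertex norms deviate from 1")
  if (length(object@rings) != V) msg <- c(msg, "rings length != vertex count")
  deg <- lengths(object@rings)
  if (sum(deg == 5L) != 12L || any(!deg %in% c(5L, 6L)))
    msg <- c(msg, "expected exactly 12 degree-5 vertices, rest degree-6")
  nE <- 3L * nrow(object@triangles) / 2L
  if (V - nE + nrow(object@triangles) != 2L)
    msg <- c(msg, "Euler characteristic V - E + F != 2")
  if (length(msg)) msg else TRUE
})

#' @describeIn SphericalMesh compact description
#' @param object a `SphericalMesh`
#' @export
setMethod("show", "SphericalMesh", function(object) {
  cat(sprintf(
    "SphericalMesh: level %d, %d vertices, %d triangles (12 pentagons)\n",
    object@level, nrow(object@coords), nrow(object@triangles)
  ))
})

#' Per-vertex scalar map
#'
#' One real value per mesh vertex; the common currency between pipeline
#' stages. `kind` tags the semantics: `"lgm"` maps live in \[0, 1\] (boundary
#' frequencies), `"gradient"` maps are nonnegative, others are unconstrained.
#'
#' @slot values numeric vector, one value per vertex.
#' @slot kind one of `"gradient"`, `"lgm"`, `"lcm"`, `"uniqueness"`, `"dp"`,
#'   `"generic"`.
#' @slot meshLevel integer level of the mesh the map lives on.
#' @export
setClass("VertexMap",
  representation(values = "numeric", kind = "character", meshLevel = "integer")
)

setValidity("VertexMap", function(object) {
  msg <- character()
  if (length(object@kind) != 1L ||
      !object@kind %in% c("gradient", "lgm", "lcm", "uniqueness", "dp", "generic"))
    msg <- c(msg, "invalid kind tag")
  if (length(object@values) != 10 * 4^object@meshLevel + 2)
    msg <- c(msg, "values length inconsistent with meshLevel")
  if (identical(object@kind, "lgm")) {
    ok <- is.finite(object@values)
    if (any(object@values[ok] < -1e-12 | object@values[ok] > 1 + 1e-12))
      msg <- c(msg, "lgm values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn VertexMap compact description
#' @param object a `VertexMap`
#' @export
setMethod("show", "VertexMap", function(object) {
  cat(sprintf(
    "VertexMap (%s): level %d, %d vertices, range [%.4g, %.4g]\n",
    object@kind, object@meshLevel, length(object@values),
    min(object@values), max(object@values)
  ))
})

#' Surface-mapped BOLD matrix for one scan
#'
#' @slot values numeric matrix, vertices x timepoints.
#' @slot subjectId,sessionId scan identity.
#' @slot ped phase-encoding tag, one of `"AP"`, `"PA"`, `"NA"`.
#' @export
setClass("BoldMatrix",
  representation(
    values = "matrix", subjectId = "character",
    sessionId = "character", ped = "character"
  )
)

setValidity("BoldMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) < 2L) msg <- c(msg, "need at least 2 timepoints")
  if (any(!is.finite(object@values))) msg <- c(msg, "non-finite BOLD entries")
  if (!object@ped %in% c("AP", "PA", "NA")) msg <- c(msg, "ped must be AP/PA/NA")
  if (length(msg)) msg else TRUE
})

#' @describeIn BoldMatrix compact description
#' @param object a `BoldMatrix`
#' @export
setMethod("show", "BoldMatrix", function(object) {
  cat(sprintf(
    "BoldMatrix: subject %s session %s (%s), %d vertices x %d timepoints\n",
    object@subjectId, object@sessionId, object@ped,
    nrow(object@values), ncol(object@values)
  ))
})

#' Local correlation tensor
#'
#' `values[i, j, v]` is the local (patch-wise Pearson) correlation between
#' target map i and base map j at sampled centre v. Centres are vertex
#' indices into the mesh; `flags` records centres where a constant patch made
#' the correlation undefined (stored as 0).
#'
#' @slot values numeric array, targets x bases x centres.
#' @slot centers integer vertex indices of the sampled centres (1-based).
#' @slot r integer patch radius (ring count).
#' @slot deformable logical; whether the deformable strategy was used.
#' @slot targetIds,baseIds subject identifiers along the first two axes.
#' @slot flags logical array marking undefined-correlation entries.
#' @export
setClass("LcmTensor",
  representation(
    values = "array", centers = "integer", r = "integer",
    deformable = "logical", targetIds = "character", baseIds = "character",
    flags = "array"
  )
)

setValidity("LcmTensor", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "values must be a 3-d array")
  else {
    if (d[1] != length(object@targetIds)) msg <- c(msg, "targetIds length mismatch")
    if (d[2] != length(object@baseIds)) msg <- c(msg, "baseIds length mismatch")
    if (d[3] != length(object@centers)) msg <- c(msg, "centers length mismatch")
    ok <- is.finite(object@values)
    if (any(abs(object@values[ok]) > 1 + 1e-9))
      msg <- c(msg, "correlation entries outside [-1, 1]")
  }
  if (anyDuplicated(object@targetIds)) msg <- c(msg, "duplicate target subject ids")
  if (anyDuplicated(object@baseIds)) msg <- c(msg, "duplicate base subject ids")
  if (length(msg)) msg else TRUE
})

#' @describeIn LcmTensor compact description
#' @param object an `LcmTensor`
#' @export
setMethod("show", "LcmTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "LcmTensor: %d targets x %d bases x %d centers (r = %d, %s)\n",
    d[1], d[2], d[3], object@r,
    if (object@deformable) "deformable" else "vanilla"
  ))
})

#' Identification result
#'
#' @slot predicted predicted base subject id per target.
#' @slot voteFractions targets x base-subjects matrix of vote fractions
#'   (rows sum to 1); for average-based and connectome identification the
#'   rows hold the similarity scores instead and do not sum to 1.
#' @slot correct logical per target (NA when truth unknown).
#' @slot ratePercent identification rate in percent, one decimal, or NA.
#' @slot tieFlags logical per target: global tie resolved to lowest index.
#' @slot method one of `"vertex"`, `"average"`, `"connectome"`.
#' @export
setClass("IdentificationReport",
  representation(
    predicted = "character", voteFractions = "matrix", correct = "logical",
    ratePercent = "numeric", tieFlags = "logical", method = "character"
  )
)

#' @describeIn IdentificationReport compact description
#' @param object an `IdentificationReport`
#' @export
setMethod("show", "IdentificationReport", function(object) {
  cat(sprintf(
    "IdentificationReport (%s): %d targets, rate %s%%\n",
    object@method, length(object@predicted),
    ifelse(is.na(object@ratePercent), "NA", format(object@ratePercent))
  ))
})

#' Parcellation boundary atlas
#'
#' Region labels per vertex, region-to-network assignment, and per
#' region-pair boundary vertex masks after dilation. A vertex lies on the
#' undilated boundary of pair (a, b) iff it carries label a or b and has a
#' 1-ring neighbour with the other label; each mask is then dilated
#' `dilationIters` times. A vertex may belong to several masks.
#'
#' @slot regionLabels integer region id per vertex.
#' @slot networkOfRegion named integer: region id -> network id.
#' @slot boundaryMasks named list of logical per-vertex masks; names are
#'   `"a_b"` with a < b the unordered region pair.
#' @slot boundaryRegions integer matrix, one (a, b) row per mask.
#' @slot dilationIters integer dilation count applied to the masks.
#' @export
setClass("BoundaryAtlas",
  representation(
    regionLabels = "integer", networkOfRegion = "integer",
    boundaryMasks = "list", boundaryRegions = "matrix",
    dilationIters = "integer"
  )
)

#' @describeIn BoundaryAtlas compact description
#' @param object a `BoundaryAtlas`
#' @export
setMethod("show", "BoundaryAtlas", function(object) {
  cat(sprintf(
    "BoundaryAtlas: %d regions, %d networks, %d boundaries (dilated x%d)\n",
    length(unique(object@regionLabels)),
    length(unique(object@networkOfRegion)),
    length(object@boundaryMasks), object@dilationIters
  ))
})

#' Cross-validated prediction result
#'
#' @slot predictions per-scan prediction averaged over iterations.
#' @slot observed observed scores.
#' @slot rValue Pearson correlation between predictions and observed scores.
#' @slot selections per iteration, per fold: selected positive / negative
#'   boundary ids and held-out row indices.
#' @slot seed master seed used.
#' @slot params list of run parameters (iterations, folds, trees, minLeaf).
#' @export
setClass("CvResult",
  representation(
    predictions = "numeric", observed = "numeric", rValue = "numeric",
    selections = "list", seed = "integer", params = "list"
  )
)

#' @describeIn CvResult compact description
#' @param object a `CvResult`
#' @export
setMethod("show", "CvResult", function(object) {
  cat(sprintf(
    "CvResult: %d scans, %d iterations x %d folds, r = %.3f\n",
    length(object@predictions), object@params$iterations,
    object@params$folds, object@rValue
  ))
})
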