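#' Number of vertices
#' @param x a mesh or map object
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' Mesh subdivision level
#' @param x a mesh or map object
#' @export
setGeneric("meshLevel", function(x) standardGeneric("meshLevel"))

#' Vertex coordinates (V x 3, unit norm)
#' @param x a `SphericalMesh`
#' @export
setGeneric("vertexCoords", function(x) standardGeneric("vertexCoords"))

#' Cyclically ordered 1-ring neighbour lists
#' @param x a `SphericalMesh`
#' @export
setGeneric("neighborRings", function(x) standardGeneric("neighborRings"))

#' Triangle index matrix
#' @param x a `SphericalMesh`
#' @export
setGeneric("meshTriangles", function(x) standardGeneric("meshTriangles"))

#' Per-vertex values of a map
#' @param x a `VertexMap`
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Identification rate in percent
#' @param x an `IdentificationReport`
#' @export
setGeneric("ratePercent", function(x) standardGeneric("ratePercent"))

#' Predicted subject ids
#' @param x an `IdentificationReport`
#' @export
setGeneric("predictedIds", function(x) standardGeneric("predictedIds"))

#' Cross-validated prediction accuracy (Pearson r)
#' @param x a `CvResult`
#' @export
setGeneric("rValue", function(x) standardGeneric("rValue"))

#' @rdname nVertices
#' @export
setMethod("nVertices", "SphericalMesh", function(x) nrow(x@coords))
#' @rdname nVertices
#' @export
setMethod("nVertices", "VertexMap", function(x) length(x@values))
#' @rdname nVertices
#' @export
setMethod("nVertices", "BoldMatrix", function(x) nrow(x@values))

#' @rdname meshLevel
#' @export
setMethod("meshLevel", "SphericalMesh", function(x) x@level)
#' @rdname meshLevel
#' @export
setMethod("meshLevel", "VertexMap", function(x) x@meshLevel)

#' @rdname vertexCoords
#' @export
setMethod("vertexCoords", "SphericalMesh", function(x) x@coords)

#' @rdname neighborRings
#' @export
setMethod("neighborRings", "SphericalMesh", function(x) x@rings)

#' @rdname meshTriangles
#' @export
setMethod("meshTriangles", "SphericalMesh", function(x) x@triangles)

#' @rdname mapValues
#' @export
setMethod("mapValues", "VertexMap", function(x) x@values)

#' @rdname ratePercent
#' @export
setMethod("ratePercent", "IdentificationReport", function(x) x@ratePercent)

#' @rdname predictedIds
#' @export
setMethod("predictedIds", "IdentificationReport", function(x) x@predicted)

#' @rdname rValue
#' @export
setMethod("rValue", "CvResult", function(x) x@rValue)

#' Construct a VertexMap
#'
#' @param values numeric vector, one value per vertex.
#' @param kind semantic tag; see [VertexMap-class].
#' @param meshLevel mesh subdivision level; inferred from `length(values)`
#'   when omitted.
#' @return a `VertexMap`
#' @export
vertexMap <- function(values, kind = "generic", meshLevel = NULL) {
  if (is(values, "VertexMap")) return(values)
  values <- as.numeric(values)
  if (is.null(meshLevel)) {
    meshLevel <- levelForCount(length(values))
    if (is.na(meshLevel))
      stop("length(values) = ", length(values),
           " is not an icosphere vertex count; give meshLevel explicitly")
  }
  new("VertexMap", values = values, kind = kind, meshLevel = as.integer(meshLevel))
}

#' Construct a BoldMatrix
#'
#' @param values numeric matrix, vertices x timepoints.
#' @param subjectId,sessionId scan identity strings.
#' @param ped phase-encoding tag (`"AP"`, `"PA"` or `"NA"`).
#' @return a `BoldMatrix`
#' @export
boldMatrix <- function(values, subjectId = "s1", sessionId = "ses1", ped = "NA") {
  new("BoldMatrix", values = as.matrix(values), subjectId = subjectId,
      sessionId = sessionId, ped = ped)
}

# icosphere level for a vertex count, NA if not one
levelForCount <- function(n) {
  lv <- log((n - 2) / 10, base = 4)
  if (n >= 12 && abs(lv - round(lv)) < 1e-9) as.integer(round(lv)) else NA_integer_
}

# values as plain numeric from VertexMap or numeric
asMapValues <- function(x) {
  if (is(x, "VertexMap")) x@values else as.numeric(x)
}
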