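## Local gradient map pipeline: BOLD -> RSFC -> Fisher z -> second-order
## correlation -> per-row surface gradient -> per-row watershed boundary
## map -> mean boundary frequency (the LGM).

#' @useDynLib lgmprint, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Vertex-wise resting-state functional connectivity matrix
#'
#' Pearson correlations of the BOLD time series between all vertex pairs.
#' Zero-variance rows cannot be correlated: their off-diagonal entries are
#' set to 0 (keeping the matrix shape) and the row indices are attached as
#' `attr(, "flaggedRows")`.
#'
#' @param bold a [BoldMatrix-class] or a vertices x timepoints matrix
#' @return symmetric V x V correlation matrix with unit diagonal
#' @export
computeRsfc <- function(bold) {
  x <- if (is(bold, "BoldMatrix")) bold@values else as.matrix(bold)
  sds <- apply(x, 1, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  r <- suppressWarnings(stats::cor(t(x)))
  if (length(bad)) {
    r[bad, ] <- 0
    r[, bad] <- 0
  }
  diag(r) <- 1
  attr(r, "flaggedRows") <- bad
  r
}

#' Fisher r-to-z transformation
#'
#' \eqn{z = \frac{1}{2} \log\frac{1+r}{1-r}}, with \eqn{|r|} clipped to
#' \eqn{1 - 10^{-7}} so that unit correlations (e.g. the RSFC diagonal) map
#' to a large finite value instead of infinity.
#'
#' @param r correlation value(s), |r| <= 1
#' @return transformed value(s); an odd, strictly increasing function
#' @export
fisherZ <- function(r) {
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  0.5 * log((1 + r) / (1 - r))
}

#' Second-order correlation matrix
#'
#' Pearson correlation between every pair of rows of a (z-transformed)
#' connectivity matrix. Connectivity maps change gradually along the
#' surface; their pairwise similarity changes sharply at functional area
#' borders, which is what the downstream gradient + watershed steps detect.
#' Constant rows are flagged and their correlations set to 0.
#'
#' @param zRsfc V x V matrix of z-transformed connectivity rows
#' @return symmetric V x V correlation matrix with unit diagonal
#' @export
secondOrderCorr <- function(zRsfc) {
  zRsfc <- as.matrix(zRsfc)
  sds <- apply(zRsfc, 1, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  s <- suppressWarnings(stats::cor(t(zRsfc)))
  if (length(bad)) {
    s[bad, ] <- 0
    s[, bad] <- 0
  }
  diag(s) <- 1
  attr(s, "flaggedRows") <- bad
  s
}

.gradCache <- new.env(parent = emptyenv())

# per-mesh edge arrays for the gradient operator and CSR rings for watershed
meshOps <- function(mesh) {
  key <- as.character(mesh@level)
  if (!is.null(.gradCache[[key]])) return(.gradCache[[key]])
  rings <- mesh@rings
  deg <- lengths(rings)
  v <- rep.int(seq_along(rings), deg)
  u <- unlist(rings, use.names = FALSE)
  d <- sqrt(rowSums((mesh@coords[u, , drop = FALSE] -
                     mesh@coords[v, , drop = FALSE])^2))
  ops <- list(
    v = v, u = u, invd = 1 / d, deg = deg,
    ringStarts = c(0L, cumsum(deg)), ringIdx = u - 1L
  )
  .gradCache[[key]] <- ops
  ops
}

#' Surface gradient magnitude of a vertex map
#'
#' Root-mean-square over the 1-ring neighbours u of the chord-normalized
#' finite differences \eqn{(f(u) - f(v)) / \|x_u - x_v\|}, scaled by
#' \eqn{\sqrt{2}}: each finite difference estimates the directional
#' derivative along its edge, and for ring directions spread evenly around
#' the tangent plane the mean squared projection onto any fixed gradient
#' direction is 1/2, so the \eqn{\sqrt{2}} factor recovers the tangential
#' gradient magnitude. A local, rotation-agnostic estimator.
#'
#' @param map per-vertex values (numeric or [VertexMap-class])
#' @param mesh a [SphericalMesh-class]
#' @return a `VertexMap` of kind `"gradient"`
#' @export
surfaceGradient <- function(map, mesh) {
  f <- asMapValues(map)
  if (length(f) != nVertices(mesh)) stop("map length != vertex count")
  ops <- meshOps(mesh)
  g <- surfaceGradientRaw(f, ops)
  vertexMap(g, kind = "gradient", meshLevel = mesh@level)
}

surfaceGradientRaw <- function(f, ops) {
  dif <- (f[ops$u] - f[ops$v]) * ops$invd
  sqrt(2 * rowsum(dif * dif, ops$v, reorder = FALSE)[, 1] / ops$deg)
}

#' Watershed basins and boundary vertices of a gradient map
#'
#' Priority-flood watershed: seeds are the local minima (a vertex none of
#' whose neighbours is strictly lower; plateau-connected minima share one
#' seed), vertices are flooded in increasing gradient order with ties broken
#' by vertex index, and a vertex whose already-labeled neighbours span two
#' or more basins becomes a boundary vertex. Boundary vertices are excluded
#' from all basins; the resulting binary boundary mask is the "binary
#' boundary map" averaged into the LGM.
#'
#' @param gradient per-vertex gradient values (numeric or [VertexMap-class])
#' @param mesh a [SphericalMesh-class]
#' @return list with `basins` (integer labels, 0 at boundary vertices),
#'   `boundary` (logical mask) and `nBasins`
#' @export
watershedBoundaries <- function(gradient, mesh) {
  g <- asMapValues(gradient)
  if (length(g) != nVertices(mesh)) stop("gradient length != vertex count")
  if (any(!is.finite(g))) stop("gradient must be finite")
  ops <- meshOps(mesh)
  res <- watershed_flood_cpp(g, ops$ringStarts, ops$ringIdx)
  list(basins = res$labels, boundary = res$boundary, nBasins = res$n_basins)
}

#' Local gradient map of one scan
#'
#' Runs the full per-scan pipeline: vertex-wise connectivity
#' ([computeRsfc()]), Fisher z ([fisherZ()]), second-order correlation
#' ([secondOrderCorr()]), then for every second-order row a surface gradient
#' ([surfaceGradient()]) and a watershed boundary map
#' ([watershedBoundaries()]). The LGM value at a vertex is the fraction of
#' rows whose boundary mask marks it, so values lie in \[0, 1\].
#'
#' Above `streamThreshold` vertices the second-order matrix is never
#' materialized: its rows are computed in blocks from the centred z matrix
#' and consumed immediately, keeping memory at O(V x T + V x block).
#'
#' @param bold a [BoldMatrix-class] (or vertices x timepoints matrix)
#' @param mesh the matching [SphericalMesh-class]
#' @param streamThreshold vertex count above which row-block streaming is
#'   used (default 8192)
#' @param blockRows rows per block in streaming mode
#' @return a `VertexMap` of kind `"lgm"`; flagged degenerate rows (zero
#'   variance at either correlation stage) are recorded in
#'   `attr(, "provenance")`
#' @export
computeLgm <- function(bold, mesh, streamThreshold = 8192, blockRows = 512) {
  x <- if (is(bold, "BoldMatrix")) bold@values else as.matrix(bold)
  V <- nVertices(mesh)
  if (nrow(x) != V) stop("BOLD row count != mesh vertex count")
  r <- computeRsfc(x)
  flaggedRsfc <- attr(r, "flaggedRows")
  z <- fisherZ(r)

  ops <- meshOps(mesh)
  counts <- numeric(V)

  if (V <= streamThreshold) {
    s <- secondOrderCorr(z)
    flagged2nd <- attr(s, "flaggedRows")
    for (i in seq_len(V)) {
      g <- surfaceGradientRaw(s[i, ], ops)
      res <- watershed_flood_cpp(g, ops$ringStarts, ops$ringIdx)
      counts <- counts + res$boundary
    }
  } else {
    zc <- z - rowMeans(z)
    rn <- sqrt(rowSums(zc^2))
    flagged2nd <- which(rn == 0)
    rn[rn == 0] <- 1
    zc <- zc / rn
    for (b0 in seq(1L, V, by = blockRows)) {
      b1 <- min(b0 + blockRows - 1L, V)
      blk <- zc[b0:b1, , drop = FALSE] %*% t(zc)
      if (length(flagged2nd)) blk[, flagged2nd] <- 0
      for (bi in seq_len(nrow(blk))) {
        i <- b0 + bi - 1L
        row <- blk[bi, ]
        if (i %in% flagged2nd) row[] <- 0
        row[i] <- 1
        g <- surfaceGradientRaw(row, ops)
        res <- watershed_flood_cpp(g, ops$ringStarts, ops$ringIdx)
        counts <- counts + res$boundary
      }
    }
  }
  out <- vertexMap(counts / V, kind = "lgm", meshLevel = mesh@level)
  attr(out, "provenance") <- list(
    flaggedRsfcRows = flaggedRsfc, flaggedSecondOrderRows = flagged2nd
  )
  out
}

#' Average two phase-encoding LGMs of one session
#'
#' Vertex-wise arithmetic mean of the AP and PA maps; when one acquisition
#' is missing the other is returned unchanged with
#' `attr(, "singleInput") = TRUE`.
#'
#' @param lgmAp,lgmPa `VertexMap`s of kind `"lgm"` (either may be NULL)
#' @return a `VertexMap` of kind `"lgm"`
#' @export
averageSessionLgm <- function(lgmAp, lgmPa) {
  if (is.null(lgmAp) && is.null(lgmPa)) stop("both inputs absent")
  if (is.null(lgmAp) || is.null(lgmPa)) {
    out <- if (is.null(lgmAp)) lgmPa else lgmAp
    attr(out, "singleInput") <- TRUE
    return(out)
  }
  a <- asMapValues(lgmAp)
  b <- asMapValues(lgmPa)
  if (length(a) != length(b)) stop("mismatched map lengths")
  lv <- if (is(lgmAp, "VertexMap")) lgmAp@meshLevel else levelForCount(length(a))
  vertexMap((a + b) / 2, kind = "lgm", meshLevel = lv)
}
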