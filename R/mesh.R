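## Icosahedral spherical meshes and neighborhood operations.
##
## All maps in the package live on these meshes. Subdivision keeps parent
## vertices first and appends edge midpoints in sorted-edge order, so the
## level-(L-1) mesh is always the index prefix of the level-L mesh; uniform
## subsampling and multi-resolution sampling rely on this nesting.

.meshCache <- new.env(parent = emptyenv())

#' Build an icosahedral unit-sphere mesh
#'
#' Starts from the regular icosahedron (12 vertices, 20 outward-oriented
#' triangles) and applies `level` rounds of midpoint subdivision, projecting
#' each new vertex onto the unit sphere. Standard levels reproduce the usual
#' cortical-surface resolutions: level 4 gives 2,562 vertices, level 5 gives
#' 10,242 and level 6 gives 40,962.
#'
#' @param level integer subdivision depth (>= 0).
#' @return a [SphericalMesh-class]
#' @examples
#' m <- makeIcosphere(2)
#' nVertices(m) # 162
#' @export
makeIcosphere <- function(level) {
  if (length(level) != 1L || is.na(level) || level < 0 || level != round(level))
    stop("level must be a single non-negative integer")
  level <- as.integer(level)
  key <- as.character(level)
  if (!is.null(.meshCache[[key]])) return(.meshCache[[key]])

  t <- (1 + sqrt(5)) / 2
  coords <- matrix(c(
    -1,  t,  0,   1,  t,  0,  -1, -t,  0,   1, -t,  0,
     0, -1,  t,   0,  1,  t,   0, -1, -t,   0,  1, -t,
     t,  0, -1,   t,  0,  1,  -t,  0, -1,  -t,  0,  1
  ), ncol = 3, byrow = TRUE)
  coords <- coords / sqrt(rowSums(coords^2))
  tri <- matrix(c(
    1, 12, 6,  1, 6, 2,   1, 2, 8,   1, 8, 11,  1, 11, 12,
    2, 6, 10,  6, 12, 5,  12, 11, 3, 11, 8, 7,  8, 2, 9,
    4, 10, 5,  4, 5, 3,   4, 3, 7,   4, 7, 9,   4, 9, 10,
    5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,   10, 9, 2
  ), ncol = 3, byrow = TRUE)
  tri <- orientOutward(tri, coords)

  if (level > 0L) {
    for (l in seq_len(level)) {
      sub <- subdivideOnce(coords, tri)
      coords <- sub$coords
      tri <- sub$tri
    }
  }
  mesh <- new("SphericalMesh",
    coords = coords, triangles = tri,
    rings = buildRings(tri, nrow(coords)), level = level
  )
  validObject(mesh)
  .meshCache[[key]] <- mesh
  mesh
}

# flip triangles whose normal points inward
orientOutward <- function(tri, coords) {
  a <- coords[tri[, 1], , drop = FALSE]
  b <- coords[tri[, 2], , drop = FALSE]
  c_ <- coords[tri[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  nrm <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  centroid <- (a + b + c_) / 3
  flip <- rowSums(nrm * centroid) < 0
  tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  storage.mode(tri) <- "integer"
  tri
}

# one midpoint-subdivision round; parent vertices keep their indices,
# midpoints are appended in sorted-edge order
subdivideOnce <- function(coords, tri) {
  V <- nrow(coords)
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- (e[, 1] - 1) * V + e[, 2]
  ukey <- sort(unique(key))
  mid <- match(key, ukey) + V            # midpoint index per directed slot
  i <- (ukey - 1) %/% V + 1
  j <- (ukey - 1) %% V + 1
  mc <- coords[i, , drop = FALSE] + coords[j, , drop = FALSE]
  mc <- mc / sqrt(rowSums(mc^2))
  nT <- nrow(tri)
  mab <- mid[seq_len(nT)]
  mbc <- mid[nT + seq_len(nT)]
  mca <- mid[2L * nT + seq_len(nT)]
  newTri <- rbind(
    cbind(tri[, 1], mab, mca),
    cbind(tri[, 2], mbc, mab),
    cbind(tri[, 3], mca, mbc),
    cbind(mab, mbc, mca)
  )
  storage.mode(newTri) <- "integer"
  list(coords = rbind(coords, mc), tri = newTri)
}

# per-vertex cyclic 1-ring, induced by the outward triangle fans and
# rotated to start at the lowest-index neighbour
buildRings <- function(tri, V) {
  v <- c(tri[, 1], tri[, 2], tri[, 3])
  p <- c(tri[, 2], tri[, 3], tri[, 1])
  q <- c(tri[, 3], tri[, 1], tri[, 2])
  ord <- order(v)
  v <- v[ord]; p <- p[ord]; q <- q[ord]
  starts <- c(1L, which(diff(v) > 0L) + 1L)
  ends <- c(starts[-1L] - 1L, length(v))
  rings <- vector("list", V)
  for (k in seq_len(V)) {
    idx <- starts[k]:ends[k]
    pp <- p[idx]; qq <- q[idx]
    deg <- length(pp)
    ring <- integer(deg)
    cur <- min(pp)
    for (s in seq_len(deg)) {
      ring[s] <- cur
      cur <- qq[match(cur, pp)]
    }
    rings[[k]] <- ring
  }
  rings
}

# directed edge list (both directions), cached on demand
meshEdges <- function(mesh) {
  tri <- mesh@triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  rbind(e, e[, c(2, 1)])
}

#' Vertices within r hops of a centre
#'
#' Returns the centre first, then the hop-1 ring, hop-2 ring, ..., hop-r ring.
#' The 1-ring keeps the mesh's cyclic ordering (starting at the lowest-index
#' neighbour); outer rings are enumerated deterministically by expanding the
#' previous ring in order through each vertex's cyclic ring.
#'
#' @param mesh a [SphericalMesh-class]
#' @param center vertex index (1-based)
#' @param r ring radius, 1..7
#' @return integer vector of vertex indices, centre first
#' @export
rRingIndices <- function(mesh, center, r) {
  if (r < 1 || r > 7) stop("r must be in 1..7")
  V <- nVertices(mesh)
  if (center < 1 || center > V) stop("invalid center index")
  rings <- mesh@rings
  seen <- logical(V)
  seen[center] <- TRUE
  ring1 <- rotateToMin(rings[[center]])
  seen[ring1] <- TRUE
  out <- c(center, ring1)
  prev <- ring1
  for (hop in seq_len(r)[-1]) {
    nxt <- integer(0)
    for (u in prev) {
      cand <- rings[[u]]
      cand <- cand[!seen[cand]]
      if (length(cand)) {
        seen[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
    }
    out <- c(out, nxt)
    prev <- nxt
  }
  out
}

rotateToMin <- function(ring) {
  k <- which.min(ring)
  if (k == 1L) ring else ring[c(k:length(ring), 1:(k - 1L))]
}

#' Rotate a 1-ring patch about its centre
#'
#' One cyclic position equals 60 degrees at hexagonal vertices (72 degrees at
#' the 12 pentagonal vertices, where a one-step shift is the nearest
#' realizable rotation). `steps = +1` rotates the ring `(a,b,c,d,e,f)` to
#' `(f,a,b,c,d,e)`.
#'
#' @param mesh a [SphericalMesh-class]
#' @param center vertex index
#' @param steps -1, 0 or +1
#' @return the ring indices of `center` cyclically shifted by `steps`
#' @export
rotateRing <- function(mesh, center, steps) {
  if (!steps %in% c(-1L, 0L, 1L)) stop("steps must be -1, 0 or +1")
  ring <- rotateToMin(mesh@rings[[center]])
  d <- length(ring)
  if (steps == 0L) ring
  else if (steps == 1L) ring[c(d, seq_len(d - 1L))]
  else ring[c(seq_len(d - 1L) + 1L, 1L)]
}

#' Slide a patch centre to a neighbouring vertex
#'
#' @param mesh a [SphericalMesh-class]
#' @param center vertex index
#' @param direction which cyclic-ring neighbour to move to, 1..degree(center)
#'   (6 directions at hexagonal vertices, 5 at pentagons)
#' @return the neighbour vertex index
#' @export
translateCenter <- function(mesh, center, direction) {
  ring <- rotateToMin(mesh@rings[[center]])
  if (direction < 1 || direction > length(ring))
    stop("direction must be in 1..", length(ring))
  ring[direction]
}

#' Dilate a vertex mask along mesh edges
#'
#' Each iteration marks every vertex adjacent to a marked vertex. Monotone
#' and saturating: `dilateMask(m, mask, a + b)` equals dilating `a` then `b`
#' times.
#'
#' @param mesh a [SphericalMesh-class]
#' @param mask logical per-vertex mask
#' @param iterations non-negative iteration count
#' @return logical per-vertex mask
#' @export
dilateMask <- function(mesh, mask, iterations) {
  if (iterations < 0) stop("iterations must be >= 0")
  mask <- as.logical(mask)
  if (length(mask) != nVertices(mesh)) stop("mask length != vertex count")
  if (!any(mask) || iterations == 0) return(mask)
  edges <- meshEdges(mesh)
  for (i in seq_len(iterations)) {
    if (all(mask)) break
    mask[edges[mask[edges[, 1]], 2]] <- TRUE
  }
  mask
}

#' Uniformly subsample a mesh to a coarser nested resolution
#'
#' Because subdivision nests, the first \eqn{10 \cdot 4^k + 2} vertices of any
#' level-L mesh (k <= L) are exactly the level-k mesh; uniform sampling is a
#' prefix selection.
#'
#' @param mesh a [SphericalMesh-class]
#' @param targetCount a valid icosphere vertex count not exceeding
#'   `nVertices(mesh)`
#' @return integer vector of retained vertex indices (a prefix)
#' @export
uniformSubsample <- function(mesh, targetCount) {
  lv <- levelForCount(targetCount)
  if (is.na(lv) || lv > mesh@level)
    stop("targetCount must be an icosphere size 10*4^k + 2 with k <= level")
  seq_len(as.integer(targetCount))
}

#' Hop distances from a set of source vertices
#'
#' Breadth-first hop counts along mesh edges; the graph-geodesic distance
#' used for parcellation growth and interior/border bookkeeping.
#'
#' @param mesh a [SphericalMesh-class]
#' @param sources integer vertex indices
#' @return integer vector of hop distances (0 at sources)
#' @export
hopDistances <- function(mesh, sources) {
  V <- nVertices(mesh)
  d <- rep.int(NA_integer_, V)
  d[sources] <- 0L
  frontier <- sources
  rings <- mesh@rings
  hop <- 0L
  while (length(frontier)) {
    hop <- hop + 1L
    nxt <- unique(unlist(rings[frontier], use.names = FALSE))
    nxt <- nxt[is.na(d[nxt])]
    d[nxt] <- hop
    frontier <- nxt
  }
  d
}
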