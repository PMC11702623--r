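## Plain-text file formats: single-column CSV vertex maps, OFF meshes,
## 0-based integer index/label files, TSV scan manifests and JSON reports.
## All round-trip stable; vertex indices in files are 0-based.

.schemaVersion <- "lgmprint-1"

#' Read a vertex map from a single-column CSV
#'
#' One value per line, no header. The length is validated against the
#' declared mesh level when given, otherwise the level is inferred (the
#' length must then be a valid icosphere vertex count).
#'
#' @param path file path
#' @param meshLevel expected mesh level (optional)
#' @param kind semantic tag for the resulting map
#' @return a [VertexMap-class]
#' @export
readVertexMap <- function(path, meshLevel = NULL, kind = "generic") {
  v <- scan(path, what = double(), quiet = TRUE, sep = ",")
  if (!is.null(meshLevel)) {
    want <- 10 * 4^meshLevel + 2
    if (length(v) != want)
      stop(sprintf("format error: expected %d values for level %d, got %d",
                   want, meshLevel, length(v)))
  }
  vertexMap(v, kind = kind, meshLevel = meshLevel)
}

#' Write a vertex map as a single-column CSV
#'
#' @param map a [VertexMap-class] or numeric vector
#' @param path output path
#' @export
writeVertexMap <- function(map, path) {
  writeLines(format(asMapValues(map), digits = 17, trim = TRUE,
                    scientific = FALSE), path)
  invisible(path)
}

#' Read / write integer label or index files
#'
#' One integer per line; on disk the values are 0-based vertex indices (or
#' labels, written verbatim). `readIndexFile`/`writeIndexFile` shift
#' indices between the 0-based file convention and 1-based R indices;
#' label files are read and written unshifted.
#'
#' @param path file path
#' @return integer vector
#' @export
readIndexFile <- function(path) {
  scan(path, what = integer(), quiet = TRUE) + 1L
}

#' @rdname readIndexFile
#' @param idx 1-based indices to write (stored 0-based)
#' @export
writeIndexFile <- function(idx, path) {
  writeLines(as.character(as.integer(idx) - 1L), path)
  invisible(path)
}

#' @rdname readIndexFile
#' @export
readLabelFile <- function(path) {
  scan(path, what = integer(), quiet = TRUE)
}

#' @rdname readIndexFile
#' @param labels integer labels to write verbatim
#' @export
writeLabelFile <- function(labels, path) {
  writeLines(as.character(as.integer(labels)), path)
  invisible(path)
}

#' Write / read a mesh in OFF format
#'
#' Plain-text OFF: header line `OFF`, counts line, vertex coordinates, then
#' faces as `3 i j k` with 0-based vertex indices.
#'
#' @param mesh a [SphericalMesh-class]
#' @param path file path
#' @export
writeOffMesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- nVertices(mesh)
  Fc <- nrow(mesh@triangles)
  writeLines("OFF", con)
  writeLines(sprintf("%d %d %d", V, Fc, 0L), con)
  writeLines(apply(mesh@coords, 1, function(x)
    paste(format(x, digits = 17, trim = TRUE), collapse = " ")), con)
  writeLines(apply(mesh@triangles - 1L, 1, function(x)
    paste(c(3L, x), collapse = " ")), con)
  invisible(path)
}

#' @rdname writeOffMesh
#' @return `readOffMesh` returns a list with `coords` and `triangles`
#'   (1-based); use [makeIcosphere()] to rebuild the full mesh object at a
#'   known level.
#' @export
readOffMesh <- function(path) {
  lines <- readLines(path)
  if (trimws(lines[1]) != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  V <- counts[1]; Fc <- counts[2]
  coords <- do.call(rbind, lapply(lines[3:(2 + V)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  tri <- do.call(rbind, lapply(lines[(3 + V):(2 + V + Fc)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]])[2:4] + 1L))
  list(coords = coords, triangles = tri)
}

#' Read a scan manifest TSV
#'
#' Tab-separated with a header; required columns `subject_id`, `session_id`,
#' `path`; optional `ped` and `score`. Paths are resolved relative to the
#' manifest's directory; (subject, session, ped) triples must be unique and
#' all paths must exist.
#'
#' @param path manifest path
#' @return data.frame
#' @export
readScanManifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "session_id", "path")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (is.null(m$ped)) m$ped <- "NA"
  key <- paste(m$subject_id, m$session_id, m$ped)
  if (anyDuplicated(key)) stop("duplicate (subject, session, ped) rows")
  dir <- dirname(path)
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", m$path), m$path,
                file.path(dir, m$path))
  if (!all(file.exists(abs))) {
    stop("missing file(s): ", paste(m$path[!file.exists(abs)], collapse = ", "))
  }
  m$path <- abs
  m
}

#' Write an identification report
#'
#' JSON with schema version, run configuration echo, per-target records
#' (prediction, correctness, tie flag) and the rate; plus a TSV sidecar of
#' the full vote-fraction matrix (one row per target x base pair).
#'
#' @param report an [IdentificationReport-class]
#' @param path output JSON path; the sidecar gets the extension `.votes.tsv`
#' @param config optional list echoed verbatim for provenance
#' @export
writeReport <- function(report, path, config = list()) {
  rec <- list(
    schema_version = .schemaVersion,
    config = config,
    method = report@method,
    rate_percent = report@ratePercent,
    targets = lapply(seq_along(report@predicted), function(i) list(
      target = rownames(report@voteFractions)[i],
      predicted = report@predicted[i],
      correct = report@correct[i],
      tie = report@tieFlags[i]
    ))
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  vf <- report@voteFractions
  votes <- data.frame(
    target = rep(rownames(vf), times = ncol(vf)),
    base = rep(colnames(vf), each = nrow(vf)),
    fraction = as.vector(vf)
  )
  utils::write.table(votes, sub("\\.json$", ".votes.tsv", path),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeReport
#' @return `readReport` returns the parsed JSON record
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Persist / load an LCM tensor as plain text
#'
#' A JSON axis manifest (subject order on both axes, centres, r, deformable
#' flag, schema version) plus a CSV of the values flattened in array order.
#'
#' @param tensor an [LcmTensor-class]
#' @param stem output path stem; writes `<stem>.json` and `<stem>.csv`
#' @export
writeLcmTensor <- function(tensor, stem) {
  jsonlite::write_json(list(
    schema_version = .schemaVersion,
    target_ids = tensor@targetIds, base_ids = tensor@baseIds,
    centers0 = tensor@centers - 1L, r = tensor@r,
    deformable = tensor@deformable, dim = dim(tensor@values)
  ), paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  writeLines(format(as.vector(tensor@values), digits = 17, trim = TRUE),
             paste0(stem, ".csv"))
  invisible(stem)
}

#' @rdname writeLcmTensor
#' @export
readLcmTensor <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  vals <- array(scan(paste0(stem, ".csv"), what = double(), quiet = TRUE),
                dim = meta$dim)
  new("LcmTensor", values = vals, centers = as.integer(meta$centers0) + 1L,
      r = as.integer(meta$r), deformable = meta$deformable,
      targetIds = meta$target_ids, baseIds = meta$base_ids,
      flags = array(FALSE, dim = meta$dim))
}
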