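#' @include mesh-geometry.R
NULL

#' Read a Wavefront OBJ mesh
#'
#' Minimal OBJ reader for triangulated meshes: `v` records for vertex
#' coordinates and `f` records with exactly three (1-based) indices.
#' Texture/normal sub-indices (`f a/b/c ...`) are accepted and stripped;
#' quads or larger polygons are rejected.
#'
#' @param path path to an OBJ file.
#' @param rigid mark the loaded mesh rigid.
#' @return a [TriMesh-class]; rest areas are set from the loaded
#'   geometry.
#' @seealso [writeOBJ()]
#' @export
readOBJ <- function(path, rigid = FALSE) {
  if (!file.exists(path)) stop("OBJ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl) || !length(fl))
    stop("not a usable OBJ: need at least one 'v' and one 'f' record")
  v <- t(vapply(strsplit(sub("^v\\s+", "", vl), "\\s+"),
                function(x) as.numeric(x[1:3]), numeric(3)))
  if (anyNA(v)) stop("malformed vertex record in OBJ")
  fparts <- strsplit(sub("^f\\s+", "", fl), "\\s+")
  nv <- lengths(fparts)
  if (any(nv != 3L))
    stop("unsupported OBJ face: only triangles are supported (found a ",
         max(nv), "-gon)")
  f <- t(vapply(fparts, function(x)
    as.integer(sub("/.*$", "", x)), integer(3)))
  if (anyNA(f)) stop("malformed face record in OBJ")
  triMesh(v, f, rigid = rigid)
}

#' Write a mesh as Wavefront OBJ
#'
#' Writes `v` and `f` records (triangles, 1-based indices) with enough
#' digits that a save/load round trip preserves coordinates to better
#' than 6 significant digits and face indices exactly.
#'
#' @param mesh a [TriMesh-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readOBJ()]
#' @export
writeOBJ <- function(mesh, path) {
  stopifnot(is(mesh, "TriMesh"))
  v <- mesh@vertices
  f <- mesh@faces
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  invisible(path)
}

#' Read an OFF mesh
#'
#' Minimal reader for ASCII OFF files with triangular faces.
#'
#' @param path path to an OFF file.
#' @return a [TriMesh-class].
#' @export
readOFF <- function(path) {
  if (!file.exists(path)) stop("OFF file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines) || toupper(lines[1L]) != "OFF")
    stop("not an OFF file")
  counts <- as.integer(strsplit(lines[2L], "\\s+")[[1L]])
  nv <- counts[1L]; nf <- counts[2L]
  if (is.na(nv) || is.na(nf) || length(lines) < 2L + nv + nf)
    stop("truncated OFF file")
  v <- t(vapply(strsplit(lines[2L + seq_len(nv)], "\\s+"),
                function(x) as.numeric(x[1:3]), numeric(3)))
  frec <- strsplit(lines[2L + nv + seq_len(nf)], "\\s+")
  f <- t(vapply(frec, function(x) {
    k <- as.integer(x[1L])
    if (k != 3L) stop("unsupported OFF face: only triangles are supported")
    as.integer(x[2:4]) + 1L
  }, integer(3)))
  triMesh(v, f)
}
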