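#' @include AllClasses.R
NULL

#' Construct a TriMesh
#'
#' Builds a [TriMesh-class] from raw vertex and face arrays. Rest areas
#' default to the face areas at construction time and are frozen
#' thereafter: the elastic energy of any later deformation is measured
#' against them.
#'
#' @param vertices numeric matrix (n x 3), um.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param boundary logical vector of per-vertex boundary flags; by
#'   default inferred from the topology (vertices on edges used by only
#'   one face).
#' @param rigid logical; rigid meshes translate as a unit (piston) and
#'   never deform.
#' @param restAreas optional explicit reference areas (um^2); defaults
#'   to the current face areas.
#' @return a validated [TriMesh-class].
#' @export
triMesh <- function(vertices, faces, boundary = NULL, rigid = FALSE,
                    restAreas = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) && (anyNA(faces) || any(faces < 1L) ||
                      any(faces > nrow(vertices))))
    stop("face index out of range")
  if (is.null(restAreas)) {
    restAreas <- triangleAreas(vertices, faces)
    if (any(restAreas <= 0))
      stop("degenerate face: a face with non-positive area at construction")
  }
  if (is.null(boundary)) boundary <- inferBoundary(vertices, faces)
  new("TriMesh", vertices = vertices, faces = faces,
      restAreas = as.numeric(restAreas), boundary = boundary,
      rigid = isTRUE(rigid))
}

## areas of raw triangle soup (internal)
triangleAreas <- function(v, f) {
  if (nrow(f) == 0L) return(numeric(0))
  a <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - a
  e2 <- v[f[, 3L], , drop = FALSE] - a
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

inferBoundary <- function(v, f) {
  b <- rep(FALSE, nrow(v))
  if (nrow(f) == 0L) return(b)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(key)
  open <- names(cnt)[cnt == 1L]
  if (length(open)) {
    idx <- unique(as.integer(unlist(strsplit(open, " ", fixed = TRUE))))
    b[idx] <- TRUE
  }
  b
}

#' Per-face areas
#'
#' Area of each triangular face: half the magnitude of the cross product
#' of two edge vectors. `faceArea()` returns a single face's area and
#' errors on a degenerate (collinear) face.
#'
#' @param mesh a [TriMesh-class].
#' @param faceId 1-based face index (for `faceArea`).
#' @return numeric vector of areas (um^2), or a single area.
#' @examples
#' m <- generateFlatGrid(2, 2, 1)
#' sum(faceAreas(m))  # 1 um^2
#' @export
faceAreas <- function(mesh) {
  stopifnot(is(mesh, "TriMesh"))
  triangleAreas(mesh@vertices, mesh@faces)
}

#' @rdname faceAreas
#' @export
faceArea <- function(mesh, faceId) {
  stopifnot(is(mesh, "TriMesh"))
  faceId <- as.integer(faceId)
  if (length(faceId) != 1L || is.na(faceId) || faceId < 1L ||
      faceId > nFaces(mesh))
    stop("faceId out of range")
  a <- triangleAreas(mesh@vertices, mesh@faces[faceId, , drop = FALSE])
  if (a <= 0) stop("degenerate face: collinear vertices")
  a
}

#' Outward face normals
#'
#' Unit normals per face, following the counterclockwise winding
#' convention (outward for closed meshes).
#'
#' @param mesh a [TriMesh-class].
#' @return numeric matrix (m x 3) of unit normals.
#' @export
faceNormals <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - a
  e2 <- v[f[, 3L], , drop = FALSE] - a
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Area-weighted vertex normals
#'
#' @param mesh a [TriMesh-class].
#' @return numeric matrix (n x 3) of unit vertex normals.
#' @export
vertexNormals <- function(mesh) {
  f <- mesh@faces
  v <- mesh@vertices
  a <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - a
  e2 <- v[f[, 3L], , drop = FALSE] - a
  fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])  # 2*area-weighted
  vn <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    vn[, 1L] <- vn[, 1L] + tabulateSum(f[, k], fn[, 1L], nrow(v))
    vn[, 2L] <- vn[, 2L] + tabulateSum(f[, k], fn[, 2L], nrow(v))
    vn[, 3L] <- vn[, 3L] + tabulateSum(f[, k], fn[, 3L], nrow(v))
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

tabulateSum <- function(index, weights, n) {
  out <- numeric(n)
  s <- rowsum(weights, index)
  out[as.integer(rownames(s))] <- s
  out
}

#' Is a mesh closed (watertight)?
#'
#' A mesh is closed when every edge is shared by exactly two faces.
#'
#' @param mesh a [TriMesh-class].
#' @return logical scalar.
#' @export
isClosed <- function(mesh) {
  f <- mesh@faces
  if (nrow(f) == 0L) return(FALSE)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}

#' Euler characteristic V - E + F
#'
#' @param mesh a [TriMesh-class].
#' @return integer; 2 for a closed genus-0 mesh.
#' @export
eulerCharacteristic <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- unique(paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  nVertices(mesh) - length(key) + nFaces(mesh)
}

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron (divergence-theorem) sum over faces; positive for
#' consistent outward winding. Open meshes are rejected unless
#' `allowOpen = TRUE`, in which case the raw signed sum is returned (the
#' caller supplies the closing convention, as the piston chamber does by
#' combining box walls with the piston plane).
#'
#' @param mesh a [TriMesh-class].
#' @param allowOpen return the raw signed sum for an open mesh.
#' @return volume (um^3).
#' @examples
#' s <- generateIcosphere(3, radius = 1)
#' enclosedVolume(s)  # ~ 4*pi/3
#' @export
enclosedVolume <- function(mesh, allowOpen = FALSE) {
  stopifnot(is(mesh, "TriMesh"))
  if (!allowOpen && !isClosed(mesh))
    stop("enclosedVolume: mesh is not closed; pass allowOpen = TRUE ",
         "to get the raw signed-tetrahedron sum")
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
      a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
      a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6
}

## face adjacency across shared edges: m x 3 matrix, entry [i, k] is the
## face sharing edge k (v_k -> v_{k+1}) of face i, or 0L at a boundary.
faceAdjacency <- function(mesh) {
  f <- mesh@faces
  m <- nrow(f)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  faceOf <- rep(seq_len(m), 3L)
  adj <- matrix(0L, m, 3L)
  sp <- split(seq_len(3L * m), key)
  for (idx in sp) {
    if (length(idx) == 2L) {
      f1 <- faceOf[idx[1L]]; f2 <- faceOf[idx[2L]]
      s1 <- ((idx[1L] - 1L) %/% m) + 1L
      s2 <- ((idx[2L] - 1L) %/% m) + 1L
      adj[f1, s1] <- f2
      adj[f2, s2] <- f1
    } else if (length(idx) > 2L) {
      stop("non-manifold edge: shared by more than two faces")
    }
  }
  adj
}

## list of incident face indices per vertex
vertexFaceIncidence <- function(mesh) {
  f <- mesh@faces
  n <- nVertices(mesh)
  idx <- rep(seq_len(nrow(f)), 3L)
  split(idx, factor(as.vector(f), levels = seq_len(n)))
}

#' Translate a mesh rigidly
#'
#' @param mesh a [TriMesh-class].
#' @param offset numeric length-3 displacement (um).
#' @return the translated mesh (rest areas untouched).
#' @export
translateMesh <- function(mesh, offset) {
  stopifnot(is(mesh, "TriMesh"), length(offset) == 3L)
  mesh@vertices <- sweep(mesh@vertices, 2L, as.numeric(offset), "+")
  mesh
}
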