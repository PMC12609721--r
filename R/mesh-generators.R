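#' @include mesh-geometry.R
NULL

## evaluate expr under a fixed seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate an icosphere, optionally with membrane ruffles
#'
#' Recursively subdivides an icosahedron and projects vertices to the
#' sphere. With a positive `ruffleAmplitude` each vertex is additionally
#' displaced radially by a seeded uniform amount in
#' `[-ruffleAmplitude, +ruffleAmplitude]`, giving a statistically ruffled
#' cell surface (the stand-in for the microvilli and lamellipodia of a
#' real cell). Rest areas are frozen at the generated (possibly ruffled)
#' face areas, so a ruffled sphere is its own relaxed reference shape.
#'
#' Subdivision level `s` produces `20 * 4^s` faces and `2 + 10 * 4^s`
#' vertices.
#'
#' @param subdivisions non-negative integer subdivision depth.
#' @param radius sphere radius (um), > 0.
#' @param ruffleAmplitude radial ruffle amplitude (um), `>= 0` and
#'   `< radius`.
#' @param seed integer seed for the ruffle displacements.
#' @return a closed [TriMesh-class].
#' @examples
#' generateIcosphere(2, radius = 1)  # 162 vertices, 320 faces
#' @export
generateIcosphere <- function(subdivisions = 2L, radius = 1,
                              ruffleAmplitude = 0, seed = 1L) {
  if (length(radius) != 1L || !is.finite(radius) || radius <= 0)
    stop("radius must be a positive number")
  if (ruffleAmplitude < 0 || ruffleAmplitude >= radius)
    stop("ruffleAmplitude must be >= 0 and < radius")
  subdivisions <- as.integer(subdivisions)
  if (is.na(subdivisions) || subdivisions < 0L)
    stop("subdivisions must be a non-negative integer")

  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  storage.mode(f) <- "integer"

  for (s in seq_len(subdivisions)) {
    res <- subdivideOnce(v, f)
    v <- res$v / sqrt(rowSums(res$v^2))
    f <- res$f
  }
  r <- rep(radius, nrow(v))
  if (ruffleAmplitude > 0)
    r <- r + withSeed(seed, stats::runif(nrow(v), -ruffleAmplitude,
                                         ruffleAmplitude))
  triMesh(v * r, f)
}

## split every edge at its midpoint; 1 face -> 4 faces
subdivideOnce <- function(v, f) {
  m <- nrow(f)
  edges <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  key <- paste(lo, hi)
  uk <- !duplicated(key)
  midIndex <- match(key, key[uk]) + nrow(v)
  mids <- (v[lo[uk], , drop = FALSE] + v[hi[uk], , drop = FALSE]) / 2
  v2 <- rbind(v, mids)
  a <- f[, 1L]; b <- f[, 2L]; c_ <- f[, 3L]
  ab <- midIndex[seq_len(m)]
  bc <- midIndex[m + seq_len(m)]
  ca <- midIndex[2L * m + seq_len(m)]
  f2 <- rbind(cbind(a, ab, ca), cbind(b, bc, ab),
              cbind(c_, ca, bc), cbind(ab, bc, ca))
  storage.mode(f2) <- "integer"
  dimnames(f2) <- NULL
  list(v = v2, f = f2)
}

#' Generate an open flat rectangular grid mesh
#'
#' A regular `nx` x `ny` vertex grid spanning `side` x `side` um in the
#' xy-plane at z = 0, each cell split into two triangles, with perimeter
#' vertices flagged as boundary (clamped by the membrane dynamics).
#'
#' @param nx,ny vertex counts per axis, `>= 2`.
#' @param side edge length of the square sheet (um).
#' @return an open [TriMesh-class] with `(nx-1)*(ny-1)*2` faces.
#' @examples
#' generateFlatGrid(3, 3, 1)  # 9 vertices, 8 faces
#' @export
generateFlatGrid <- function(nx, ny, side = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 2L || ny < 2L)
    stop("nx and ny must be integers >= 2")
  if (side <= 0) stop("side must be > 0")
  xs <- seq(0, side, length.out = nx)
  ys <- seq(0, side, length.out = ny)
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  id <- function(i, j) (j - 1L) * nx + i
  fl <- vector("list", (nx - 1L) * (ny - 1L))
  k <- 0L
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      k <- k + 1L
      ## counterclockwise seen from +z
      fl[[k]] <- rbind(c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
                       c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
    }
  }
  f <- do.call(rbind, fl)
  storage.mode(f) <- "integer"
  bnd <- rep(FALSE, nx * ny)
  bnd[id(1L, seq_len(ny))] <- TRUE
  bnd[id(nx, seq_len(ny))] <- TRUE
  bnd[id(seq_len(nx), 1L)] <- TRUE
  bnd[id(seq_len(nx), ny)] <- TRUE
  triMesh(v, f, boundary = bnd)
}

#' Generate the rigid piston plane
#'
#' A two-triangle rigid square at height `z` spanning the chamber cross
#' section `[0, side] x [0, side]`. Rigid meshes translate as a unit and
#' carry no elastic energy.
#'
#' @param side chamber side length (um).
#' @param z piston height (um).
#' @return a rigid [TriMesh-class].
#' @export
generatePistonPlane <- function(side = 0.5, z = side / 2) {
  v <- rbind(c(0, 0, z), c(side, 0, z), c(side, side, z), c(0, side, z))
  f <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  triMesh(v, f, rigid = TRUE)
}

#' Generate a closed box (chamber) mesh
#'
#' Axis-aligned box `[0, side]^3` as twelve triangles with outward
#' winding; used for chamber-volume bookkeeping and as a fixture for
#' volume computations.
#'
#' @param side edge length (um).
#' @return a closed [TriMesh-class].
#' @export
generateBox <- function(side = 1) {
  if (side <= 0) stop("side must be > 0")
  s <- side
  v <- rbind(c(0, 0, 0), c(s, 0, 0), c(s, s, 0), c(0, s, 0),
             c(0, 0, s), c(s, 0, s), c(s, s, s), c(0, s, s))
  f <- rbind(
    c(1, 3, 2), c(1, 4, 3),   # bottom (z = 0), outward = -z
    c(5, 6, 7), c(5, 7, 8),   # top, outward = +z
    c(1, 2, 6), c(1, 6, 5),   # y = 0, outward = -y
    c(2, 3, 7), c(2, 7, 6),   # x = s, outward = +x
    c(3, 4, 8), c(3, 8, 7),   # y = s, outward = +y
    c(4, 1, 5), c(4, 5, 8))   # x = 0, outward = -x
  storage.mode(f) <- "integer"
  triMesh(v, f)
}
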