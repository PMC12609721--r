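## Independent reference implementations used to cross-check the package.
## These are deliberately written in a different style (plain loops, no
## shared code) so that agreement is meaningful.

## O(n^2) fixed-radius candidate pairs
bruteForcePairs <- function(mobilePos, staticPos, cutoff) {
  out <- list()
  for (i in seq_len(nrow(mobilePos))) {
    for (j in seq_len(nrow(staticPos))) {
      d <- sqrt(sum((mobilePos[i, ] - staticPos[j, ])^2))
      if (d <= cutoff) out[[length(out) + 1L]] <- c(i, j, d)
    }
  }
  if (!length(out))
    return(data.frame(mobile = integer(0), static = integer(0),
                      distance = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(mobile = as.integer(m[, 1]), static = as.integer(m[, 2]),
             distance = m[, 3])
}

## canonical sorted key for a pair set, for exact set comparison
pairKey <- function(df) sort(paste(df$mobile, df$static, sep = ":"))

## cotangent-Laplacian bending energy, edge-by-edge reference
oracleBendingEnergy <- function(mesh, kappaB) {
  v <- vertices(mesh)
  f <- faces(mesh)
  n <- nrow(v)
  Lx <- matrix(0, n, 3)
  A <- numeric(n)
  cotAt <- function(pk, pi, pj) {
    u <- pi - pk; w <- pj - pk
    cr <- c(u[2] * w[3] - u[3] * w[2],
            u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    sum(u * w) / sqrt(sum(cr^2))
  }
  for (t in seq_len(nrow(f))) {
    tri <- f[t, ]
    p1 <- v[tri[1], ]; p2 <- v[tri[2], ]; p3 <- v[tri[3], ]
    e1 <- p2 - p1; e2 <- p3 - p1
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    area <- 0.5 * sqrt(sum(cr^2))
    for (k in 1:3) A[tri[k]] <- A[tri[k]] + area / 3
    ## three edges, each weighted by the cotangent of the opposite angle
    corners <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
    for (cn in corners) {
      i <- tri[cn[1]]; j <- tri[cn[2]]; k <- tri[cn[3]]
      w <- 0.5 * cotAt(v[k, ], v[i, ], v[j, ])
      Lx[i, ] <- Lx[i, ] + w * (v[j, ] - v[i, ])
      Lx[j, ] <- Lx[j, ] + w * (v[i, ] - v[j, ])
    }
  }
  interior <- which(!boundaryVertices(mesh))
  m2 <- 0
  for (i in interior) m2 <- m2 + sum(Lx[i, ]^2) / (4 * A[i])
  2 * kappaB * m2
}

## total stretching energy, face-by-face reference
oracleElasticEnergy <- function(mesh, kappa1, kappa2) {
  kap <- kappa1 * kappa2 / (kappa1 + kappa2)
  v <- vertices(mesh)
  f <- faces(mesh)
  rest <- restAreas(mesh)
  E <- 0
  for (t in seq_len(nrow(f))) {
    p1 <- v[f[t, 1], ]; p2 <- v[f[t, 2], ]; p3 <- v[f[t, 3], ]
    e1 <- p2 - p1; e2 <- p3 - p1
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    a <- 0.5 * sqrt(sum(cr^2))
    E <- E + kap / (2 * rest[t]^2) * (a - rest[t])^2
  }
  E
}

## vectorised stretching energy of one movable vertex of a mesh, as a
## function of candidate positions `pos` (m x 3); all other vertices
## fixed. Used as the Boltzmann-quadrature oracle.
vertexEnergyProfile <- function(mesh, vid, pos) {
  f <- faces(mesh)
  v <- vertices(mesh)
  rest <- restAreas(mesh)
  incident <- which(f[, 1] == vid | f[, 2] == vid | f[, 3] == vid)
  E <- numeric(nrow(pos))
  for (t in incident) {
    others <- setdiff(f[t, ], vid)
    b <- v[others[1], ]; cc <- v[others[2], ]
    u <- sweep(-pos, 2, b, "+")        # b - p
    w <- sweep(-pos, 2, cc, "+")       # c - p
    cr1 <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cr2 <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cr3 <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    a <- 0.5 * sqrt(cr1^2 + cr2^2 + cr3^2)
    E <- E + (a - rest[t])^2 / (2 * rest[t]^2)
  }
  E   # per unit kappa
}

## small hand-built single-triangle mesh helpers
oneFaceMesh <- function(scale = 1) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  m <- triMesh(v, rbind(c(1L, 2L, 3L)))
  if (scale != 1) m@vertices <- v * scale
  m
}
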