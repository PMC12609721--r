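#' @include AllClasses.R mesh-geometry.R
NULL

#' Parameter block constructors
#'
#' Convenience constructors for the energy parameter blocks. All
#' energies are expressed in kT units (beta = 1): the Metropolis
#' criterion uses `exp(-dE)` with no explicit temperature factor, so
#' temperature enters only through this normalisation and the particle
#' speed scales.
#'
#' @param kappa1,kappa2 membrane rigidities (kT), `>= 0`, not both zero.
#' @param kappaB bending constant (kT).
#' @param enabled enable the bending term (off by default; the membrane
#'   dynamics use stretching elasticity only).
#' @param c pressure displacement constant.
#' @param vInt initial enclosed volume (um^3).
#' @param nRT isothermal-work prefactor (energy units).
#' @return the corresponding parameter object.
#' @name parameter-constructors
NULL

#' @rdname parameter-constructors
#' @export
elasticParams <- function(kappa1 = 1, kappa2 = 1e6) {
  new("ElasticParams", kappa1 = as.numeric(kappa1),
      kappa2 = as.numeric(kappa2))
}

#' @rdname parameter-constructors
#' @export
bendingParams <- function(kappaB = 1, enabled = FALSE) {
  new("BendingParams", kappaB = as.numeric(kappaB), enabled = isTRUE(enabled))
}

#' @rdname parameter-constructors
#' @export
pressureParams <- function(c = 0, vInt) {
  new("PressureParams", c = as.numeric(c), vInt = as.numeric(vInt))
}

#' @rdname parameter-constructors
#' @export
thermoParams <- function(nRT = 1) {
  new("ThermoParams", nRT = as.numeric(nRT))
}

#' Kinetic energy of a particle ensemble
#'
#' Total kinetic interaction energy `sum(m_i |v_i|^2 / 2)` over the
#' particles, in kT units given velocities in um/us and masses in the
#' simulation's (arbitrary) mass units.
#'
#' @param masses per-particle masses (> 0), or a [ParticleEnsemble-class]
#'   (then `velocities` is ignored).
#' @param velocities n x 3 velocity matrix (um/us).
#' @return total kinetic energy (kT).
#' @examples
#' kineticEnergy(2, matrix(c(0, 0, 3), 1))  # 9
#' @export
kineticEnergy <- function(masses, velocities) {
  if (is(masses, "ParticleEnsemble")) {
    velocities <- masses@velocities
    masses <- masses@masses
  }
  velocities <- rbind(velocities)
  if (length(masses) != nrow(velocities))
    stop("masses and velocities must have equal length")
  if (any(masses <= 0)) stop("all masses must be > 0")
  sum(0.5 * masses * rowSums(velocities^2))
}

#' Total momentum of a particle ensemble
#'
#' Componentwise `sum(m_i v_i)`.
#'
#' @inheritParams kineticEnergy
#' @return length-3 momentum vector (mass * um/us).
#' @export
particleMomentum <- function(masses, velocities) {
  if (is(masses, "ParticleEnsemble")) {
    velocities <- masses@velocities
    masses <- masses@masses
  }
  velocities <- rbind(velocities)
  if (length(masses) != nrow(velocities))
    stop("masses and velocities must have equal length")
  if (any(masses <= 0)) stop("all masses must be > 0")
  colSums(masses * velocities)
}

#' Effective rigidity of two apposed membranes
#'
#' `kappa1 * kappa2 / (kappa1 + kappa2)`: the series combination of the
#' two rigidities. When one membrane is much stiffer, the effective
#' rigidity approaches the softer membrane's value.
#'
#' @param kappa1,kappa2 non-negative rigidities (kT), not both zero.
#' @return effective rigidity (kT).
#' @examples
#' effectiveRigidity(2, 2)    # 1
#' effectiveRigidity(1, 1e6)  # ~ 1
#' @export
effectiveRigidity <- function(kappa1, kappa2) {
  if (kappa1 < 0 || kappa2 < 0) stop("rigidities must be >= 0")
  if (kappa1 + kappa2 <= 0) stop("at least one rigidity must be > 0")
  kappa1 * kappa2 / (kappa1 + kappa2)
}

kappaEff <- function(params) effectiveRigidity(params@kappa1, params@kappa2)

#' Elastic stretching energy of a mesh
#'
#' Per-face quadratic stretching penalty against the frozen rest areas:
#' `sum_i kappa_eff / (2 a_i^2) * (da_i)^2`, with `a_i` the rest area of
#' face i and `da_i` its current deviation from rest. Zero iff the mesh
#' is undeformed; invariant under rigid-body motion.
#'
#' @param mesh a deformable [TriMesh-class] with rest areas.
#' @param params an [ElasticParams-class].
#' @return elastic energy (kT).
#' @examples
#' g <- generateFlatGrid(3, 3, 1)
#' elasticEnergy(g, elasticParams(2, 2))  # 0: undeformed
#' @export
elasticEnergy <- function(mesh, params) {
  stopifnot(is(mesh, "TriMesh"), is(params, "ElasticParams"))
  if (!length(mesh@restAreas) && nFaces(mesh) > 0L)
    stop("mesh has no rest areas")
  if (mesh@rigid) return(0)
  a <- mesh@restAreas
  da <- faceAreas(mesh) - a
  sum(kappaEff(params) / (2 * a^2) * da^2)
}

#' Discrete Helfrich bending energy
#'
#' `2 * kappaB * M2` with `M2` the discrete squared-mean-curvature
#' moment built from the cotangent Laplace-Beltrami operator: for each
#' interior vertex, `|L x_v|^2 / (4 A_v)` where `L x_v` is the cotangent
#' Laplacian of the coordinate field and `A_v` the barycentric one-ring
#' area (one third of the incident face area). For a refining sphere
#' this converges to the smooth Helfrich value `8 pi kappaB`,
#' independent of radius. The term is disabled by default and is not
#' part of the membrane dynamics; evaluating it with a disabled
#' parameter block is an error.
#'
#' @param mesh a closed or boundary-clamped [TriMesh-class].
#' @param params a [BendingParams-class] with `enabled = TRUE`.
#' @return bending energy (kT).
#' @export
bendingEnergy <- function(mesh, params) {
  stopifnot(is(mesh, "TriMesh"), is(params, "BendingParams"))
  if (!params@enabled)
    stop("bending energy is disabled; construct bendingParams(..., ",
         "enabled = TRUE) to evaluate it")
  v <- mesh@vertices
  f <- mesh@faces
  n <- nrow(v)
  ## cotangent weights per half-edge corner
  Lx <- matrix(0, n, 3L)
  ringArea <- numeric(n)
  areas <- faceAreas(mesh)
  for (corner in 1:3) {
    i <- f[, corner]
    j <- f[, corner %% 3L + 1L]
    k <- f[, (corner + 1L) %% 3L + 1L]
    ## angle at k, opposite edge (i, j)
    u <- v[i, , drop = FALSE] - v[k, , drop = FALSE]
    w <- v[j, , drop = FALSE] - v[k, , drop = FALSE]
    cosA <- rowSums(u * w)
    crossN <- sqrt(pmax(rowSums(u^2) * rowSums(w^2) - cosA^2, 0))
    cot <- cosA / pmax(crossN, 1e-300)
    d <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
    half <- 0.5 * cot * d
    for (ax in 1:3) {
      Lx[, ax] <- Lx[, ax] + tabulateSum(i, half[, ax], n)
      Lx[, ax] <- Lx[, ax] + tabulateSum(j, -half[, ax], n)
    }
    ringArea <- ringArea + tabulateSum(i, areas / 3, n)
  }
  interior <- !mesh@boundary
  m2 <- sum(rowSums(Lx[interior, , drop = FALSE]^2) /
              (4 * ringArea[interior]))
  2 * params@kappaB * m2
}

#' Pressure-induced displacement magnitude
#'
#' `D_P = c * (dV)^2 / V_int`: the restoring displacement applied along
#' vertex normals once per iteration, inward when the enclosed volume
#' grew beyond `vInt` and outward when it shrank. The magnitude is even
#' in `dV`; the engine chooses the sign.
#'
#' @param deltaV volume change relative to the initial volume (um^3).
#' @param params a [PressureParams-class].
#' @return displacement magnitude (um).
#' @examples
#' pressureDisplacement(2, pressureParams(c = 1, vInt = 4))  # 1
#' @export
pressureDisplacement <- function(deltaV, params) {
  stopifnot(is(params, "PressureParams"))
  if (params@vInt <= 0) stop("vInt must be > 0")
  params@c * deltaV^2 / params@vInt
}

#' Isothermal work of a volume change
#'
#' `W = nRT * log(V2 / V1)` for a compartment whose volume changes from
#' `V1` (initial) to `V2` (current) at constant temperature;
#' antisymmetric under swapping the volumes.
#'
#' @param params a [ThermoParams-class].
#' @param V1,V2 initial and current volumes (um^3), > 0.
#' @return work (energy units of `nRT`).
#' @examples
#' isothermalWork(thermoParams(1), 1, 2)  # log(2)
#' @export
isothermalWork <- function(params, V1, V2) {
  stopifnot(is(params, "ThermoParams"))
  if (any(V1 <= 0) || any(V2 <= 0)) stop("volumes must be > 0")
  params@nRT * log(V2 / V1)
}
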