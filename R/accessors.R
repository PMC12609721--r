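#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("vertices", "TriMesh", function(x, ...) x@vertices)

#' @rdname accessors
#' @export
setMethod("faces", "TriMesh", function(x, ...) x@faces)

#' @rdname accessors
#' @export
setMethod("restAreas", "TriMesh", function(x, ...) x@restAreas)

#' @rdname accessors
#' @export
setMethod("isRigid", "TriMesh", function(x, ...) x@rigid)

#' @rdname accessors
#' @export
setMethod("boundaryVertices", "TriMesh", function(x, ...) x@boundary)

#' @rdname accessors
#' @export
setMethod("nVertices", "TriMesh", function(x, ...) nrow(x@vertices))

#' @rdname accessors
#' @export
setMethod("nFaces", "TriMesh", function(x, ...) nrow(x@faces))

#' @rdname accessors
#' @export
setMethod("species", "SurfaceMoleculeSet", function(x, ...) x@species)

#' @rdname accessors
#' @export
setMethod("bondPartners", "SurfaceMoleculeSet", function(x, ...) x@bond)

#' @rdname accessors
#' @export
setMethod("observables", "TrajectoryLog", function(x, ...) x@data)

#' @rdname accessors
#' @export
setMethod("snapshots", "TrajectoryLog", function(x, ...) x@snapshots)

#' Number of molecules in a set
#' @param x a [SurfaceMoleculeSet-class].
#' @return integer count.
#' @export
nMolecules <- function(x) {
  stopifnot(is(x, "SurfaceMoleculeSet"))
  length(x@species)
}

setMethod("show", "TriMesh", function(object) {
  closed <- isClosed(object)
  cat(sprintf("TriMesh: %d vertices, %d faces%s%s\n",
              nVertices(object), nFaces(object),
              if (object@rigid) " [rigid]" else "",
              if (closed) " [closed]" else " [open]"))
  cat(sprintf("  total area %.4g um^2", sum(faceAreas(object))))
  if (closed) cat(sprintf(", enclosed volume %.4g um^3", enclosedVolume(object)))
  cat("\n")
  invisible(object)
})

setMethod("show", "ParticleEnsemble", function(object) {
  n <- nrow(object@positions)
  cat(sprintf("ParticleEnsemble: %d particles (%d top / %d bottom)\n",
              n, sum(object@compartment == "top"),
              sum(object@compartment == "bottom")))
  invisible(object)
})

setMethod("show", "SurfaceMoleculeSet", function(object) {
  n <- length(object@species)
  cat(sprintf("SurfaceMoleculeSet: %d molecules, %d bound\n",
              n, sum(!is.na(object@bond))))
  if (n) {
    tab <- table(object@species)
    cat("  species:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(object)
})

setMethod("show", "TrajectoryLog", function(object) {
  cat(sprintf("TrajectoryLog: %d iterations of scenario '%s', %d snapshots\n",
              nrow(object@data),
              if (!is.null(object@meta$scenario)) object@meta$scenario else "?",
              length(object@snapshots)))
  if (nrow(object@data))
    cat("  columns:", paste(names(object@data), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: scenario '%s', %d iterations of %g us, seed %d\n",
              object@scenario, as.integer(object@iterations),
              object@timestep, as.integer(object@seed)))
  cat(sprintf("  box [%g,%g]x[%g,%g]x[%g,%g] um, sigma %g um\n",
              object@box[1,1], object@box[2,1], object@box[1,2],
              object@box[2,2], object@box[1,3], object@box[2,3],
              object@sigma))
  invisible(object)
})

#' Coerce a trajectory log to a data.frame
#'
#' @param x a [TrajectoryLog-class].
#' @param ... ignored.
#' @return the per-iteration observable data.frame.
#' @export
as.data.frame.TrajectoryLog <- function(x, ...) x@data
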