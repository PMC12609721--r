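#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the simulator's S4 containers:
#' mesh geometry (`vertices`, `faces`, `restAreas`, `isRigid`,
#' `boundaryVertices`), molecule state (`species`, `bondPartners`) and
#' trajectory output (`observables`, `snapshots`).
#'
#' @param x an object of one of the package's S4 classes.
#' @param ... passed to methods.
#' @return The slot contents in their natural form (matrix, vector,
#'   data.frame or list); see the class documentation for details.
#' @name accessors
#' @aliases vertices faces restAreas isRigid boundaryVertices
#'   nVertices nFaces species bondPartners observables snapshots
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x, ...) standardGeneric("vertices"))

#' @rdname accessors
#' @export
setGeneric("faces", function(x, ...) standardGeneric("faces"))

#' @rdname accessors
#' @export
setGeneric("restAreas", function(x, ...) standardGeneric("restAreas"))

#' @rdname accessors
#' @export
setGeneric("isRigid", function(x, ...) standardGeneric("isRigid"))

#' @rdname accessors
#' @export
setGeneric("boundaryVertices", function(x, ...) standardGeneric("boundaryVertices"))

#' @rdname accessors
#' @export
setGeneric("nVertices", function(x, ...) standardGeneric("nVertices"))

#' @rdname accessors
#' @export
setGeneric("nFaces", function(x, ...) standardGeneric("nFaces"))

#' @rdname accessors
#' @export
setGeneric("species", function(x, ...) standardGeneric("species"))

#' @rdname accessors
#' @export
setGeneric("bondPartners", function(x, ...) standardGeneric("bondPartners"))

#' @rdname accessors
#' @export
setGeneric("observables", function(x, ...) standardGeneric("observables"))

#' @rdname accessors
#' @export
setGeneric("snapshots", function(x, ...) standardGeneric("snapshots"))
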