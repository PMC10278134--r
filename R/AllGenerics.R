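#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor family for the package's S4 containers; use these instead of
#' reaching into slots.
#'
#' @param object an S4 object from this package
#' @param ... unused
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frequencies", function(object, ...) standardGeneric("frequencies"))

#' @rdname accessors
#' @export
setGeneric("modeVectors", function(object, ...) standardGeneric("modeVectors"))

#' @rdname accessors
#' @export
setGeneric("atomMasses", function(object, ...) standardGeneric("atomMasses"))

#' @rdname accessors
#' @export
setGeneric("hrFactors", function(object, ...) standardGeneric("hrFactors"))

#' @rdname accessors
#' @export
setGeneric("reorgEnergies", function(object, ...) standardGeneric("reorgEnergies"))

#' @rdname accessors
#' @export
setGeneric("totalReorg", function(object, ...) standardGeneric("totalReorg"))

#' @rdname accessors
#' @export
setGeneric("energyGrid", function(object, ...) standardGeneric("energyGrid"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(object, ...) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object, ...) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("excitationEnergies",
           function(object, ...) standardGeneric("excitationEnergies"))

#' @rdname accessors
#' @export
setGeneric("oscStrengths", function(object, ...) standardGeneric("oscStrengths"))

#' @rdname accessors
#' @export
setGeneric("frameState", function(object, ...) standardGeneric("frameState"))

#' @rdname accessors
#' @export
setGeneric("frameReplica", function(object, ...) standardGeneric("frameReplica"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object, ...) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(object, ...) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("coords", function(object, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("ciBounds", function(object, ...) standardGeneric("ciBounds"))
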