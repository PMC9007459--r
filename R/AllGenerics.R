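#' Accessors for imsfold S4 containers
#'
#' Small accessor generics so user code never touches slots directly:
#' `ccsAxis()` and `intensity()` for [CCSProfile-class] /
#' [CIUFingerprint-class]; `voltages()` and `fingerprintMatrix()` for
#' fingerprints; `components()` and `rSquared()` for [ConformerFit-class];
#' `atoms()` and `coords()` for [Structure-class] / [Trajectory-class];
#' `nFrames()`, `getFrame()` and `energies()` for trajectories; `beads()`
#' and `contacts()` for [GoModel-class].
#'
#' @param object an imsfold S4 object.
#' @param i frame index for `getFrame`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ccsAxis", function(object) standardGeneric("ccsAxis"))
#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("voltages", function(object) standardGeneric("voltages"))
#' @rdname accessors
#' @export
setGeneric("fingerprintMatrix",
           function(object) standardGeneric("fingerprintMatrix"))
#' @rdname accessors
#' @export
setGeneric("components", function(object) standardGeneric("components"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("getFrame", function(object, i) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setGeneric("energies", function(object) standardGeneric("energies"))
#' @rdname accessors
#' @export
setGeneric("beads", function(object) standardGeneric("beads"))
#' @rdname accessors
#' @export
setGeneric("contacts", function(object) standardGeneric("contacts"))

#' @rdname accessors
#' @export
setMethod("ccsAxis", "CCSProfile", function(object) object@axis)
#' @rdname accessors
#' @export
setMethod("ccsAxis", "CIUFingerprint", function(object) object@ccsAxis)
#' @rdname accessors
#' @export
setMethod("ccsAxis", "ConformerFit", function(object) object@axis)
#' @rdname accessors
#' @export
setMethod("intensity", "CCSProfile", function(object) object@intensity)
#' @rdname accessors
#' @export
setMethod("voltages", "CIUFingerprint", function(object) object@voltages)
#' @rdname accessors
#' @export
setMethod("fingerprintMatrix", "CIUFingerprint",
          function(object) object@matrix)
#' @rdname accessors
#' @export
setMethod("components", "ConformerFit", function(object) object@components)
#' @rdname accessors
#' @export
setMethod("rSquared", "ConformerFit", function(object) object@rSquared)
#' @rdname accessors
#' @export
setMethod("rSquared", "CalibrationModel", function(object) object@r2)
#' @rdname accessors
#' @export
setMethod("atoms", "Structure", function(object) object@atoms)
#' @rdname accessors
#' @export
setMethod("atoms", "Trajectory", function(object) object@atoms)
#' @rdname accessors
#' @export
setMethod("coords", "Structure", function(object) {
  m <- as.matrix(object@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
})
#' @rdname accessors
#' @export
setMethod("coords", "Trajectory", function(object) object@coords)
#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(object) dim(object@coords)[3])
#' @rdname accessors
#' @export
setMethod("getFrame", "Trajectory", function(object, i) {
  stopifnot(i >= 1, i <= nFrames(object))
  a <- object@atoms
  a$x <- object@coords[, 1, i]
  a$y <- object@coords[, 2, i]
  a$z <- object@coords[, 3, i]
  new("Structure", atoms = a)
})
#' @rdname accessors
#' @export
setMethod("energies", "Trajectory", function(object) object@energies)
#' @rdname accessors
#' @export
setMethod("beads", "GoModel", function(object) object@beads)
#' @rdname accessors
#' @export
setMethod("contacts", "GoModel", function(object) object@contacts)
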