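#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics used across the package classes: conformer and
#' residue identity, shift values, assignment masks, weights and order
#' parameters. Accessors are the supported way to reach slot contents.
#'
#' @param object an object of one of the package classes.
#' @param x an object of one of the package classes.
#' @return The corresponding slot content (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("entityId", function(object) standardGeneric("entityId"))

#' @rdname accessors
#' @export
setGeneric("residueNumbers", function(object) standardGeneric("residueNumbers"))

#' @rdname accessors
#' @export
setGeneric("residueNames", function(object) standardGeneric("residueNames"))

#' @rdname accessors
#' @export
setGeneric("shiftValues", function(object) standardGeneric("shiftValues"))

#' @rdname accessors
#' @export
setGeneric("assignedMask", function(object) standardGeneric("assignedMask"))

#' @rdname accessors
#' @export
setGeneric("conformerIds", function(object) standardGeneric("conformerIds"))

#' @rdname accessors
#' @export
setGeneric("ensembleWeights", function(object) standardGeneric("ensembleWeights"))

#' @rdname accessors
#' @export
setGeneric("supportSet", function(object) standardGeneric("supportSet"))

#' @rdname accessors
#' @export
setGeneric("perAtomR2", function(object) standardGeneric("perAtomR2"))

#' @rdname accessors
#' @export
setGeneric("totalR2", function(object) standardGeneric("totalR2"))

#' @rdname accessors
#' @export
setGeneric("residualNorm", function(object) standardGeneric("residualNorm"))

#' @rdname accessors
#' @export
setGeneric("s2Values", function(object) standardGeneric("s2Values"))

#' @rdname accessors
#' @export
setGeneric("scalingParams", function(object) standardGeneric("scalingParams"))
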