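#' @include AllClasses.R
NULL

#' Elastic stiffness of a bending test
#'
#' For a [LoadDisplCurve-class], detects the linear elastic range and
#' returns its least-squares slope (see [analyzeCurve] for the window rule);
#' for a [MechSummary-class], extracts the stored value.
#'
#' @param object a curve or summary.
#' @param ... passed to the curve method.
#' @return numeric stiffness in N/mm (curve method: with attributes
#'   `window` and `r2`).
#' @export
setGeneric("elasticStiffness",
           function(object, ...) standardGeneric("elasticStiffness"))

#' Ultimate load of a bending test
#'
#' Maximum force sustained before failure.
#'
#' @param object a [LoadDisplCurve-class] or [MechSummary-class].
#' @param ... unused.
#' @return numeric force in N (curve method: with attribute `index`).
#' @export
setGeneric("ultimateLoad",
           function(object, ...) standardGeneric("ultimateLoad"))

#' Yield load of a bending test
#'
#' Force at the changing point between the elastic and plastic ranges,
#' detected as the first departure of the measured curve from the
#' extrapolated elastic line.
#'
#' @param object a [LoadDisplCurve-class] or [MechSummary-class].
#' @param ... passed to the curve method.
#' @return numeric force in N.
#' @export
setGeneric("yieldLoad", function(object, ...) standardGeneric("yieldLoad"))

#' @rdname voxelSize
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname intensities
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname maskArray
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))

#' @rdname feStiffness
#' @export
setGeneric("feStiffness", function(object) standardGeneric("feStiffness"))

#' @rdname displacements
#' @export
setGeneric("displacements",
           function(object) standardGeneric("displacements"))

#' @rdname tissueModulus
#' @export
setGeneric("tissueModulus",
           function(object) standardGeneric("tissueModulus"))
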