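#' @include AllClasses.R
NULL

#' Accessors for TILField, TILSpecimen and KFunctionEstimate
#'
#' Slot access goes through these accessors, never `@`.
#'
#' @param x a [TILField-class], [TILSpecimen-class] or
#'   [KFunctionEstimate-class] object, as appropriate.
#' @return `cells()` the cell data.frame; `fieldId()` the field identifier;
#'   `fieldWidth()`/`fieldHeight()` dimensions in micrometres; `fieldArea()`
#'   the area alpha in square micrometres; `nCells()` the number of
#'   segmented (DAPI+) cells; `patientId()`, `arm()`, `timepoint()` specimen
#'   labels; `fields()` the list of fields; `kValues()`/`radii()` the
#'   K-function estimate and its radii.
#' @name accessors
#' @examples
#' f <- simulateCSRField(fieldSimConfig(intensities = c(CD8 = 1e-4)), seed = 1)
#' nCells(f); fieldArea(f)
NULL

#' @rdname accessors
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))
#' @rdname accessors
#' @export
setMethod("cells", "TILField", function(x) x@cells)

#' @rdname accessors
#' @export
setGeneric("fieldId", function(x) standardGeneric("fieldId"))
#' @rdname accessors
#' @export
setMethod("fieldId", "TILField", function(x) x@fieldId)

#' @rdname accessors
#' @export
setGeneric("fieldWidth", function(x) standardGeneric("fieldWidth"))
#' @rdname accessors
#' @export
setMethod("fieldWidth", "TILField", function(x) x@widthUm)

#' @rdname accessors
#' @export
setGeneric("fieldHeight", function(x) standardGeneric("fieldHeight"))
#' @rdname accessors
#' @export
setMethod("fieldHeight", "TILField", function(x) x@heightUm)

#' @rdname accessors
#' @export
setGeneric("fieldArea", function(x) standardGeneric("fieldArea"))
#' @rdname accessors
#' @export
setMethod("fieldArea", "TILField", function(x) x@widthUm * x@heightUm)

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setMethod("nCells", "TILField", function(x) nrow(x@cells))

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setMethod("patientId", "TILSpecimen", function(x) x@patientId)

#' @rdname accessors
#' @export
setGeneric("arm", function(x) standardGeneric("arm"))
#' @rdname accessors
#' @export
setMethod("arm", "TILSpecimen", function(x) x@arm)

#' @rdname accessors
#' @export
setGeneric("timepoint", function(x) standardGeneric("timepoint"))
#' @rdname accessors
#' @export
setMethod("timepoint", "TILSpecimen", function(x) x@timepoint)

#' @rdname accessors
#' @export
setGeneric("fields", function(x) standardGeneric("fields"))
#' @rdname accessors
#' @export
setMethod("fields", "TILSpecimen", function(x) x@fields)

#' @rdname accessors
#' @export
setGeneric("kValues", function(x) standardGeneric("kValues"))
#' @rdname accessors
#' @export
setMethod("kValues", "KFunctionEstimate",
          function(x) stats::setNames(x@kValues, x@radii))

#' @rdname accessors
#' @export
setGeneric("radii", function(x) standardGeneric("radii"))
#' @rdname accessors
#' @export
setMethod("radii", "KFunctionEstimate", function(x) x@radii)
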