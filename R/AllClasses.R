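#' @include conditions.R
NULL

#' Marker panel of the mIHC assay
#'
#' The seven-channel panel: DAPI (nuclear counterstain, the denominator
#' population) plus six lineage/differentiation markers. Every cell table
#' must carry one 0/1 column per marker.
#'
#' @return Character vector of marker names.
#' @export
#' @examples
#' tilMarkers()
tilMarkers <- function() {
  c("DAPI", "CD4", "CD8", "CD20", "CD127", "KLRG1", "FoxP3")
}

.cellRequiredCols <- function() c("cell_id", "x_um", "y_um", tilMarkers())

#' @title TILField: one imaged mIHC field
#'
#' @description An axis-aligned rectangular field imaged at 20x, holding the
#' segmented cells as a data.frame with one row per DAPI+ nucleus: `cell_id`,
#' coordinates `x_um`/`y_um` (micrometres, origin at the lower-left corner),
#' one logical column per panel marker, and, once [assignPhenotypes()] has
#' run, a `phenotype` label and an `ambiguous` flag.
#'
#' @slot fieldId character identifier.
#' @slot widthUm,heightUm field dimensions in micrometres (> 0).
#' @slot cells data.frame of cells; all coordinates inside the rectangle and
#'   DAPI TRUE for every row.
#'
#' @aliases TILField-class
#' @exportClass TILField
setClass("TILField",
  representation(fieldId = "character", widthUm = "numeric",
                 heightUm = "numeric", cells = "data.frame"))

setValidity("TILField", function(object) {
  msgs <- character()
  if (length(object@fieldId) != 1L || is.na(object@fieldId))
    msgs <- c(msgs, "fieldId must be a single non-NA string")
  for (d in c("widthUm", "heightUm")) {
    v <- slot(object, d)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msgs <- c(msgs, sprintf("%s must be a single positive number", d))
  }
  cells <- object@cells
  missing <- setdiff(.cellRequiredCols(), names(cells))
  if (length(missing))
    msgs <- c(msgs, sprintf("cells is missing column(s): %s",
                            paste(missing, collapse = ", ")))
  if (!length(msgs) && nrow(cells)) {
    if (anyDuplicated(cells$cell_id))
      msgs <- c(msgs, "duplicate cell_id within field")
    bad <- !is.finite(cells$x_um) | !is.finite(cells$y_um) |
      cells$x_um < 0 | cells$x_um > object@widthUm |
      cells$y_um < 0 | cells$y_um > object@heightUm
    if (any(bad))
      msgs <- c(msgs, sprintf(
        "cell(s) outside the %g x %g um field rectangle: %s",
        object@widthUm, object@heightUm,
        paste(utils::head(cells$cell_id[bad], 5L), collapse = ", ")))
    for (m in tilMarkers()) {
      if (!is.logical(cells[[m]]) || anyNA(cells[[m]]))
        msgs <- c(msgs, sprintf("marker column '%s' must be logical, no NA", m))
    }
    if (is.logical(cells$DAPI) && !all(cells$DAPI))
      msgs <- c(msgs, "DAPI must be TRUE for every segmented cell")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TILField
#'
#' @param fieldId identifier.
#' @param width_um,height_um field dimensions in micrometres.
#' @param cells data.frame with columns `cell_id`, `x_um`, `y_um` and one
#'   logical (or 0/1) column per marker in [tilMarkers()].
#' @return A validated [TILField-class] object.
#' @export
#' @examples
#' cells <- data.frame(cell_id = "c1", x_um = 5, y_um = 5,
#'                     DAPI = TRUE, CD4 = FALSE, CD8 = TRUE, CD20 = FALSE,
#'                     CD127 = FALSE, KLRG1 = FALSE, FoxP3 = FALSE)
#' TILField("f1", 100, 100, cells)
TILField <- function(fieldId, width_um, height_um, cells) {
  cells <- as.data.frame(cells)
  for (m in intersect(tilMarkers(), names(cells))) {
    v <- cells[[m]]
    if (is.numeric(v)) {
      if (!all(v %in% c(0, 1)))
        tilParseStop(sprintf("marker column '%s' has non-0/1 values", m))
      cells[[m]] <- as.logical(v)
    }
  }
  if (!is.null(cells$cell_id)) cells$cell_id <- as.character(cells$cell_id)
  obj <- methods::new("TILField", fieldId = as.character(fieldId),
                      widthUm = as.numeric(width_um),
                      heightUm = as.numeric(height_um), cells = cells)
  obj
}

# fast internal constructor for the simulator: skips validity on trusted input
.newField <- function(fieldId, width_um, height_um, cells) {
  obj <- methods::new("TILField")
  obj@fieldId <- fieldId
  obj@widthUm <- width_um
  obj@heightUm <- height_um
  obj@cells <- cells
  obj
}

#' @title TILSpecimen: one patient-by-timepoint sample
#'
#' @description A specimen groups the imaged fields of one FFPE slide
#' together with its treatment-arm and timepoint labels. The study design
#' images ten fields per slide; at least one is required.
#'
#' @slot patientId character identifier.
#' @slot arm "NAC" (neoadjuvant chemotherapy) or "NAPC" (chemotherapy plus
#'   pembrolizumab).
#' @slot timepoint "pre" (biopsy) or "post" (surgical resection).
#' @slot fields list of [TILField-class] objects.
#'
#' @aliases TILSpecimen-class
#' @exportClass TILSpecimen
setClass("TILSpecimen",
  representation(patientId = "character", arm = "character",
                 timepoint = "character", fields = "list"))

setValidity("TILSpecimen", function(object) {
  msgs <- character()
  if (length(object@patientId) != 1L || is.na(object@patientId))
    msgs <- c(msgs, "patientId must be a single non-NA string")
  if (!identical(length(object@arm), 1L) || !object@arm %in% c("NAC", "NAPC"))
    msgs <- c(msgs, "arm must be 'NAC' or 'NAPC'")
  if (!identical(length(object@timepoint), 1L) ||
      !object@timepoint %in% c("pre", "post"))
    msgs <- c(msgs, "timepoint must be 'pre' or 'post'")
  if (length(object@fields) < 1L)
    msgs <- c(msgs, "a specimen needs at least one field")
  if (!all(vapply(object@fields, methods::is, logical(1), "TILField")))
    msgs <- c(msgs, "fields must all be TILField objects")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TILSpecimen
#'
#' @param patientId identifier.
#' @param arm "NAC" or "NAPC".
#' @param timepoint "pre" or "post".
#' @param fields list of [TILField-class] objects (at least one).
#' @return A validated [TILSpecimen-class] object.
#' @export
TILSpecimen <- function(patientId, arm, timepoint, fields) {
  methods::new("TILSpecimen", patientId = as.character(patientId),
               arm = arm, timepoint = timepoint, fields = fields)
}

.newSpecimen <- function(patientId, arm, timepoint, fields) {
  obj <- methods::new("TILSpecimen")
  obj@patientId <- patientId
  obj@arm <- arm
  obj@timepoint <- timepoint
  obj@fields <- fields
  obj
}

#' @title KFunctionEstimate: a bivariate K-function estimate for one field
#'
#' @description Carries the estimated cross-type K values over a radius
#' sweep together with everything needed to interpret them: the
#' normalization (`"cross"` uses n_ref * n_target; `"as_printed"` uses
#' n*(n-1) and is only defined when reference and target are the same point
#' set), the edge correction (`"none"` or `"translation"`), the point counts
#' and the field area. Under complete spatial randomness the expectation of
#' the translation-corrected estimate is pi*r^2.
#'
#' @slot refPhenotype,targetPhenotype phenotype selectors.
#' @slot radii radii in micrometres (strictly increasing).
#' @slot kValues estimated K(r), in square micrometres, aligned to `radii`.
#' @slot normalization "cross" or "as_printed".
#' @slot correction "none" or "translation".
#' @slot nRef,nTarget point counts.
#' @slot areaUm2 field area alpha in square micrometres.
#'
#' @aliases KFunctionEstimate-class
#' @exportClass KFunctionEstimate
setClass("KFunctionEstimate",
  representation(refPhenotype = "character", targetPhenotype = "character",
                 radii = "numeric", kValues = "numeric",
                 normalization = "character", correction = "character",
                 nRef = "integer", nTarget = "integer", areaUm2 = "numeric"))

setValidity("KFunctionEstimate", function(object) {
  msgs <- character()
  if (length(object@kValues) != length(object@radii))
    msgs <- c(msgs, "kValues and radii must align")
  if (any(object@radii <= 0) || is.unsorted(object@radii, strictly = TRUE))
    msgs <- c(msgs, "radii must be positive and strictly increasing")
  if (any(object@kValues < 0)) msgs <- c(msgs, "kValues must be non-negative")
  if (!object@normalization %in% c("cross", "as_printed"))
    msgs <- c(msgs, "normalization must be 'cross' or 'as_printed'")
  if (!object@correction %in% c("none", "translation"))
    msgs <- c(msgs, "correction must be 'none' or 'translation'")
  if (object@areaUm2 <= 0) msgs <- c(msgs, "areaUm2 must be positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TILField", function(object) {
  cat(sprintf("TILField '%s': %g x %g um (%.0f um^2), %d cells\n",
              object@fieldId, object@widthUm, object@heightUm,
              object@widthUm * object@heightUm, nrow(object@cells)))
  if ("phenotype" %in% names(object@cells)) {
    tab <- table(object@cells$phenotype)
    cat("  phenotypes:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  } else {
    cat("  phenotypes: not yet assigned (run assignPhenotypes())\n")
  }
})

setMethod("show", "TILSpecimen", function(object) {
  n <- vapply(object@fields, function(f) nrow(f@cells), integer(1))
  cat(sprintf("TILSpecimen '%s' [%s, %s]: %d field(s), %d cells total\n",
              object@patientId, object@arm, object@timepoint,
              length(object@fields), sum(n)))
})

setMethod("show", "KFunctionEstimate", function(object) {
  cat(sprintf(
    "KFunctionEstimate %s -> %s (normalization=%s, correction=%s)\n",
    object@refPhenotype, object@targetPhenotype, object@normalization,
    object@correction))
  cat(sprintf("  n_ref=%d, n_target=%d, area=%.0f um^2\n",
              object@nRef, object@nTarget, object@areaUm2))
  print(data.frame(r_um = object@radii, K_um2 = object@kValues,
                   csr_pi_r2 = pi * object@radii^2))
})
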