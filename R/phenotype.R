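#' @include AllClasses.R accessors.R
NULL

#' Canonical TIL phenotype selectors
#'
#' The seven phenotypes analysed throughout: CD20+ B cells, CD4+ T cells
#' and their CD127+ and FoxP3+ (Treg) subsets, CD8+ T cells and their
#' CD127+ (memory-like) and KLRG1+ (effector-like) subsets. A selector is
#' either a lineage (`"B_cell"`, `"CD4_T"`, `"CD8_T"`, `"other"`,
#' `"DAPI"`) or a lineage plus subset markers joined by `+`
#' (e.g. `"CD8_T+CD127"`). Subset selectors count cells whose lineage label
#' matches and whose subset marker is positive, so subset densities nest
#' inside their lineage density.
#'
#' @return character vector of the seven selectors.
#' @export
#' @examples
#' tilPhenotypes()
tilPhenotypes <- function() {
  c("B_cell", "CD4_T", "CD4_T+CD127", "CD4_T+FoxP3",
    "CD8_T", "CD8_T+CD127", "CD8_T+KLRG1")
}

.legalSubsets <- list(CD4_T = c("CD127", "FoxP3"),
                      CD8_T = c("CD127", "KLRG1"),
                      B_cell = character(), other = character(),
                      DAPI = character())

.parseSelector <- function(phenotype) {
  parts <- strsplit(phenotype, "+", fixed = TRUE)[[1]]
  lineage <- parts[1]
  subsets <- parts[-1]
  if (!lineage %in% names(.legalSubsets))
    tilContractStop(sprintf("unknown phenotype lineage '%s'", lineage))
  bad <- setdiff(subsets, .legalSubsets[[lineage]])
  if (length(bad))
    tilContractStop(sprintf("subset marker(s) %s not defined for lineage %s",
                            paste(bad, collapse = "/"), lineage))
  list(lineage = lineage, subsets = subsets)
}

#' Assign TIL phenotypes from marker calls
#'
#' Exclusive lineage gating on the binary marker calls: CD20+ cells are
#' B cells; otherwise CD4+ cells are CD4 T cells; otherwise CD8+ cells are
#' CD8 T cells; everything else (DAPI-only) is "other". A cell positive for
#' more than one lineage marker (CD20 with CD4 or CD8, or CD4 with CD8)
#' cannot be gated: it is assigned "other" and flagged in the `ambiguous`
#' column, with a warning reporting the count — conflicts are surfaced,
#' never silently dropped and never resolved into a fabricated lineage.
#' Subset markers (CD127, KLRG1, FoxP3) are not part of the gate; subset
#' membership is read off the marker columns by the selector machinery.
#'
#' @param x a [TILField-class] or [TILSpecimen-class].
#' @return the same object with `phenotype` and `ambiguous` columns added
#'   to its cell table(s).
#' @export
#' @examples
#' f <- simulateCSRField(fieldSimConfig(intensities = c(CD8 = 2e-4)), seed = 1)
#' table(cells(assignPhenotypes(f))$phenotype)
setGeneric("assignPhenotypes", function(x) standardGeneric("assignPhenotypes"))

#' @rdname assignPhenotypes
#' @export
setMethod("assignPhenotypes", "TILField", function(x) {
  df <- x@cells
  n <- nrow(df)
  ambiguous <- (df$CD20 & (df$CD4 | df$CD8)) | (df$CD4 & df$CD8)
  phenotype <- rep("other", n)
  phenotype[df$CD8]  <- "CD8_T"
  phenotype[df$CD4]  <- "CD4_T"
  phenotype[df$CD20] <- "B_cell"
  phenotype[ambiguous] <- "other"
  if (any(ambiguous))
    warning(sprintf(
      "field %s: %d cell(s) with conflicting lineage markers gated to 'other'",
      x@fieldId, sum(ambiguous)), call. = FALSE)
  df$phenotype <- phenotype
  df$ambiguous <- ambiguous
  x@cells <- df
  x
})

#' @rdname assignPhenotypes
#' @export
setMethod("assignPhenotypes", "TILSpecimen", function(x) {
  x@fields <- lapply(x@fields, assignPhenotypes)
  x
})

.requirePhenotypes <- function(field) {
  if (!"phenotype" %in% names(field@cells))
    tilContractStop("phenotypes not assigned; run assignPhenotypes() first")
}

#' Logical mask of cells matching a phenotype selector
#'
#' @param field a phenotyped [TILField-class].
#' @param phenotype a selector, see [tilPhenotypes()].
#' @return logical vector over the field's cells.
#' @export
phenotypeMask <- function(field, phenotype) {
  .requirePhenotypes(field)
  sel <- .parseSelector(phenotype)
  df <- field@cells
  if (sel$lineage == "DAPI") return(df$DAPI)
  mask <- df$phenotype == sel$lineage
  for (m in sel$subsets) mask <- mask & df[[m]]
  mask
}

#' Per-field infiltration density as a ratio to DAPI
#'
#' The count of cells matching `phenotype` divided by the DAPI+ count
#' (i.e. all segmented cells) — the standard mIHC positivity ratio. Subset
#' selectors nest: a CD8+CD127+ cell counts toward both `"CD8_T+CD127"`
#' and `"CD8_T"`.
#'
#' @param field a phenotyped [TILField-class].
#' @param phenotype selector, see [tilPhenotypes()].
#' @return fraction in \[0, 1\].
#' @export
fieldDensity <- function(field, phenotype) {
  .requirePhenotypes(field)
  n <- nrow(field@cells)
  if (n == 0L)
    tilValidationStop(sprintf(
      "field %s has no DAPI+ cells: density undefined", field@fieldId))
  sum(phenotypeMask(field, phenotype)) / n
}

.specimenDensity <- function(specimen, phenotype,
                             aggregate = c("mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  num <- vapply(specimen@fields,
                function(f) sum(phenotypeMask(f, phenotype)), numeric(1))
  den <- vapply(specimen@fields, nCells, integer(1))
  if (all(den == 0L))
    tilValidationStop(sprintf("specimen %s has no cells in any field",
                              specimen@patientId))
  keep <- den > 0L
  if (aggregate == "mean") mean(num[keep] / den[keep])
  else sum(num[keep]) / sum(den[keep])
}

#' Specimen-level density table
#'
#' One row per specimen and phenotype, carrying the per-field ratios
#' aggregated across the specimen's fields (~10 per slide in the study
#' design). Aggregation is the unweighted mean of per-field ratios by
#' default; `"pooled"` divides total positive count by total DAPI count
#' instead. When a clinical table is supplied, arm labels are taken from it
#' and response labels are joined on for downstream group comparisons.
#'
#' @param specimens list of phenotyped [TILSpecimen-class] objects.
#' @param phenotypes selectors to tabulate; default the seven canonical
#'   phenotypes.
#' @param aggregate "mean" (default) or "pooled".
#' @param clinical optional clinical data.frame from [readClinicalTable()]
#'   (or the simulator); joined by `patient_id` to attach response labels.
#' @return data.frame with columns patient_id, arm, timepoint, phenotype,
#'   n_fields, density (and response if clinical is given).
#' @export
specimenDensityTable <- function(specimens, phenotypes = tilPhenotypes(),
                                 aggregate = c("mean", "pooled"),
                                 clinical = NULL) {
  aggregate <- match.arg(aggregate)
  rows <- lapply(specimens, function(sp) {
    if (length(sp@fields) == 0L)
      tilValidationStop(sprintf("specimen %s has no fields", sp@patientId))
    data.frame(
      patient_id = sp@patientId, arm = sp@arm, timepoint = sp@timepoint,
      phenotype = phenotypes, n_fields = length(sp@fields),
      density = vapply(phenotypes,
                       function(p) .specimenDensity(sp, p, aggregate),
                       numeric(1)),
      row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (!is.null(clinical)) {
    resp <- responseTable(clinical)
    out$response <- resp$category[match(out$patient_id, resp$patient_id)]
  }
  out
}
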