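#' @include conditions.R
NULL

#' Mean viable-tumor percentage across slides
#'
#' Pathological response is read per patient from the HE slides: each
#' slide's percentage of viable tumor area is estimated and the arithmetic
#' mean over the patient's 1-5 slides is the final response value.
#'
#' @param slide_percents numeric vector of per-slide percentages in
#'   \[0, 100\].
#' @return mean percentage.
#' @export
#' @examples
#' meanViablePercent(c(5, 10, 15))  # 10
meanViablePercent <- function(slide_percents) {
  if (length(slide_percents) < 1L)
    tilValidationStop("at least one slide value is required")
  if (anyNA(slide_percents) ||
      any(slide_percents < 0 | slide_percents > 100))
    tilValidationStop("viable percentages must lie in [0, 100]")
  mean(slide_percents)
}

#' Classify pathological response
#'
#' pCR (pathological complete response) is the absence of viable tumor
#' cells (mean 0%); MPR (major pathological response) is 10% or less viable
#' tumor (the boundary 10.0 is MPR); everything above 10% is non-MPR.
#' pCR is a subset of MPR: rate computations count pCR patients as MPR.
#'
#' @param mean_viable mean viable-tumor percentage in \[0, 100\].
#' @return one of "pCR", "MPR", "non-MPR" (factor-free character).
#' @export
#' @examples
#' classifyResponse(0)    # "pCR"
#' classifyResponse(10)   # "MPR"
#' classifyResponse(12.5) # "non-MPR"
classifyResponse <- function(mean_viable) {
  if (length(mean_viable) != 1L || is.na(mean_viable) ||
      mean_viable < 0 || mean_viable > 100)
    tilValidationStop("mean viable percentage must be a value in [0, 100]")
  if (mean_viable == 0) "pCR"
  else if (mean_viable <= 10) "MPR"
  else "non-MPR"
}

#' Per-patient response calls from a clinical table
#'
#' @param clinical data.frame from [readClinicalTable()] (or the
#'   simulator), with `patient_id`, `arm` and the list-column
#'   `viable_percent_per_slide`.
#' @return data.frame with patient_id, arm, mean_viable_percent, category.
#' @export
responseTable <- function(clinical) {
  mv <- vapply(clinical$viable_percent_per_slide, meanViablePercent,
               numeric(1))
  data.frame(patient_id = clinical$patient_id, arm = clinical$arm,
             mean_viable_percent = mv,
             category = vapply(mv, classifyResponse, character(1)),
             stringsAsFactors = FALSE)
}

# display rounding: one decimal, half away from zero (base round() is
# round-half-even)
.round1up <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

#' Per-arm MPR and pCR rates
#'
#' MPR counts include pCR patients (0% viable satisfies "10% or less").
#' Rates are percentages rounded to one decimal, half away from zero.
#'
#' @param calls data.frame from [responseTable()].
#' @return data.frame with one row per arm: n, mpr_n, mpr_rate, pcr_n,
#'   pcr_rate.
#' @export
armResponseRates <- function(calls) {
  if (!nrow(calls)) tilValidationStop("empty response table")
  arms <- sort(unique(calls$arm))
  out <- do.call(rbind, lapply(arms, function(a) {
    sub <- calls[calls$arm == a, , drop = FALSE]
    mpr <- sum(sub$category %in% c("MPR", "pCR"))
    pcr <- sum(sub$category == "pCR")
    data.frame(arm = a, n = nrow(sub), mpr_n = mpr,
               mpr_rate = .round1up(100 * mpr / nrow(sub)),
               pcr_n = pcr, pcr_rate = .round1up(100 * pcr / nrow(sub)))
  }))
  rownames(out) <- NULL
  out
}

#' Tertiary lymphoid structure density
#'
#' Number of TLSs per square millimetre of evaluated tumor area. TLSs are
#' identified morphologically upstream and consumed as counts.
#'
#' @param tls_count non-negative integer count(s).
#' @param evaluated_area_mm2 evaluated area(s) in square millimetres (> 0).
#' @return density in structures per square millimetre.
#' @export
#' @examples
#' tlsDensity(3, 2)  # 1.5
tlsDensity <- function(tls_count, evaluated_area_mm2) {
  if (any(is.na(tls_count)) || any(tls_count < 0) ||
      any(tls_count != round(tls_count)))
    tilValidationStop("tls_count must be non-negative integers")
  if (any(is.na(evaluated_area_mm2)) || any(evaluated_area_mm2 <= 0))
    tilValidationStop("evaluated area must be > 0")
  tls_count / evaluated_area_mm2
}

#' TLS densities for an annotation table
#'
#' @param annotations data.frame from [readTLSTable()].
#' @return the same data.frame with a `tls_density` column appended.
#' @export
tlsDensityTable <- function(annotations) {
  annotations$tls_density <- tlsDensity(annotations$tls_count,
                                        annotations$evaluated_area_mm2)
  annotations
}
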