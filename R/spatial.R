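#' @include AllClasses.R phenotype.R
NULL

#' Euclidean distance between points
#'
#' @param p,q length-2 numeric vectors `(x, y)` or two-column matrices of
#'   points (recycled row-wise).
#' @return distance(s) in the coordinate units (micrometres for cell
#'   coordinates).
#' @export
#' @examples
#' euclideanDistance(c(0, 0), c(3, 4))  # 5
euclideanDistance <- function(p, q) {
  p <- if (is.matrix(p)) p else matrix(p, ncol = 2L, byrow = TRUE)
  q <- if (is.matrix(q)) q else matrix(q, ncol = 2L, byrow = TRUE)
  if (!all(is.finite(p)) || !all(is.finite(q)))
    tilContractStop("coordinates must be finite")
  d <- cbind(p[, 1] - q[, 1], p[, 2] - q[, 2])
  out <- sqrt(d[, 1]^2 + d[, 2]^2)
  if (length(out) == 1L) out[[1]] else out
}

.xyid <- function(points) {
  nm <- names(points)
  if (!all(c("x_um", "y_um") %in% nm))
    tilContractStop("point sets need x_um and y_um columns")
  id <- if ("cell_id" %in% nm) as.character(points$cell_id) else NULL
  list(x = as.numeric(points$x_um), y = as.numeric(points$y_um), id = id)
}

#' Count target cells within a radius of each reference cell
#'
#' For every reference point, the number of target points at Euclidean
#' distance `<= r` (inclusive). When the same physical cell appears in both
#' sets — matched by `cell_id` — it is excluded from its own count. The
#' planar search is grid-accelerated but returns exactly the brute-force
#' result; `torus = TRUE` uses wrap-around distances (edge-effect-free, for
#' calibration against complete spatial randomness).
#'
#' @param ref,target data.frames with columns `x_um`, `y_um` and optionally
#'   `cell_id`.
#' @param r radius, same units as the coordinates; must be > 0.
#' @param torus use toroidal distances (requires `width`/`height`).
#' @param width,height field dimensions; required for `torus`.
#' @return integer vector of counts, one per reference row.
#' @export
#' @examples
#' ref <- data.frame(x_um = 0, y_um = 0)
#' tg  <- data.frame(x_um = c(10, 0, 31), y_um = c(0, 29, 0))
#' countWithinRadius(ref, tg, r = 30)  # 2
countWithinRadius <- function(ref, target, r, torus = FALSE,
                              width = NULL, height = NULL) {
  assertScalarNumber(r, "r", positive = TRUE)
  a <- .xyid(ref); b <- .xyid(target)
  if (torus && (is.null(width) || is.null(height)))
    tilContractStop("toroidal distances need field width and height")
  if (is.null(width))  width  <- max(a$x, b$x, 0) + r
  if (is.null(height)) height <- max(a$y, b$y, 0) + r
  if (!is.null(a$id) && !is.null(b$id)) {
    universe <- unique(c(a$id, b$id))
    ida <- match(a$id, universe) - 1L
    idb <- match(b$id, universe) - 1L
  } else {
    ida <- rep(-1L, length(a$x))
    idb <- rep(-1L, length(b$x))
  }
  cpp_count_within_radius(a$x, a$y, ida, b$x, b$y, idb,
                          r, torus, width, height)
}

.fieldPair <- function(field, refPhenotype, targetPhenotype) {
  .requirePhenotypes(field)
  df <- field@cells
  mr <- phenotypeMask(field, refPhenotype)
  mt <- phenotypeMask(field, targetPhenotype)
  # row indices double as cell identities for self-exclusion
  list(xr = df$x_um[mr], yr = df$y_um[mr], ir = which(mr) - 1L,
       xt = df$x_um[mt], yt = df$y_um[mt], it = which(mt) - 1L)
}

#' Proximity density: mean within-radius neighbour count
#'
#' The average, over all reference-phenotype cells of a field, of the
#' number of target-phenotype cells whose nuclear centres lie within `r`
#' micrometres (default 30, the radius used for cell-neighbourhood
#' analysis). Counts are raw — no edge correction is applied, matching the
#' definition of the proximity readout; the resulting edge deficit is a
#' property of the estimator, characterised in the package tests.
#'
#' @param field a phenotyped [TILField-class].
#' @param refPhenotype,targetPhenotype selectors, see [tilPhenotypes()].
#' @param r radius in micrometres (default 30).
#' @param torus use toroidal distances (calibration only).
#' @return mean count (cells per reference cell).
#' @export
proximityDensity <- function(field, refPhenotype, targetPhenotype, r = 30,
                             torus = FALSE) {
  assertScalarNumber(r, "r", positive = TRUE)
  p <- .fieldPair(field, refPhenotype, targetPhenotype)
  if (length(p$xr) == 0L)
    tilValidationStop(sprintf(
      "field %s has no '%s' reference cells: proximity undefined",
      field@fieldId, refPhenotype))
  counts <- cpp_count_within_radius(p$xr, p$yr, p$ir, p$xt, p$yt, p$it,
                                    r, torus, field@widthUm, field@heightUm)
  mean(counts)
}

.kEstimate <- function(field, refPhenotype, targetPhenotype, radii,
                       normalization, correction) {
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE))
    tilContractStop("radii must be positive and strictly increasing")
  p <- .fieldPair(field, refPhenotype, targetPhenotype)
  nRef <- length(p$xr); nTarget <- length(p$xt)
  if (nRef == 0L || nTarget == 0L)
    tilValidationStop(sprintf(
      "field %s: empty phenotype set ('%s' n=%d, '%s' n=%d)",
      field@fieldId, refPhenotype, nRef, targetPhenotype, nTarget))
  if (normalization == "as_printed") {
    if (!identical(refPhenotype, targetPhenotype))
      tilContractStop(paste0(
        "normalization 'as_printed' divides by n*(n-1), which is only ",
        "defined when reference and target are the same point set; use ",
        "normalization 'cross' for distinct phenotypes"))
    if (nRef < 2L)
      tilValidationStop("'as_printed' normalization needs n >= 2")
  }
  res <- cpp_k_prox_sweep(p$xr, p$yr, p$ir, p$xt, p$yt, p$it,
                          as.numeric(radii), correction == "translation",
                          field@widthUm, field@heightUm)
  alpha <- field@widthUm * field@heightUm
  D <- if (normalization == "as_printed") nRef * (nRef - 1)
       else as.numeric(nRef) * nTarget
  est <- methods::new("KFunctionEstimate",
    refPhenotype = refPhenotype, targetPhenotype = targetPhenotype,
    radii = as.numeric(radii), kValues = alpha * res$ksum / D,
    normalization = normalization, correction = correction,
    nRef = nRef, nTarget = nTarget, areaUm2 = alpha)
  list(estimate = est, counts = res$counts)
}

#' Bivariate (cross-type) K function of a field
#'
#' Estimates \deqn{\hat K(r) = \frac{\alpha}{D} \sum_{i \in ref}
#' \sum_{j \in target, j \ne i} I(d_{ij} \le r)\, e_{ij}}
#' where \eqn{\alpha} is the field area, the indicator is inclusive
#' (\eqn{d \le r}), and pairs formed by the same physical cell are
#' excluded. `normalization = "cross"` (the default) uses
#' \eqn{D = n_{ref}\, n_{target}}, appropriate for two distinct phenotypes;
#' `"as_printed"` uses the univariate \eqn{D = n(n-1)} and is only accepted
#' when reference and target are the same point set. The edge weight is
#' \eqn{e_{ij} = 1} for `correction = "none"` and the translation
#' correction \eqn{e_{ij} = WH / ((W - |\Delta x|)(H - |\Delta y|))} for
#' rectangular fields, which makes the estimator exactly unbiased for
#' \eqn{\pi r^2} under complete spatial randomness.
#'
#' @param field a phenotyped [TILField-class].
#' @param refPhenotype,targetPhenotype selectors, see [tilPhenotypes()].
#' @param radii strictly increasing positive radii in micrometres; default
#'   the standard sweep \{10, 20, 30, 40, 60, 80\}.
#' @param normalization "cross" or "as_printed".
#' @param correction "translation" (default) or "none" (the literal
#'   uncorrected sum).
#' @return a [KFunctionEstimate-class].
#' @export
bivariateK <- function(field, refPhenotype, targetPhenotype,
                       radii = c(10, 20, 30, 40, 60, 80),
                       normalization = c("cross", "as_printed"),
                       correction = c("translation", "none")) {
  normalization <- match.arg(normalization)
  correction <- match.arg(correction)
  .kEstimate(field, refPhenotype, targetPhenotype, radii,
             normalization, correction)$estimate
}

#' Radius sweep: K function and proximity density at several radii
#'
#' Evaluates the bivariate K estimate and the (uncorrected) proximity
#' density over the whole radius sweep in a single pass over the pairwise
#' distances — each pair's distance is computed once.
#'
#' @inheritParams bivariateK
#' @return list with `k`, a [KFunctionEstimate-class], and `proximity`, a
#'   data.frame with one row per radius (`radius_um`, `mean_count`,
#'   `n_ref`).
#' @export
radiusSweep <- function(field, refPhenotype, targetPhenotype,
                        radii = c(10, 20, 30, 40, 60, 80),
                        normalization = c("cross", "as_printed"),
                        correction = c("translation", "none")) {
  normalization <- match.arg(normalization)
  correction <- match.arg(correction)
  res <- .kEstimate(field, refPhenotype, targetPhenotype, radii,
                    normalization, correction)
  prox <- data.frame(radius_um = as.numeric(radii),
                     mean_count = colMeans(res$counts),
                     n_ref = nrow(res$counts))
  list(k = res$estimate, proximity = prox)
}

#' Default reference-target phenotype pairs for proximity analysis
#'
#' CD8 T cells and their CD127+/KLRG1+ subsets around CD4 T cell and
#' CD20 B cell references, plus CD4 T cells (and their CD127+ subset)
#' around B cells.
#'
#' @return data.frame with columns `ref` and `target`.
#' @export
defaultProximityPairs <- function() {
  rbind(
    expand.grid(ref = c("CD4_T", "B_cell"),
                target = c("CD8_T", "CD8_T+CD127", "CD8_T+KLRG1"),
                stringsAsFactors = FALSE),
    data.frame(ref = "B_cell", target = c("CD4_T", "CD4_T+CD127")))
}

#' Cohort-level proximity densities
#'
#' Computes, for every specimen and (reference, target) phenotype pair, the
#' specimen-level proximity density: the mean over the specimen's fields
#' (those with at least one reference cell) of the per-field mean
#' within-`r` neighbour count. Fields without reference cells are excluded
#' from the mean; specimens with no eligible field are dropped with a
#' message, never silently.
#'
#' @param specimens list of phenotyped [TILSpecimen-class] objects.
#' @param pairs data.frame with `ref` and `target` selector columns;
#'   default [defaultProximityPairs()].
#' @param r radius in micrometres (default 30).
#' @return data.frame with columns patient_id, arm, timepoint, ref, target,
#'   radius_um, n_fields_used, mean_count.
#' @export
cohortProximity <- function(specimens, pairs = defaultProximityPairs(),
                            r = 30) {
  assertScalarNumber(r, "r", positive = TRUE)
  selectors <- unique(c(pairs$ref, pairs$target))
  rows <- vector("list", length(specimens))
  for (si in seq_along(specimens)) {
    sp <- specimens[[si]]
    # per-field masks computed once, shared across pairs
    masks <- lapply(sp@fields, function(f) {
      .requirePhenotypes(f)
      lapply(stats::setNames(selectors, selectors),
             function(s) phenotypeMask(f, s))
    })
    out <- data.frame(patient_id = sp@patientId, arm = sp@arm,
                      timepoint = sp@timepoint, ref = pairs$ref,
                      target = pairs$target, radius_um = r,
                      n_fields_used = NA_integer_,
                      mean_count = NA_real_)
    for (pi in seq_len(nrow(pairs))) {
      vals <- numeric(0)
      for (fi in seq_along(sp@fields)) {
        f <- sp@fields[[fi]]
        mr <- masks[[fi]][[pairs$ref[pi]]]
        if (!any(mr)) next
        mt <- masks[[fi]][[pairs$target[pi]]]
        cnt <- cpp_count_within_radius(
          f@cells$x_um[mr], f@cells$y_um[mr], which(mr) - 1L,
          f@cells$x_um[mt], f@cells$y_um[mt], which(mt) - 1L,
          r, FALSE, f@widthUm, f@heightUm)
        vals <- c(vals, mean(cnt))
      }
      out$n_fields_used[pi] <- length(vals)
      out$mean_count[pi] <- if (length(vals)) mean(vals) else NA_real_
    }
    rows[[si]] <- out
  }
  res <- do.call(rbind, rows)
  dropped <- is.na(res$mean_count)
  if (any(dropped)) {
    message(sprintf(
      "cohortProximity: dropped %d specimen-pair combination(s) with no eligible fields",
      sum(dropped)))
    res <- res[!dropped, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}
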