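#' @include AllClasses.R phenotype.R response.R
NULL

# Exclusive simulation classes and the marker calls they imply. The seven
# TIL phenotypes plus "other" (DAPI-only stromal/tumor nuclei) partition
# the simulated cells; selector-level phenotypes (e.g. "CD8_T") are unions
# of these classes after gating.
.simClassMarkers <- list(
  B_cell    = "CD20",
  CD4       = "CD4",
  CD4_CD127 = c("CD4", "CD127"),
  CD4_FoxP3 = c("CD4", "FoxP3"),
  CD8       = "CD8",
  CD8_CD127 = c("CD8", "CD127"),
  CD8_KLRG1 = c("CD8", "KLRG1"),
  other     = character())

#' Simulation classes of the field generator
#'
#' Mutually exclusive cell classes used by the generator; each implies a
#' marker-call pattern (all cells are DAPI+). After gating, selector
#' phenotypes are unions of classes: `"CD8_T"` matches `CD8`, `CD8_CD127`
#' and `CD8_KLRG1` cells.
#'
#' @return character vector of class names.
#' @export
simClasses <- function() names(.simClassMarkers)

#' Field simulation configuration
#'
#' @param width_um,height_um field rectangle in micrometres; the default
#'   669 x 500 um emulates a 20x multispectral field.
#' @param intensities named vector of expected cells per square micrometre
#'   for classes placed by complete spatial randomness (CSR); names from
#'   [simClasses()].
#' @param attraction optional cluster block (or list of blocks) driving a
#'   Neyman-Scott (Thomas-type) parent-offspring process: a list with
#'   `parent_phenotypes` (classes acting as parents), `parent_intensity`
#'   (cells/um^2; scalar split equally, or one value per parent class),
#'   `offspring_phenotype` (classes clustered around the parents),
#'   `mean_offspring` (expected offspring per parent, recycled across
#'   offspring classes), `dispersion` (Gaussian displacement sd, um) and
#'   `background_fraction` (rho, the fraction of offspring placed uniformly
#'   instead of near a parent). Classes used in a block must not also
#'   appear in `intensities`.
#' @param boundary "clipped" (displacements redrawn until inside, keeping
#'   intensities exact) or "toroidal" (wrap-around; for edge-effect-free
#'   calibration).
#' @return a validated config list of class `fieldSimConfig`.
#' @export
fieldSimConfig <- function(width_um = 669, height_um = 500,
                           intensities = c(other = 1.5e-3),
                           attraction = NULL,
                           boundary = c("clipped", "toroidal")) {
  boundary <- match.arg(boundary)
  assertScalarNumber(width_um, "width_um", positive = TRUE)
  assertScalarNumber(height_um, "height_um", positive = TRUE)
  if (length(intensities)) {
    bad <- setdiff(names(intensities), simClasses())
    if (length(bad))
      tilContractStop(sprintf("unknown simulation class(es): %s",
                              paste(bad, collapse = ", ")))
    if (any(intensities < 0) || anyNA(intensities))
      tilContractStop("intensities must be non-negative")
  }
  if (!is.null(attraction)) {
    if (!is.null(attraction$parent_phenotypes)) attraction <- list(attraction)
    used <- character()
    for (b in attraction) {
      if (is.null(b$dispersion) || b$dispersion <= 0)
        tilContractStop("attraction dispersion (sigma) must be > 0")
      rho <- b$background_fraction
      if (is.null(rho) || rho < 0 || rho > 1)
        tilContractStop("background_fraction must lie in [0, 1]")
      if (any(b$parent_intensity < 0) || any(b$mean_offspring < 0))
        tilContractStop("attraction intensities must be non-negative")
      cls <- c(b$parent_phenotypes, b$offspring_phenotype)
      if (!all(cls %in% simClasses()))
        tilContractStop("attraction block uses unknown classes")
      used <- c(used, cls)
    }
    clash <- intersect(used, names(intensities))
    if (length(clash))
      tilContractStop(sprintf(
        "class(es) %s appear both in intensities and in an attraction block",
        paste(clash, collapse = ", ")))
  }
  structure(list(width_um = width_um, height_um = height_um,
                 intensities = intensities, attraction = attraction,
                 boundary = boundary),
            class = "fieldSimConfig")
}

# assemble a cell data.frame from class labels and coordinates
.cellsFromClasses <- function(class, x, y) {
  n <- length(class)
  df <- data.frame(cell_id = as.character(seq_len(n)), x_um = x, y_um = y)
  df$DAPI <- rep(TRUE, n)
  is4 <- class %in% c("CD4", "CD4_CD127", "CD4_FoxP3")
  is8 <- class %in% c("CD8", "CD8_CD127", "CD8_KLRG1")
  df$CD4 <- is4
  df$CD8 <- is8
  df$CD20 <- class == "B_cell"
  df$CD127 <- class %in% c("CD4_CD127", "CD8_CD127")
  df$KLRG1 <- class == "CD8_KLRG1"
  df$FoxP3 <- class == "CD4_FoxP3"
  df
}

.simFieldCells <- function(config) {
  W <- config$width_um; H <- config$height_um
  area <- W * H
  class <- character(0); x <- numeric(0); y <- numeric(0)
  lam <- config$intensities
  if (length(lam)) {
    ns <- stats::rpois(length(lam), lam * area)
    if (sum(ns)) {
      class <- rep(names(lam), ns)
      x <- stats::runif(sum(ns), 0, W)
      y <- stats::runif(sum(ns), 0, H)
    }
  }
  for (b in config$attraction %||% list()) {
    kap <- rep_len(b$parent_intensity, length(b$parent_phenotypes))
    np <- stats::rpois(length(kap), kap * area)
    px <- stats::runif(sum(np), 0, W)
    py <- stats::runif(sum(np), 0, H)
    class <- c(class, rep(b$parent_phenotypes, np))
    x <- c(x, px); y <- c(y, py)
    mu <- rep_len(b$mean_offspring, length(b$offspring_phenotype))
    for (k in seq_along(b$offspring_phenotype)) {
      noff <- stats::rpois(sum(np), mu[k])
      tot <- sum(noff)
      if (!tot) next
      parent <- rep.int(seq_len(sum(np)), noff)
      bg <- stats::runif(tot) < b$background_fraction
      ox <- numeric(tot); oy <- numeric(tot)
      nbg <- sum(bg)
      if (nbg) {
        ox[bg] <- stats::runif(nbg, 0, W)
        oy[bg] <- stats::runif(nbg, 0, H)
      }
      cl <- which(!bg)
      if (length(cl)) {
        cx <- px[parent[cl]] + stats::rnorm(length(cl), 0, b$dispersion)
        cy <- py[parent[cl]] + stats::rnorm(length(cl), 0, b$dispersion)
        if (config$boundary == "toroidal") {
          cx <- cx %% W; cy <- cy %% H
        } else {
          # redraw the Gaussian displacement until the point falls inside
          out <- which(cx < 0 | cx > W | cy < 0 | cy > H)
          while (length(out)) {
            cx[out] <- px[parent[cl[out]]] +
              stats::rnorm(length(out), 0, b$dispersion)
            cy[out] <- py[parent[cl[out]]] +
              stats::rnorm(length(out), 0, b$dispersion)
            out <- out[cx[out] < 0 | cx[out] > W |
                       cy[out] < 0 | cy[out] > H]
          }
        }
        ox[cl] <- cx; oy[cl] <- cy
      }
      class <- c(class, rep(b$offspring_phenotype[k], tot))
      x <- c(x, ox); y <- c(y, oy)
    }
  }
  .cellsFromClasses(class, x, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a field under complete spatial randomness
#'
#' Every class in `config$intensities` receives a Poisson(lambda * area)
#' number of cells placed uniformly at random; marker flags follow the
#' class. Any attraction block in the config is ignored here — this is the
#' CSR null model used for calibration.
#'
#' @param config a [fieldSimConfig()].
#' @param field_id identifier for the simulated field.
#' @param seed optional integer; when given, the field is reproducible.
#' @return a [TILField-class].
#' @export
#' @examples
#' f <- simulateCSRField(fieldSimConfig(intensities = c(CD8 = 1e-3)), seed = 7)
#' nCells(f)  # ~ 1e-3 * 669 * 500
simulateCSRField <- function(config, field_id = "field1", seed = NULL) {
  if (!inherits(config, "fieldSimConfig"))
    tilContractStop("config must come from fieldSimConfig()")
  gen <- function() {
    if (!length(config$intensities) || all(config$intensities == 0))
      warning("all intensities are zero: simulating an empty field",
              call. = FALSE)
    csr <- config; csr$attraction <- NULL
    .newField(field_id, config$width_um, config$height_um,
              .simFieldCells(csr))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a field with parent-offspring spatial attraction
#'
#' CSR placement for the classes in `config$intensities` plus a
#' Neyman-Scott cluster process for each attraction block: parents are a
#' Poisson process at `parent_intensity`, each parent spawns a
#' Poisson(`mean_offspring`) number of offspring per offspring class,
#' displaced isotropically by a Gaussian with sd `dispersion`; a fraction
#' `background_fraction` of offspring is placed uniformly instead.
#' The expected total count of each offspring class is
#' `parent_intensity * mean_offspring * area` regardless of
#' `background_fraction`.
#'
#' @inheritParams simulateCSRField
#' @return a [TILField-class].
#' @export
simulateAttractionField <- function(config, field_id = "field1",
                                    seed = NULL) {
  if (!inherits(config, "fieldSimConfig"))
    tilContractStop("config must come from fieldSimConfig()")
  if (is.null(config$attraction))
    tilContractStop("config has no attraction block")
  gen <- function() .newField(field_id, config$width_um, config$height_um,
                              .simFieldCells(config))
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Cohort simulation configuration
#'
#' Defaults emulate the study cohort: two arms (NAC n=30, NAPC n=35) with
#' paired pre/post specimens, ten 669 x 500 um fields per specimen,
#' baseline TIL intensities shared by both arms, arm- and class-specific
#' post/pre density fold-changes (chemotherapy raises only B cells;
#' chemo-immunotherapy raises B, CD4 and especially CD8 and its
#' CD127+/KLRG1+ subsets; Tregs unchanged), spatial attraction of CD8
#' classes to CD4/B parents in post-NAPC only, a logistic MPR model on the
#' latent log2 post/pre change of the CD8 density (intercepts calibrated so
#' the marginal MPR rates match the configured per-arm rates exactly), and
#' exponential DFS/OS with the hazard reduced by `hr_high_vs_low` for
#' patients above the cohort-median latent post-treatment CD8 density.
#'
#' @param n_per_arm named counts, e.g. `c(NAC = 30, NAPC = 35)`.
#' @param fields_per_specimen fields imaged per slide (default 10).
#' @param width_um,height_um field geometry.
#' @param baseline_intensity named per-class intensities (cells/um^2) at
#'   the pre-treatment timepoint.
#' @param fold_change list with one named multiplier vector per arm
#'   (post = pre * fold).
#' @param patient_sdlog lognormal sd of the per-patient density factor
#'   (shared by both timepoints, so it cancels in post/pre changes).
#' @param timepoint_sdlog lognormal sd of the per-specimen factor.
#' @param attraction NULL to disable, or a list with `arm`, `timepoint`,
#'   `dispersion` (um) and `background_fraction`; the CD8 classes then
#'   cluster around CD4/B parents in that arm and timepoint, with marginal
#'   class intensities preserved.
#' @param mpr_rate per-arm marginal MPR probabilities.
#' @param mpr_slope logistic slope on the latent log2 CD8 density change.
#' @param pcr_given_mpr per-arm probability that an MPR patient is pCR.
#' @param hr_high_vs_low true hazard ratio of density-high vs density-low
#'   patients (applies to DFS and OS).
#' @param median_dfs_low,median_os_low median survival (months) of the
#'   low-density group.
#' @param censoring_rate probability a patient's time is censored.
#' @param tls_density per-condition TLS densities (structures/mm^2):
#'   `pre`, `post_NAC`, `post_NAPC`.
#' @return a config list of class `cohortSimConfig`.
#' @export
cohortSimConfig <- function(
    n_per_arm = c(NAC = 30, NAPC = 35),
    fields_per_specimen = 10,
    width_um = 669, height_um = 500,
    baseline_intensity = c(other = 1.5e-3, B_cell = 1.0e-4,
                           CD4 = 1.2e-4, CD4_CD127 = 4e-5,
                           CD4_FoxP3 = 3e-5, CD8 = 1.2e-4,
                           CD8_CD127 = 4e-5, CD8_KLRG1 = 3e-5),
    fold_change = list(
      NAC  = c(other = 1, B_cell = 2.0, CD4 = 1.0, CD4_CD127 = 1.0,
               CD4_FoxP3 = 1.0, CD8 = 1.0, CD8_CD127 = 1.0,
               CD8_KLRG1 = 1.0),
      NAPC = c(other = 1, B_cell = 2.0, CD4 = 1.8, CD4_CD127 = 1.8,
               CD4_FoxP3 = 1.0, CD8 = 2.0, CD8_CD127 = 2.5,
               CD8_KLRG1 = 2.5)),
    patient_sdlog = 0.4,
    timepoint_sdlog = 0.25,
    attraction = list(arm = "NAPC", timepoint = "post",
                      dispersion = 15, background_fraction = 0.4),
    mpr_rate = c(NAC = 0.20, NAPC = 23 / 35),
    mpr_slope = 1.5,
    pcr_given_mpr = c(NAC = 0, NAPC = 16 / 23),
    hr_high_vs_low = 0.32,
    median_dfs_low = 18,
    median_os_low = 36,
    censoring_rate = 0.3,
    tls_density = c(pre = 0.05, post_NAC = 0.08, post_NAPC = 0.12)) {
  if (is.null(names(n_per_arm)) ||
      !all(names(n_per_arm) %in% c("NAC", "NAPC")) || any(n_per_arm < 1))
    tilContractStop("n_per_arm must be named NAC/NAPC counts >= 1")
  if (!all(names(baseline_intensity) %in% simClasses()))
    tilContractStop("baseline_intensity uses unknown classes")
  for (a in names(n_per_arm)) {
    fc <- fold_change[[a]]
    if (is.null(fc) || !all(names(baseline_intensity) %in% names(fc)) ||
        any(fc <= 0))
      tilContractStop(sprintf(
        "fold_change$%s must cover every baseline class with values > 0", a))
    if (is.na(mpr_rate[a]) || mpr_rate[a] <= 0 || mpr_rate[a] >= 1)
      tilContractStop("mpr_rate must lie in (0, 1) for every arm")
  }
  if (censoring_rate < 0 || censoring_rate >= 1)
    tilContractStop("censoring_rate must lie in [0, 1)")
  structure(as.list(environment()), class = "cohortSimConfig")
}

# intercept a with E[plogis(a + slope * Z)] = target, Z ~ N(meanZ, sdZ)
.calibrateLogisticIntercept <- function(target, slope, meanZ, sdZ) {
  if (sdZ == 0 || slope == 0)
    return(stats::qlogis(target) - slope * meanZ)
  f <- function(a)
    stats::integrate(function(z)
      stats::plogis(a + slope * z) * stats::dnorm(z, meanZ, sdZ),
      meanZ - 10 * sdZ, meanZ + 10 * sdZ)$value - target
  stats::uniroot(f, c(-60, 60), tol = 1e-10)$root
}

.cd8Classes <- c("CD8", "CD8_CD127", "CD8_KLRG1")
.parentClasses <- c("CD4", "CD4_CD127", "B_cell")

#' Simulate a full two-arm cohort
#'
#' Generates paired pre/post specimens for every patient with known ground
#' truth: latent per-class densities (baseline x arm fold-change x patient
#' and timepoint lognormal factors), mIHC-like fields realised from those
#' densities (CSR, or the attraction process in the configured
#' arm/timepoint), MPR/pCR labels from the calibrated logistic model,
#' per-slide viable-tumor percentages consistent with the label (pCR: all
#' 0; MPR: slides Uniform(0, 10]; non-MPR: Uniform(10, 90]), exponential
#' DFS/OS tied to the latent post-treatment CD8 density, and TLS
#' annotations.
#'
#' @param config a [cohortSimConfig()].
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param fields generate the per-field point patterns (set FALSE for fast
#'   clinical-layer-only simulation, e.g. when calibrating rates).
#' @return list with `specimens` (list of [TILSpecimen-class]; empty when
#'   `fields = FALSE`), `clinical` (data.frame in the schema of
#'   [readClinicalTable()], plus the parsed list-column), `tls`
#'   (annotation data.frame) and `truth` (per-patient latent ground truth).
#' @export
simulateCohort <- function(config = cohortSimConfig(), seed = NULL,
                           fields = TRUE) {
  if (!inherits(config, "cohortSimConfig"))
    tilContractStop("config must come from cohortSimConfig()")
  gen <- function() .simulateCohortImpl(config, fields)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

.simulateCohortImpl <- function(config, fields) {
  arms <- rep(names(config$n_per_arm), config$n_per_arm)
  npat <- length(arms)
  pid <- sprintf("P%03d", seq_len(npat))
  base <- config$baseline_intensity
  sP <- config$patient_sdlog; sT <- config$timepoint_sdlog
  # mean-1 lognormal factors; the patient factor cancels in post/pre changes
  uP <- stats::rlnorm(npat, -sP^2 / 2, sP)
  vPre <- stats::rlnorm(npat, -sT^2 / 2, sT)
  vPost <- stats::rlnorm(npat, -sT^2 / 2, sT)

  lamPre <- lamPost <- matrix(0, npat, length(base),
                              dimnames = list(pid, names(base)))
  for (i in seq_len(npat)) {
    fc <- config$fold_change[[arms[i]]][names(base)]
    lamPre[i, ] <- base * uP[i] * vPre[i]
    lamPost[i, ] <- base * fc * uP[i] * vPost[i]
  }
  cd8 <- intersect(.cd8Classes, names(base))
  cd8Pre <- rowSums(lamPre[, cd8, drop = FALSE])
  cd8Post <- rowSums(lamPost[, cd8, drop = FALSE])
  z <- log2(cd8Post / cd8Pre)

  # MPR labels: intercept calibrated per arm so the marginal rate is exact
  mpr <- logical(npat); pcr <- logical(npat)
  sdZ <- sqrt(2) * sT / log(2)
  for (a in unique(arms)) {
    idx <- arms == a
    fc <- config$fold_change[[a]]
    foldAgg <- sum(base[cd8] * fc[cd8]) / sum(base[cd8])
    aInt <- .calibrateLogisticIntercept(config$mpr_rate[[a]],
                                        config$mpr_slope,
                                        log2(foldAgg), sdZ)
    pMpr <- stats::plogis(aInt + config$mpr_slope * z[idx])
    mpr[idx] <- stats::runif(sum(idx)) < pMpr
    pcr[idx] <- mpr[idx] &
      stats::runif(sum(idx)) < config$pcr_given_mpr[[a]]
  }

  # per-slide viable percentages: witnesses of the label
  nSlides <- sample(1:5, npat, replace = TRUE)
  viable <- vector("list", npat)
  for (i in seq_len(npat)) {
    viable[[i]] <-
      if (pcr[i]) rep(0, nSlides[i])
      else if (mpr[i]) stats::runif(nSlides[i], 0, 10)
      else stats::runif(nSlides[i], 10, 90)
  }

  # exponential survival, hazard reduced for density-high patients
  high <- cd8Post >= stats::median(cd8Post)
  hr <- config$hr_high_vs_low
  cr <- config$censoring_rate
  simSurv <- function(medLow) {
    h <- log(2) / medLow * ifelse(high, hr, 1)
    t <- stats::rexp(npat, h)
    if (cr > 0) {
      cens <- stats::rexp(npat, h * cr / (1 - cr))
      list(time = pmin(t, cens), event = t <= cens)
    } else list(time = t, event = rep(TRUE, npat))
  }
  dfs <- simSurv(config$median_dfs_low)
  os <- simSurv(config$median_os_low)

  clinical <- data.frame(
    patient_id = pid, arm = arms,
    viable_percent = vapply(viable, function(v)
      paste(sprintf("%.6g", v), collapse = ";"), character(1)),
    dfs_time = dfs$time, dfs_event = dfs$event,
    os_time = os$time, os_event = os$event,
    stringsAsFactors = FALSE)
  clinical$viable_percent_per_slide <- viable

  # TLS annotations per specimen
  tlsRows <- list()
  for (tp in c("pre", "post")) {
    dens <- if (tp == "pre") rep(config$tls_density[["pre"]], npat)
            else config$tls_density[paste0("post_", arms)]
    area <- stats::runif(npat, 50, 150)
    tlsRows[[tp]] <- data.frame(
      specimen_id = paste(pid, tp, sep = "_"),
      tls_count = stats::rpois(npat, as.numeric(dens) * area),
      evaluated_area_mm2 = area, stringsAsFactors = FALSE)
  }
  tls <- do.call(rbind, tlsRows)
  rownames(tls) <- NULL

  truth <- data.frame(
    patient_id = pid, arm = arms, patient_factor = uP,
    cd8_density_pre = cd8Pre, cd8_density_post = cd8Post,
    log2_cd8_change = z, mpr = mpr, pcr = pcr,
    survival_group = ifelse(high, "high", "low"),
    stringsAsFactors = FALSE)

  specimens <- list()
  if (fields) {
    att <- config$attraction
    specimens <- vector("list", 2L * npat)
    k <- 0L
    for (i in seq_len(npat)) {
      for (tp in c("pre", "post")) {
        lam <- if (tp == "pre") lamPre[i, ] else lamPost[i, ]
        attract <- !is.null(att) && arms[i] == att$arm && tp == att$timepoint
        if (attract) {
          parents <- intersect(.parentClasses, names(lam))
          offs <- intersect(.cd8Classes, names(lam))
          kapTot <- sum(lam[parents])
          block <- list(parent_phenotypes = parents,
                        parent_intensity = as.numeric(lam[parents]),
                        offspring_phenotype = offs,
                        mean_offspring = as.numeric(lam[offs]) / kapTot,
                        dispersion = att$dispersion,
                        background_fraction = att$background_fraction)
          cfg <- fieldSimConfig(config$width_um, config$height_um,
                                lam[setdiff(names(lam), c(parents, offs))],
                                attraction = block)
        } else {
          cfg <- fieldSimConfig(config$width_um, config$height_um, lam)
        }
        flds <- lapply(seq_len(config$fields_per_specimen), function(j)
          .newField(sprintf("%s_%s_f%02d", pid[i], tp, j),
                    config$width_um, config$height_um,
                    .simFieldCells(cfg)))
        k <- k + 1L
        specimens[[k]] <- .newSpecimen(pid[i], arms[i], tp, flds)
      }
    }
  }
  list(specimens = specimens, clinical = clinical, tls = tls, truth = truth)
}
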