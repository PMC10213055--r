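#' @include simulate.R io.R
NULL

#' Write a miniature end-to-end dataset
#'
#' Simulates a small cohort (2 arms x 4 patients x pre/post x 3 fields by
#' default) and writes it in the exact input schemas consumed by the
#' readers: one cell CSV per field under `cells/`, a `fields.csv` geometry
#' table, `clinical.csv`, `tls.csv`, and a `truth.json` ground-truth
#' manifest. Output is byte-identical across runs at a fixed seed, so the
#' bundle doubles as a regression fixture.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed.
#' @param config optional [cohortSimConfig()]; the default shrinks the
#'   cohort to 4 patients per arm and 3 fields per specimen.
#' @return Invisibly, a list with the file paths and the simulated objects.
#' @export
makeFixtureBundle <- function(out_dir, seed = 1,
                              config = cohortSimConfig(
                                n_per_arm = c(NAC = 4, NAPC = 4),
                                fields_per_specimen = 3)) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) tilIOStop(sprintf("cannot create directory %s", out_dir))
  cellDir <- file.path(out_dir, "cells")
  dir.create(cellDir, showWarnings = FALSE)

  sim <- simulateCohort(config, seed = seed, fields = TRUE)

  geom <- list()
  for (sp in sim$specimens) {
    for (f in fields(sp)) {
      df <- cells(f)
      for (m in tilMarkers()) df[[m]] <- as.integer(df[[m]])
      df$x_um <- sprintf("%.6f", df$x_um)
      df$y_um <- sprintf("%.6f", df$y_um)
      utils::write.csv(df[, .cellRequiredCols()],
                       file.path(cellDir, paste0(fieldId(f), ".csv")),
                       row.names = FALSE, quote = FALSE)
      geom[[fieldId(f)]] <- data.frame(
        field_id = fieldId(f), width_um = fieldWidth(f),
        height_um = fieldHeight(f),
        patient_id = patientId(sp), arm = arm(sp),
        timepoint = timepoint(sp))
    }
  }
  geomDf <- do.call(rbind, geom)
  rownames(geomDf) <- NULL
  utils::write.csv(geomDf, file.path(out_dir, "fields.csv"),
                   row.names = FALSE, quote = FALSE)

  clin <- sim$clinical
  clin$viable_percent_per_slide <- NULL
  clin$dfs_time <- sprintf("%.6f", clin$dfs_time)
  clin$os_time <- sprintf("%.6f", clin$os_time)
  clin$dfs_event <- as.integer(clin$dfs_event)
  clin$os_event <- as.integer(clin$os_event)
  utils::write.csv(clin, file.path(out_dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)

  tls <- sim$tls
  tls$evaluated_area_mm2 <- sprintf("%.6f", tls$evaluated_area_mm2)
  utils::write.csv(tls, file.path(out_dir, "tls.csv"),
                   row.names = FALSE, quote = FALSE)

  jsonlite::write_json(
    list(seed = seed, truth = sim$truth),
    file.path(out_dir, "truth.json"),
    digits = NA, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    paths = list(cells = cellDir,
                 fields = file.path(out_dir, "fields.csv"),
                 clinical = file.path(out_dir, "clinical.csv"),
                 tls = file.path(out_dir, "tls.csv"),
                 truth = file.path(out_dir, "truth.json")),
    sim = sim))
}

#' Read a fixture bundle back into memory
#'
#' @param dir directory written by [makeFixtureBundle()].
#' @return list with `specimens`, `clinical`, `tls`.
#' @export
readFixtureBundle <- function(dir) {
  geom <- utils::read.csv(file.path(dir, "fields.csv"),
                          stringsAsFactors = FALSE)
  bySpec <- split(geom, paste(geom$patient_id, geom$timepoint, sep = "_"))
  specimens <- lapply(bySpec, function(g) {
    flds <- lapply(seq_len(nrow(g)), function(i)
      readCellTable(file.path(dir, "cells", paste0(g$field_id[i], ".csv")),
                    g$field_id[i], g$width_um[i], g$height_um[i]))
    TILSpecimen(g$patient_id[1], g$arm[1], g$timepoint[1], flds)
  })
  list(specimens = unname(specimens),
       clinical = readClinicalTable(file.path(dir, "clinical.csv")),
       tls = readTLSTable(file.path(dir, "tls.csv")))
}
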