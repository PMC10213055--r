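#' @include AllClasses.R
NULL

#' Read a per-field cell table
#'
#' Parses one field's segmented-cell CSV (comma-delimited, UTF-8, header
#' row) into a [TILField-class]. The expected columns are `cell_id`, `x_um`,
#' `y_um` and one 0/1 column per marker in [tilMarkers()]. Row order is
#' preserved and coordinates are parsed as decimal micrometres with origin
#' at the lower-left corner of the field.
#'
#' @param path path to the CSV file.
#' @param field_id identifier for the field; defaults to the file name
#'   without extension.
#' @param width_um,height_um field rectangle dimensions in micrometres.
#' @return A validated [TILField-class].
#' @seealso [readFieldGeometry()] for the geometry metadata table,
#'   [readClinicalTable()], [readTLSTable()].
#' @export
readCellTable <- function(path, field_id = NULL,
                          width_um = 669, height_um = 500) {
  if (!file.exists(path)) tilIOStop(sprintf("no such file: %s", path))
  if (is.null(field_id))
    field_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if ("cell_id" %in% names(df)) df$cell_id <- as.character(df$cell_id)
  missing <- setdiff(.cellRequiredCols(), names(df))
  if (length(missing))
    tilSchemaStop(sprintf("cell table %s is missing column(s): %s",
                          basename(path), paste(missing, collapse = ", ")))
  for (m in tilMarkers()) {
    v <- df[[m]]
    if (!is.numeric(v) || anyNA(v) || !all(v %in% c(0, 1)))
      tilParseStop(sprintf("marker column '%s' in %s must be 0/1",
                           m, basename(path)))
  }
  if (!is.numeric(df$x_um) || !is.numeric(df$y_um) ||
      anyNA(df$x_um) || anyNA(df$y_um))
    tilParseStop(sprintf("coordinates in %s must be numeric", basename(path)))
  fld <- tryCatch(
    TILField(field_id, width_um, height_um, df),
    error = function(e) {
      if (inherits(e, "til_error")) stop(e)
      tilValidationStop(conditionMessage(e))
    })
  fld
}

#' Read field geometry metadata
#'
#' CSV with columns `field_id`, `width_um`, `height_um`.
#'
#' @param path path to the CSV.
#' @return data.frame with one row per field.
#' @export
readFieldGeometry <- function(path) {
  if (!file.exists(path)) tilIOStop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("field_id", "width_um", "height_um")
  missing <- setdiff(need, names(df))
  if (length(missing))
    tilSchemaStop(sprintf("field geometry is missing column(s): %s",
                          paste(missing, collapse = ", ")))
  if (any(!is.finite(df$width_um)) || any(df$width_um <= 0) ||
      any(!is.finite(df$height_um)) || any(df$height_um <= 0))
    tilValidationStop("field dimensions must be positive")
  if (anyDuplicated(df$field_id))
    tilValidationStop("duplicate field_id in geometry table")
  df$field_id <- as.character(df$field_id)
  df
}

#' Read the per-patient clinical table
#'
#' One row per patient: `patient_id`, `arm` (NAC|NAPC), `viable_percent`
#' (per-slide viable-tumor percentages as a ';'-delimited list, 1-5 values
#' each in \[0,100\]), `dfs_time`, `dfs_event`, `os_time`, `os_event`
#' (times in months, events as 0/1). Any further columns are carried along
#' as covariates.
#'
#' @param path path to the CSV.
#' @return data.frame of validated clinical records with
#'   `viable_percent` parsed into a list-column `viable_percent_per_slide`.
#' @export
readClinicalTable <- function(path) {
  if (!file.exists(path)) tilIOStop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "arm", "viable_percent",
            "dfs_time", "dfs_event", "os_time", "os_event")
  missing <- setdiff(need, names(df))
  if (length(missing))
    tilSchemaStop(sprintf("clinical table is missing column(s): %s",
                          paste(missing, collapse = ", ")))
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    tilValidationStop(sprintf(
      "duplicate patient_id: %s",
      paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", ")))
  if (!all(df$arm %in% c("NAC", "NAPC")))
    tilValidationStop("arm must be 'NAC' or 'NAPC'")
  viable <- lapply(strsplit(as.character(df$viable_percent), ";", fixed = TRUE),
                   function(v) suppressWarnings(as.numeric(trimws(v))))
  for (i in seq_along(viable)) {
    v <- viable[[i]]
    if (length(v) < 1L || anyNA(v))
      tilParseStop(sprintf("patient %s: unparseable viable_percent '%s'",
                           df$patient_id[i], df$viable_percent[i]))
    if (any(v < 0 | v > 100))
      tilValidationStop(sprintf(
        "patient %s: viable percentage outside [0,100]", df$patient_id[i]))
  }
  for (tc in c("dfs_time", "os_time")) {
    if (!is.numeric(df[[tc]]) || anyNA(df[[tc]]) || any(df[[tc]] < 0))
      tilValidationStop(sprintf("%s must be non-negative months", tc))
  }
  for (ec in c("dfs_event", "os_event")) {
    if (anyNA(df[[ec]]) || !all(df[[ec]] %in% c(0, 1)))
      tilParseStop(sprintf("%s must be 0/1", ec))
    df[[ec]] <- as.logical(df[[ec]])
  }
  df$viable_percent_per_slide <- viable
  df
}

#' Read tertiary lymphoid structure annotations
#'
#' CSV with columns `specimen_id`, `tls_count` (non-negative integer) and
#' `evaluated_area_mm2` (> 0). TLSs are identified morphologically upstream;
#' this package only consumes the counts.
#'
#' @param path path to the CSV.
#' @return validated data.frame.
#' @export
readTLSTable <- function(path) {
  if (!file.exists(path)) tilIOStop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "tls_count", "evaluated_area_mm2")
  missing <- setdiff(need, names(df))
  if (length(missing))
    tilSchemaStop(sprintf("TLS table is missing column(s): %s",
                          paste(missing, collapse = ", ")))
  if (!is.numeric(df$tls_count) || anyNA(df$tls_count) ||
      any(df$tls_count < 0) || any(df$tls_count != round(df$tls_count)))
    tilValidationStop("tls_count must be non-negative integers")
  if (!is.numeric(df$evaluated_area_mm2) || anyNA(df$evaluated_area_mm2) ||
      any(df$evaluated_area_mm2 <= 0))
    tilValidationStop("evaluated_area_mm2 must be > 0")
  df$specimen_id <- as.character(df$specimen_id)
  df
}

#' Write a result table as TSV
#'
#' Serialises any downstream result data.frame deterministically: columns in
#' the order given (or sorted if `sort_cols`), rows sorted by the key
#' columns, numbers at full precision (`%.17g`, so re-reading round-trips
#' exactly), logicals as 0/1. A comment header records the seed when one is
#' supplied, so every artifact carries its provenance.
#'
#' @param records data.frame of results.
#' @param path output path (directory must exist).
#' @param key columns to sort rows by; defaults to all non-numeric columns.
#' @param seed optional integer recorded in the header line.
#' @return `path`, invisibly.
#' @seealso [readResultTable()]
#' @export
writeResultTable <- function(records, path, key = NULL, seed = NULL) {
  records <- as.data.frame(records)
  if (!dir.exists(dirname(path)))
    tilIOStop(sprintf("directory does not exist: %s", dirname(path)))
  if (is.null(key))
    key <- names(records)[!vapply(records, is.numeric, logical(1))]
  if (nrow(records) && length(key))
    records <- records[do.call(order, records[key]), , drop = FALSE]
  out <- records
  for (nm in names(out)) {
    if (is.logical(out[[nm]])) out[[nm]] <- as.integer(out[[nm]])
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Read a result table written by [writeResultTable()]
#'
#' @param path TSV path.
#' @return data.frame; the recorded seed, if any, is attached as
#'   `attr(x, "seed")`.
#' @export
readResultTable <- function(path) {
  if (!file.exists(path)) tilIOStop(sprintf("no such file: %s", path))
  first <- readLines(path, n = 1L)
  seed <- NULL
  if (startsWith(first, "# seed:"))
    seed <- as.integer(sub("# seed:\\s*", "", first))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "seed") <- seed
  df
}

#' Validate a directory of cell tables plus a clinical table
#'
#' Runs every file through the schema and invariant checks; collects rather
#' than stops at the first failure.
#'
#' @param cells_dir directory of per-field cell CSVs (optionally with a
#'   `fields.csv` geometry table).
#' @param clinical_path optional clinical CSV.
#' @return Invisibly, a character vector of problems (empty if clean).
#' @export
validateInputs <- function(cells_dir, clinical_path = NULL) {
  problems <- character()
  geom <- NULL
  gpath <- file.path(cells_dir, "fields.csv")
  if (file.exists(gpath)) {
    geom <- tryCatch(readFieldGeometry(gpath), til_error = function(e) {
      problems <<- c(problems, conditionMessage(e)); NULL
    })
  }
  files <- setdiff(list.files(cells_dir, pattern = "\\.csv$",
                              full.names = TRUE), gpath)
  for (f in files) {
    fid <- sub("\\.[^.]*$", "", basename(f))
    w <- 669; h <- 500
    if (!is.null(geom) && fid %in% geom$field_id) {
      i <- match(fid, geom$field_id)
      w <- geom$width_um[i]; h <- geom$height_um[i]
    }
    tryCatch(readCellTable(f, fid, w, h),
             til_error = function(e)
               problems <<- c(problems, conditionMessage(e)))
  }
  if (!is.null(clinical_path))
    tryCatch(readClinicalTable(clinical_path),
             til_error = function(e)
               problems <<- c(problems, conditionMessage(e)))
  if (length(problems))
    message(sprintf("validation found %d problem(s)", length(problems)))
  invisible(problems)
}
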