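# Tabular I/O with strict schema validation -------------------------------

.measurement_schema <- c(
  subject_id = "character", phase = "character", load_watts = "numeric",
  pep = "numeric", hr = "numeric", sbp = "numeric", dbp = "numeric",
  lvet = "numeric", heather_index = "numeric", valid = "logical"
)

#' Write a measurement table to CSV
#'
#' Writes the canonical measurement columns (`subject_id`, `phase`,
#' `load_watts`, `pep`, `hr`, `sbp`, `dbp`, `lvet`, `heather_index`,
#' `valid`); extra in-memory columns are dropped.
#'
#' @param measurements measurement data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(measurements, path) {
  miss <- setdiff(names(.measurement_schema), names(measurements))
  if (length(miss))
    stop("measurements lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  utils::write.csv(measurements[, names(.measurement_schema)], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read and validate a measurement table
#'
#' Strict schema validation: all canonical columns must be present, numeric
#' columns must parse as numbers, phase labels must come from
#' [phase_levels()], and a repeated header line inside the file is reported
#' with its line number.
#'
#' @param path CSV file written by [write_measurement_table()] (or
#'   compatible).
#' @return Validated data frame with an added `state` column.
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(lines)))
    stop("empty measurement table: ", path, call. = FALSE)
  header <- lines[1]
  dup <- which(lines[-1] == header) + 1L
  if (length(dup))
    stop("duplicated header in ", path, " at line ", dup[1], call. = FALSE)
  if (length(lines) < 2L)
    stop("measurement table has a header but no rows: ", path, call. = FALSE)

  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(names(.measurement_schema), names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in names(.measurement_schema)) {
    want <- .measurement_schema[[col]]
    if (want == "numeric" && !is.numeric(d[[col]]))
      stop("column '", col, "' in ", path, " is not numeric", call. = FALSE)
    if (want == "logical" && !is.logical(d[[col]])) {
      parsed <- as.logical(d[[col]])
      if (any(is.na(parsed) & !is.na(d[[col]])))
        stop("column '", col, "' in ", path, " is not logical", call. = FALSE)
      d[[col]] <- parsed
    }
  }
  bad <- setdiff(unique(d$phase), phase_levels())
  if (length(bad))
    stop("phase label(s) outside the controlled vocabulary in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  d$state <- phase_state(d$phase)
  d
}

#' Write the tables of a cohort to a directory
#'
#' Writes `subjects.csv`, `measurements.csv` and, when present, `beats.csv`
#' and `cuff_curves.csv`.
#'
#' @param cohort a `pep_cohort`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pep_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  write_measurement_table(cohort$measurements,
                          file.path(dir, "measurements.csv"))
  if (!is.null(cohort$beats))
    utils::write.csv(cohort$beats, file.path(dir, "beats.csv"),
                     row.names = FALSE)
  if (!is.null(cohort$cuff_curves))
    utils::write.csv(cohort$cuff_curves, file.path(dir, "cuff_curves.csv"),
                     row.names = FALSE)
  invisible(dir)
}
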