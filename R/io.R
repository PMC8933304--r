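# Delimited-text readers for the pipeline's input schemas. All files are
# header-bearing, comma-delimited by default with tab accepted; lines
# starting with '#' (output headers) are ignored.

read_table_checked <- function(path, required, label) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  out <- readr::read_delim(
    path, delim = delim, comment = "#",
    show_col_types = FALSE, progress = FALSE
  )
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s file %s lacks required column(s): %s",
                  label, path, paste(missing_cols, collapse = ", ")))
  }
  out
}

#' Read an admission line list
#'
#' Expects a delimited text file with header columns `patient_id`,
#' `admission_date` (ISO 8601), `sex`, `nationality`, `icd10` and at least
#' one of `birth_date` / `age`. Rows with unparseable dates are kept (and
#' counted in `attr(, "n_malformed")`); [select_index_admissions()] reports
#' and drops them.
#'
#' @param path Path to a CSV/TSV file.
#' @return Tibble of admission records.
#' @export
read_line_list <- function(path) {
  out <- read_table_checked(
    path, c("patient_id", "admission_date", "sex", "nationality", "icd10"),
    "line list"
  )
  if (!"age" %in% names(out) && !"birth_date" %in% names(out)) {
    abort(sprintf("line list file %s lacks required column(s): age or birth_date",
                  path))
  }
  out$admission_date <- as.Date(as.character(out$admission_date))
  if ("birth_date" %in% names(out)) {
    out$birth_date <- as.Date(as.character(out$birth_date))
  }
  n_bad <- sum(is.na(out$admission_date))
  if (n_bad > 0) {
    inform(sprintf("%s: %d row(s) with unparseable admission_date", path,
                   n_bad))
  }
  attr(out, "n_malformed") <- n_bad
  out
}

#' Read a population denominator table
#'
#' Columns: `year`, `sex`, `nationality`, `age_band`, `count`.
#'
#' @param path Path to a CSV/TSV file.
#' @return Tibble.
#' @export
read_population <- function(path) {
  read_table_checked(
    path, c("year", "sex", "nationality", "age_band", "count"), "population"
  )
}

#' Read a life table
#'
#' Columns: `sex`, one of `age` / `age_band`, and one of `q` (annual death
#' probability) / `m` (central death rate).
#'
#' @param path Path to a CSV/TSV file.
#' @return Tibble.
#' @export
read_life_table <- function(path) {
  out <- read_table_checked(path, "sex", "life table")
  if (!any(c("age", "age_band") %in% names(out))) {
    abort(sprintf("life table file %s lacks required column(s): age or age_band",
                  path))
  }
  if (!any(c("q", "m") %in% names(out))) {
    abort(sprintf("life table file %s lacks required column(s): q or m", path))
  }
  out
}

#' Read a MOF:hip ratio table
#'
#' Columns: `sex`, `age_band`, `ratio` (other major osteoporotic fractures
#' to hip, dimensionless).
#'
#' @param path Path to a CSV/TSV file.
#' @return Tibble.
#' @export
read_ratio_table <- function(path) {
  read_table_checked(path, c("sex", "age_band", "ratio"), "ratio table")
}

#' Write a pipeline output table with its configuration hash
#'
#' Prepends a `# config_hash:` comment line so every output records the run
#' configuration it came from, then writes the table as CSV. Files written
#' this way are readable by the package's own readers (the comment line is
#' skipped).
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param config_hash Hash string to embed (see [run_pipeline()]).
#' @return `path`, invisibly.
#' @export
write_output <- function(x, path, config_hash = NULL) {
  x <- tibble::as_tibble(x)
  if (is.null(config_hash)) {
    readr::write_csv(x, path)
  } else {
    writeLines(sprintf("# config_hash: %s", config_hash), path)
    readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  }
  invisible(path)
}
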