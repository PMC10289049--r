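# Cohort file I/O: delimited text in and out, validation on read.
# Numeric output uses 17 significant digits so doubles round-trip exactly.

#' Read a cohort from delimited text
#'
#' Reads a CSV (or other delimited) file of lipid panels, optionally
#' renaming columns, and streams the records through [validate_panels()].
#'
#' @param path path to a delimited text file with a header row. Required
#'   columns (after mapping): `tc`, `hdl`, `tg` (mg/dL); optional `ldl_ref`
#'   and covariate columns.
#' @param column_map optional named character vector mapping file column
#'   names to canonical names, e.g. `c(TOTAL_CHOL = "tc")`.
#' @param require_ldl_ref passed to [validate_panels()].
#' @param sep field separator.
#' @return A `"panel_validation"` list (`accepted`, `rejected`,
#'   `reason_counts`); the accepted component is the analysis cohort.
#' @export
read_cohort <- function(path, column_map = NULL, require_ldl_ref = FALSE,
                        sep = ",") {
  if (!file.exists(path)) stop("cannot read cohort file: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    hit <- names(raw) %in% names(column_map)
    names(raw)[hit] <- column_map[names(raw)[hit]]
  }
  missing_cols <- setdiff(c("tc", "hdl", "tg"), names(raw))
  if (length(missing_cols)) {
    stop("cohort file lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_panels(raw, require_ldl_ref = require_ldl_ref)
}

#' Write a cohort to delimited text
#'
#' Numeric columns are written at full precision (up to 15 significant
#' digits), so `write_cohort()` then [read_cohort()] round-trips values.
#'
#' @param data cohort data frame.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, sep = ",") {
  stopifnot(is.data.frame(data))
  out <- data
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
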