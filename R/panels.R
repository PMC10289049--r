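# Lipid-panel validation. Mirrors the exclusion rules of the source analysis:
# records missing TC, HDL-C or TG (or the reference LDL-C when evaluation
# against a reference is requested) are rejected, as are physically
# impossible values. Rejections are returned with structured reasons,
# never silently dropped.

#' Validate raw lipid-panel records
#'
#' Checks a data frame of lipid panels (columns `tc`, `hdl`, `tg` in mg/dL;
#' optional `ldl_ref` and covariates) and splits it into accepted panels and
#' rejected records. Accepted panels carry a derived `non_hdl = tc - hdl`
#' column. A record is rejected when any required analyte is missing, when
#' any of `tc`, `hdl`, `tg` (or a present `ldl_ref`) is negative, or when
#' `tc < hdl` (a physical impossibility). The first applicable reason is
#' reported, in the order: `missing_tc`, `missing_hdl`, `missing_tg`,
#' `missing_ldl_ref`, `negative_value`, `tc_lt_hdl`.
#'
#' @param data data frame of raw records.
#' @param require_ldl_ref logical; additionally require a non-missing
#'   `ldl_ref` column (needed for accuracy evaluation against a reference).
#' @return A list of class `"panel_validation"`:
#'   `accepted` (data frame with `non_hdl` added), `rejected` (data frame
#'   with a `reason` column), and `reason_counts` (named integer vector).
#' @export
#' @examples
#' v <- validate_panels(data.frame(tc = c(200, 40), hdl = c(50, 50), tg = 100))
#' v$reason_counts
validate_panels <- function(data, require_ldl_ref = FALSE) {
  stopifnot(is.data.frame(data))
  for (col in c("tc", "hdl", "tg")) {
    if (!col %in% names(data)) data[[col]] <- NA_real_
  }
  if (require_ldl_ref && !"ldl_ref" %in% names(data)) {
    data$ldl_ref <- NA_real_
  }

  n <- nrow(data)
  reason <- rep(NA_character_, n)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  flag(is.na(data$tc), "missing_tc")
  flag(is.na(data$hdl), "missing_hdl")
  flag(is.na(data$tg), "missing_tg")
  if (require_ldl_ref) flag(is.na(data$ldl_ref), "missing_ldl_ref")
  neg <- data$tc < 0 | data$hdl < 0 | data$tg < 0
  if ("ldl_ref" %in% names(data)) {
    neg <- neg | (!is.na(data$ldl_ref) & data$ldl_ref < 0)
  }
  flag(neg, "negative_value")
  flag(data$tc < data$hdl, "tc_lt_hdl")

  ok <- is.na(reason)
  accepted <- data[ok, , drop = FALSE]
  accepted$non_hdl <- accepted$tc - accepted$hdl
  rejected <- data[!ok, , drop = FALSE]
  rejected$reason <- reason[!ok]
  counts <- table(factor(rejected$reason))
  out <- list(
    accepted = accepted,
    rejected = rejected,
    reason_counts = stats::setNames(as.integer(counts), names(counts))
  )
  class(out) <- "panel_validation"
  out
}

#' @export
print.panel_validation <- function(x, ...) {
  cat(sprintf("<panel_validation> %d accepted, %d rejected\n",
              nrow(x$accepted), nrow(x$rejected)))
  if (length(x$reason_counts)) {
    for (r in names(x$reason_counts)) {
      cat(sprintf("  %-16s %d\n", r, x$reason_counts[[r]]))
    }
  }
  invisible(x)
}
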