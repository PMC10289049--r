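# Patient-level error summaries between estimated and reference LDL-C.
# Sign convention: error = estimate - reference, so underestimation is
# negative. Quantiles use linear interpolation between order statistics
# (stats::quantile type 7), recorded in the summary for reproducibility.

#' Summarise estimation errors against a reference
#'
#' Computes the signed error distribution `estimate - reference` (mg/dL),
#' the relative error `100 * (estimate - reference) / reference` (%), their
#' medians and interquartile ranges, and the fraction of patients with
#' absolute error strictly below a tolerance (default 5 mg/dL).
#'
#' @param estimate,reference paired numeric LDL-C values, mg/dL; references
#'   must be strictly positive (they are the denominator of the relative
#'   error).
#' @param tolerance mg/dL; `frac_within` counts `|error| < tolerance`
#'   (strict inequality).
#' @return A list of class `"ldl_error_summary"`: `median_error`,
#'   `iqr_error` (named `q25`/`q75`), `median_relative_error`,
#'   `iqr_relative_error`, `frac_within`, `tolerance`, `n`, `quantile_type`.
#' @export
#' @examples
#' summarize_errors(c(96, 109, 100), c(100, 110, 100))
summarize_errors <- function(estimate, reference, tolerance = 5) {
  stopifnot(is.numeric(estimate), is.numeric(reference),
            is.numeric(tolerance), length(tolerance) == 1L, tolerance >= 0)
  if (length(estimate) != length(reference)) {
    stop("estimate and reference must have equal length", call. = FALSE)
  }
  if (length(estimate) == 0L) {
    stop("empty input: error summary is undefined", call. = FALSE)
  }
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("references must be finite and strictly positive for relative errors",
         call. = FALSE)
  }
  err <- estimate - reference
  rel <- 100 * err / reference
  q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  qe <- q(err)
  qr <- q(rel)
  out <- list(
    median_error = qe[2],
    iqr_error = c(q25 = qe[1], q75 = qe[3]),
    median_relative_error = qr[2],
    iqr_relative_error = c(q25 = qr[1], q75 = qr[3]),
    frac_within = mean(abs(err) < tolerance),
    tolerance = tolerance,
    n = length(err),
    quantile_type = 7L
  )
  class(out) <- "ldl_error_summary"
  out
}

#' @export
print.ldl_error_summary <- function(x, ...) {
  cat(sprintf("<ldl_error_summary> n = %d\n", x$n))
  cat(sprintf("  error          : %.1f (%.1f to %.1f) mg/dL\n",
              x$median_error, x$iqr_error[["q25"]], x$iqr_error[["q75"]]))
  cat(sprintf("  relative error : %.1f (%.1f to %.1f) %%\n",
              x$median_relative_error, x$iqr_relative_error[["q25"]],
              x$iqr_relative_error[["q75"]]))
  cat(sprintf("  |error| < %g mg/dL : %.1f%%\n",
              x$tolerance, 100 * x$frac_within))
  invisible(x)
}
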