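# Confirmed upward reclassification across a treatment threshold when
# switching from Friedewald to an alternative equation.

#' Upward reclassification at a treatment cutpoint
#'
#' Among patients whose Friedewald LDL-C falls below a cutpoint (default
#' 70 mg/dL, the intensification threshold for very-high-risk patients),
#' computes the fraction correctly reclassified to at/above the cutpoint by
#' an alternative equation — "correctly" meaning the reference LDL-C is also
#' at/above the cutpoint. "Reclassified to > cutpoint" is implemented as
#' `>= cutpoint` for both the alternative estimate and the reference, so the
#' below/at-or-above dichotomy partitions all values.
#'
#' @param data data frame of panels with columns `tc`, `hdl`, `tg` and
#'   `ldl_ref` (mg/dL).
#' @param alternative equation id or `"ldl_equation"` object to switch to.
#' @param tg_range half-open TG interval `[lo, hi)` in mg/dL restricting the
#'   analysis population (default `[0, 400)`).
#' @param cutpoint mg/dL treatment threshold.
#' @param override_tg_domain passed to [estimate_ldl()].
#' @return A list of class `"ldl_reclassification"`: `denominator` (panels
#'   with TG in range and Friedewald estimate below the cutpoint),
#'   `numerator` (of those, alternative estimate and reference both at/above
#'   it), `proportion` (`NA` and `undefined = TRUE` when the denominator is
#'   empty), `incorrect` (alternative at/above but reference below — counted
#'   separately, not part of the headline proportion), and the analysis
#'   parameters.
#' @export
#' @examples
#' d <- data.frame(tc = c(150, 160), hdl = 50, tg = c(180, 90),
#'                 ldl_ref = c(75, 80))
#' upward_reclassification(d, "martin_hopkins")
upward_reclassification <- function(data, alternative, tg_range = c(0, 400),
                                    cutpoint = 70, override_tg_domain = FALSE) {
  stopifnot(is.data.frame(data), all(c("tc", "hdl", "tg") %in% names(data)),
            length(tg_range) == 2L, tg_range[1] < tg_range[2])
  if (!"ldl_ref" %in% names(data) || anyNA(data$ldl_ref)) {
    stop("every panel must carry a reference LDL-C (ldl_ref) for reclassification",
         call. = FALSE)
  }
  alt_def <- if (inherits(alternative, "ldl_equation")) alternative else ldl_equation(alternative)
  in_range <- data$tg >= tg_range[1] & data$tg < tg_range[2]
  sub <- data[in_range, , drop = FALSE]
  fw <- estimate_ldl(sub, equation = "friedewald",
                     override_tg_domain = override_tg_domain)
  denom_mask <- fw < cutpoint
  d <- sub[denom_mask, , drop = FALSE]
  denominator <- nrow(d)
  if (denominator > 0L) {
    alt <- estimate_ldl(d, equation = alt_def,
                        override_tg_domain = override_tg_domain)
    up <- alt >= cutpoint
    numerator <- sum(up & d$ldl_ref >= cutpoint)
    incorrect <- sum(up & d$ldl_ref < cutpoint)
  } else {
    numerator <- 0L
    incorrect <- 0L
  }
  out <- list(
    equation = alt_def$id,
    tg_range = tg_range,
    cutpoint = cutpoint,
    cohort_size = nrow(data),
    denominator = denominator,
    numerator = as.integer(numerator),
    incorrect = as.integer(incorrect),
    proportion = if (denominator > 0L) numerator / denominator else NA_real_,
    undefined = denominator == 0L
  )
  class(out) <- "ldl_reclassification"
  out
}

#' @export
print.ldl_reclassification <- function(x, ...) {
  cat(sprintf(
    "<ldl_reclassification> %s, TG [%g, %g), cutpoint %g mg/dL\n",
    x$equation, x$tg_range[1], x$tg_range[2], x$cutpoint))
  if (x$undefined) {
    cat("  denominator empty: proportion undefined\n")
  } else {
    cat(sprintf("  correct upward: %d / %d = %.1f%% (incorrect: %d)\n",
                x$numerator, x$denominator, 100 * x$proportion, x$incorrect))
  }
  invisible(x)
}
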