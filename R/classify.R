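# Guideline-based LDL-C categorization and estimate-vs-reference concordance.

#' The guideline LDL-C category scheme
#'
#' Eight clinical guideline categories with cut-points at 40, 55, 70, 100,
#' 130, 160 and 190 mg/dL. Bins are half-open `[low, high)`: an LDL-C of
#' exactly 70 falls in "70-99". The lowest bin absorbs negative estimates.
#'
#' @param edges numeric cut-points (strictly increasing); the default is the
#'   guideline scheme and is the only scheme shipped.
#' @return A list of class `"category_scheme"` with `edges` and `labels`.
#' @export
ldl_category_scheme <- function(edges = c(40, 55, 70, 100, 130, 160, 190)) {
  stopifnot(is.numeric(edges), !is.unsorted(edges, strictly = TRUE))
  labels <- c(
    paste0("<", edges[1]),
    paste0(edges[-length(edges)], "-", edges[-1] - 1),
    paste0(">=", edges[length(edges)])
  )
  structure(list(edges = edges, labels = labels), class = "category_scheme")
}

#' Categorize LDL-C values
#'
#' Maps LDL-C values (estimated or measured) to guideline categories.
#'
#' @param ldl numeric LDL-C values, mg/dL; must be finite (negative values
#'   are allowed and map to the lowest category).
#' @param scheme a [ldl_category_scheme()].
#' @return An ordered factor with one level per category.
#' @export
#' @examples
#' ldl_category(c(-3, 69.999, 70, 200))
ldl_category <- function(ldl, scheme = ldl_category_scheme()) {
  stopifnot(is.numeric(ldl))
  if (any(!is.finite(ldl))) {
    stop("LDL-C values must be finite for categorization", call. = FALSE)
  }
  idx <- findInterval(ldl, scheme$edges) + 1L
  factor(scheme$labels[idx], levels = scheme$labels, ordered = TRUE)
}

#' Concordance between estimated and reference LDL-C categories
#'
#' Overall concordance is the fraction of pairs whose estimated and
#' reference LDL-C fall in the same guideline category. Per-category
#' concordance is reported under a configurable orientation: stratified by
#' the reference category (the default: of patients whose *measured* LDL-C
#' is in a category, the fraction whose estimate agrees) or by the estimated
#' category.
#'
#' @param estimate,reference paired numeric LDL-C values, mg/dL.
#' @param scheme a [ldl_category_scheme()].
#' @param by orientation of the per-category breakdown: `"reference"` or
#'   `"estimate"`.
#' @return A list of class `"ldl_concordance"`: `overall` (proportion in
#'   `[0, 1]`), `by_category` (data frame with category, denominator `n`,
#'   concordant count and `proportion`), `n` and `orientation`.
#' @export
#' @examples
#' concordance(c(35, 60, 80), c(38, 72, 85))
concordance <- function(estimate, reference, scheme = ldl_category_scheme(),
                        by = c("reference", "estimate")) {
  by <- match.arg(by)
  stopifnot(is.numeric(estimate), is.numeric(reference))
  if (length(estimate) != length(reference)) {
    stop("estimate and reference must have equal length", call. = FALSE)
  }
  if (length(estimate) == 0L) {
    stop("empty input: concordance is undefined", call. = FALSE)
  }
  ce <- ldl_category(estimate, scheme)
  cr <- ldl_category(reference, scheme)
  agree <- ce == cr
  strat <- if (by == "reference") cr else ce
  n_k <- tapply(agree, strat, length, default = 0L)
  hit_k <- tapply(agree, strat, sum, default = 0L)
  out <- list(
    overall = mean(agree),
    by_category = data.frame(
      category = scheme$labels,
      n = as.integer(n_k),
      concordant = as.integer(hit_k),
      proportion = ifelse(n_k > 0, hit_k / n_k, NA_real_),
      row.names = NULL
    ),
    n = length(agree),
    orientation = by
  )
  class(out) <- "ldl_concordance"
  out
}

#' @export
print.ldl_concordance <- function(x, digits = 1, ...) {
  cat(sprintf("<ldl_concordance> overall %.1f%% (n = %d, per-category by %s)\n",
              100 * x$overall, x$n, x$orientation))
  bc <- x$by_category
  bc$proportion <- round(100 * bc$proportion, digits)
  print(bc, row.names = FALSE)
  invisible(x)
}
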