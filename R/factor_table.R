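# Martin/Hopkins adjustable TG:VLDL-C factor tables and the stratum lookup.
#
# The factor replaces Friedewald's fixed divisor 5: VLDL-C is estimated as
# TG / factor(TG, non-HDL-C), with the factor read from a 2-D table indexed
# by TG strata (rows) and non-HDL-C strata (columns). All strata are
# half-open [low, high); a value on a boundary falls in the upper stratum.

.nonhdl_edges <- c(0, 100, 130, 160, 190, 220, Inf)

.load_factor_table <- function(variant = c("standard", "extended")) {
  variant <- match.arg(variant)
  key <- paste0("mh_", variant)
  if (!is.null(.registry_env[[key]])) {
    return(.registry_env[[key]])
  }
  file <- sprintf("martin_hopkins_factors_%s.tsv", variant)
  path <- .extdata(file)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  factors <- as.matrix(raw[, -(1:2), drop = FALSE])
  dimnames(factors) <- NULL
  tbl <- list(
    variant = variant,
    tg_edges = c(raw$tg_lo, raw$tg_hi[nrow(raw)]),
    nonhdl_edges = .nonhdl_edges,
    factors = factors,
    digest = unname(tools::md5sum(path))
  )
  # structural invariants: strata tile their range, factors all positive
  stopifnot(
    !is.unsorted(tbl$tg_edges, strictly = TRUE),
    all(raw$tg_lo[-1] == raw$tg_hi[-nrow(raw)]),
    all(is.finite(factors)), all(factors > 0),
    ncol(factors) == length(.nonhdl_edges) - 1L
  )
  .registry_env[[key]] <- tbl
  tbl
}

#' Martin/Hopkins factor table
#'
#' Returns the packaged adjustable TG:VLDL-C factor table. The `standard`
#' variant covers TG `[0, 400)` mg/dL (29 TG strata by 6 non-HDL-C strata;
#' factors range 3.1 to 9.5); the `extended` variant covers TG `[400, 800)`.
#'
#' @param variant `"standard"` or `"extended"`.
#' @return A list of class `"mh_factor_table"`: `variant`, `tg_edges`,
#'   `nonhdl_edges` (stratum boundaries, half-open intervals), `factors`
#'   (matrix of positive divisors, TG strata in rows), and the asset `digest`.
#' @export
#' @examples
#' tbl <- mh_factor_table()
#' range(tbl$factors) # 3.1 to 9.5
mh_factor_table <- function(variant = c("standard", "extended")) {
  tbl <- .load_factor_table(match.arg(variant))
  class(tbl) <- "mh_factor_table"
  tbl
}

#' @export
print.mh_factor_table <- function(x, ...) {
  cat(sprintf(
    "<mh_factor_table> %s: TG [%g, %g) mg/dL, %d x %d strata, factors %.1f-%.1f\n",
    x$variant, min(x$tg_edges), max(x$tg_edges),
    nrow(x$factors), ncol(x$factors), min(x$factors), max(x$factors)
  ))
  invisible(x)
}

#' Look up the adjustable TG:VLDL-C factor
#'
#' Piecewise-constant lookup of the Martin/Hopkins divisor for given
#' triglyceride and non-HDL cholesterol values. Strata are half-open
#' `[low, high)`; non-HDL-C values at or beyond the last stratum boundary
#' fall in the last stratum.
#'
#' @param tg triglycerides, mg/dL (vectorised).
#' @param non_hdl non-HDL cholesterol (TC - HDL-C), mg/dL (vectorised,
#'   recycled against `tg`).
#' @param table a table from [mh_factor_table()], or a variant name.
#' @return Numeric vector of positive divisors.
#' @export
#' @examples
#' martin_hopkins_factor(100, 150) # mid-range factor
martin_hopkins_factor <- function(tg, non_hdl, table = "standard") {
  if (is.character(table)) table <- mh_factor_table(table)
  stopifnot(is.numeric(tg), is.numeric(non_hdl))
  n <- max(length(tg), length(non_hdl))
  tg <- rep_len(tg, n)
  non_hdl <- rep_len(non_hdl, n)
  if (any(!is.finite(tg)) || any(!is.finite(non_hdl)) || any(non_hdl < 0)) {
    stop("tg and non_hdl must be finite and non_hdl non-negative", call. = FALSE)
  }
  lo <- min(table$tg_edges)
  hi <- max(table$tg_edges)
  bad <- tg < lo | tg >= hi
  if (any(bad)) {
    other <- if (table$variant == "standard") "extended" else "standard"
    stop(sprintf(
      "TG = %g mg/dL outside the %s table range [%g, %g); use the %s variant",
      tg[which(bad)[1L]], table$variant, lo, hi, other), call. = FALSE)
  }
  i <- findInterval(tg, table$tg_edges, rightmost.closed = FALSE)
  j <- findInterval(non_hdl, table$nonhdl_edges)
  j <- pmin(j, ncol(table$factors))
  table$factors[cbind(i, j)]
}
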