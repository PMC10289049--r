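# Equation registry: data-driven definitions of the 23 published LDL-C
# equations plus the extended-triglyceride Martin/Hopkins variant.

# content digests of the packaged assets; guards against silent edits
.asset_digests <- c(
  martin_hopkins_factors_standard.tsv = "d28590bbb30149e145a7437674778a0c",
  martin_hopkins_factors_extended.tsv = "d538f885326cee6e16d1633dd35f0e74",
  equations.tsv = "d18b494fd7cec70962ab5ac46ea76e28"
)

.registry_env <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "ldlcompare")
  if (!nzchar(path)) {
    # fall back for load_all()-style development loads
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) {
    stop("packaged data asset not found: ", file, call. = FALSE)
  }
  path
}

.load_registry <- function() {
  if (!is.null(.registry_env$registry)) {
    return(.registry_env$registry)
  }
  path <- .extdata("equations.tsv")
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(
    nrow(reg) == 24L,
    all(reg$family %in% c("fixed_ratio", "linear", "table_factor", "quadratic")),
    !anyDuplicated(reg$id)
  )
  fr <- reg[reg$family == "fixed_ratio", ]
  if (any(!is.finite(fr$k)) || any(fr$k <= 0)) {
    stop("fixed-ratio registry entries must carry a single positive divisor")
  }
  .registry_env$registry <- reg
  reg
}

#' The LDL-C equation registry
#'
#' Returns the registry of closed-form LDL-C estimation equations bundled with
#' the package: 23 primary published equations (the historical Friedewald
#' fixed-ratio family, linear models in TC/HDL-C/TG, the Martin/Hopkins
#' adjustable-factor lookup, and quadratic/interaction forms such as Sampson)
#' plus the extended-triglyceride Martin/Hopkins variant for TG 400-799 mg/dL.
#'
#' All coefficients are expressed in mg/dL working units. The `provenance`
#' column distinguishes coefficient sets transcribed from the original
#' publications (`transcribed`) from behavioural reconstructions calibrated to
#' published error profiles (`reconstructed`); see the package vignette.
#'
#' @param primary_only logical; if `TRUE`, drop the extended-TG variant and
#'   return only the 23 primary equations.
#' @return A data frame with one row per equation: `id`, `label`, `family`
#'   (one of `fixed_ratio`, `linear`, `table_factor`, `quadratic`),
#'   family-specific coefficient columns, the TG validity domain
#'   (`tg_lo`, `tg_hi`, half-open `[tg_lo, tg_hi)` in mg/dL), `source_units`,
#'   `provenance` and `citation`.
#' @seealso [estimate_ldl()], [ldl_equation()]
#' @export
#' @examples
#' eqs <- ldl_equations()
#' table(eqs$family)
ldl_equations <- function(primary_only = FALSE) {
  reg <- .load_registry()
  if (primary_only) reg <- reg[reg$id != "martin_hopkins_extended", ]
  reg
}

#' Retrieve a single equation definition
#'
#' @param id character scalar, an equation identifier present in
#'   [ldl_equations()] (e.g. `"friedewald"`, `"martin_hopkins"`, `"sampson"`).
#' @return A list of class `"ldl_equation"` with the registry fields for that
#'   equation.
#' @export
ldl_equation <- function(id) {
  reg <- .load_registry()
  i <- match(id, reg$id)
  if (length(id) != 1L || is.na(i)) {
    stop("unknown equation id: ", paste(id, collapse = ", "),
         "\navailable: ", paste(reg$id, collapse = ", "), call. = FALSE)
  }
  def <- as.list(reg[i, ])
  class(def) <- "ldl_equation"
  def
}

#' @export
print.ldl_equation <- function(x, ...) {
  cat(sprintf("<ldl_equation> %s (%s)\n", x$id, x$label))
  cat("  family    :", x$family, "\n")
  cat(sprintf("  TG domain : [%g, %g) mg/dL\n", x$tg_lo, x$tg_hi))
  form <- switch(x$family,
    fixed_ratio = sprintf("TC - HDL - TG/%g", x$k),
    linear = sprintf("%g*TC %+g*HDL %+g*TG %+g", x$a_tc, x$a_hdl, x$a_tg, x$a0),
    quadratic = sprintf(
      "%g*TC %+g*HDL %+g*TG %+g*TG^2 %+g*TG*nonHDL %+g",
      x$a_tc, x$a_hdl, x$a_tg, x$a_tg2, x$a_tgnonhdl, x$a0),
    table_factor = sprintf("TC - HDL - TG/factor(TG, nonHDL; %s table)", x$table)
  )
  cat("  form      :", form, "\n")
  cat("  source    :", x$citation, "\n")
  invisible(x)
}
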