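# Estimation engine: applies any registry equation to lipid panels.
# All four structural families share the signature (tc, hdl, tg) in mg/dL.

.fixed_ratio_ldl <- function(tc, hdl, tg, k) tc - hdl - tg / k

.linear_ldl <- function(tc, hdl, tg, def) {
  def$a_tc * tc + def$a_hdl * hdl + def$a_tg * tg + def$a0
}

.quadratic_ldl <- function(tc, hdl, tg, def) {
  non_hdl <- tc - hdl
  def$a_tc * tc + def$a_hdl * hdl + def$a_tg * tg +
    def$a_tg2 * tg^2 + def$a_tgnonhdl * tg * non_hdl + def$a0
}

.table_factor_ldl <- function(tc, hdl, tg, table) {
  tc - hdl - tg / martin_hopkins_factor(tg, tc - hdl, table)
}

#' Estimate LDL-C with a registry equation
#'
#' Applies one of the packaged closed-form LDL-C equations to lipid-panel
#' values. Inputs and the returned estimate are in mg/dL. Estimates are
#' returned as-is: they are neither rounded nor clipped, so a value below
#' zero is possible for extreme panels (such values classify to the lowest
#' guideline category downstream).
#'
#' By default an equation refuses triglyceride values outside its validity
#' domain (for the Friedewald-family equations, TG >= 400 mg/dL, the usual
#' clinical boundary). Set `override_tg_domain = TRUE` to force evaluation
#' anyway, e.g. for research comparisons in hypertriglyceridemia. Under the
#' override, the table-factor (Martin/Hopkins) equations look the factor up
#' in whichever table variant covers the TG value, clamping beyond
#' 800 mg/dL to the nearest stratum.
#'
#' @param tc total cholesterol, mg/dL; alternatively a data frame with
#'   columns `tc`, `hdl`, `tg`.
#' @param hdl HDL cholesterol, mg/dL.
#' @param tg triglycerides, mg/dL.
#' @param equation equation id (see [ldl_equations()]) or an
#'   `"ldl_equation"` object. `"martin_hopkins_auto"` is a convenience
#'   composite applying the standard adjustable-factor table below
#'   TG 400 mg/dL and the extended table at 400-799 mg/dL.
#' @param override_tg_domain logical; allow TG outside the equation's
#'   validity domain.
#' @return Numeric vector of estimated LDL-C, mg/dL.
#' @export
#' @examples
#' estimate_ldl(200, 50, 100, "friedewald") # 130
#' estimate_ldl(200, 50, 100, "chen")       # 125
#' estimate_ldl(200, 50, 100, "martin_hopkins")
estimate_ldl <- function(tc, hdl = NULL, tg = NULL, equation = "friedewald",
                         override_tg_domain = FALSE) {
  if (is.data.frame(tc)) {
    stopifnot(all(c("tc", "hdl", "tg") %in% names(tc)))
    hdl <- tc$hdl
    tg <- tc$tg
    tc <- tc$tc
  }
  stopifnot(is.numeric(tc), is.numeric(hdl), is.numeric(tg))
  n <- max(length(tc), length(hdl), length(tg))
  tc <- rep_len(tc, n); hdl <- rep_len(hdl, n); tg <- rep_len(tg, n)

  if (identical(equation, "martin_hopkins_auto")) {
    out <- rep(NA_real_, n)
    std <- tg < 400
    if (any(std)) {
      out[std] <- estimate_ldl(tc[std], hdl[std], tg[std], "martin_hopkins",
                               override_tg_domain = override_tg_domain)
    }
    if (any(!std)) {
      out[!std] <- estimate_ldl(tc[!std], hdl[!std], tg[!std],
                                "martin_hopkins_extended",
                                override_tg_domain = override_tg_domain)
    }
    return(out)
  }

  def <- if (inherits(equation, "ldl_equation")) equation else ldl_equation(equation)

  if (!override_tg_domain) {
    bad <- tg < def$tg_lo | tg >= def$tg_hi
    if (any(bad)) {
      stop(sprintf(
        "TG = %g mg/dL outside the validity domain [%g, %g) of equation '%s'; set override_tg_domain = TRUE to force",
        tg[which(bad)[1L]], def$tg_lo, def$tg_hi, def$id), call. = FALSE)
    }
  }

  switch(def$family,
    fixed_ratio = .fixed_ratio_ldl(tc, hdl, tg, def$k),
    linear = .linear_ldl(tc, hdl, tg, def),
    quadratic = .quadratic_ldl(tc, hdl, tg, def),
    table_factor = {
      if (override_tg_domain) {
        tc - hdl - tg / .mh_factor_any(tg, tc - hdl)
      } else {
        .table_factor_ldl(tc, hdl, tg, mh_factor_table(def$table))
      }
    },
    stop("unknown equation family: ", def$family)
  )
}

# factor lookup across both table variants: TG below 400 uses the standard
# table, 400-799 the extended one; values beyond are clamped to the nearest
# stratum. Used when a table-factor equation is forced outside its domain.
.mh_factor_any <- function(tg, non_hdl) {
  tgc <- pmin(pmax(tg, 0), 800 - 1e-9)
  f <- numeric(length(tgc))
  std <- tgc < 400
  if (any(std)) {
    f[std] <- martin_hopkins_factor(tgc[std], non_hdl[std],
                                    mh_factor_table("standard"))
  }
  if (any(!std)) {
    f[!std] <- martin_hopkins_factor(tgc[!std], non_hdl[!std],
                                     mh_factor_table("extended"))
  }
  f
}

#' Table-factor LDL-C with an explicit factor table
#'
#' The Martin/Hopkins estimator with a caller-supplied factor table:
#' `TC - HDL - TG / factor(TG, nonHDL)`. Exposed separately from
#' [estimate_ldl()] so degenerate or experimental tables can be plugged in
#' (a table whose every cell is 5 reduces exactly to Friedewald).
#'
#' @inheritParams estimate_ldl
#' @param table an `"mh_factor_table"` (or structurally compatible list).
#' @return Numeric vector of estimated LDL-C, mg/dL.
#' @export
table_factor_ldl <- function(tc, hdl, tg, table = mh_factor_table("standard")) {
  if (is.data.frame(tc)) {
    hdl <- tc$hdl; tg <- tc$tg; tc <- tc$tc
  }
  .table_factor_ldl(tc, hdl, tg, table)
}
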