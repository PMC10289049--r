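# The evaluation pipeline: equation x stratum concordance, error summaries
# and upward-reclassification analysis, gathered into one classed object.

.top_equations <- c("martin_hopkins", "sampson", "chen", "puavilai", "delong")

#' Evaluate LDL-C equations against a reference
#'
#' Runs the full accuracy analysis on a cohort carrying a reference LDL-C:
#' for every requested equation and stratum, the guideline-category
#' concordance (overall and per category) and the patient-level error
#' summary; and, for the configured alternative equations, the confirmed
#' upward-reclassification analysis against Friedewald at the treatment
#' cutpoint. Estimation inside the evaluation overrides per-equation TG
#' validity domains: the analysis population is what defines the TG range.
#' Following the primary-analysis convention, every stratum except the
#' 400-799 mg/dL triglyceride band is evaluated among records with TG
#' below 400 mg/dL (the `n_analysis` accounting column records the
#' resulting denominator).
#'
#' @param data cohort data frame with `tc`, `hdl`, `tg`, `ldl_ref` (mg/dL)
#'   and any covariates the requested strata need.
#' @param equations character vector of equation ids (default: all 23
#'   primary equations).
#' @param strata character vector of stratum names from [cohort_strata()]
#'   (default `"tg_lt400"`, the primary analysis population).
#' @param scheme a [ldl_category_scheme()].
#' @param tolerance mg/dL tolerance for the `frac_within` error statistic.
#' @param orientation per-category concordance orientation, see
#'   [concordance()].
#' @param cutpoint mg/dL treatment threshold for reclassification.
#' @param reclassify equation ids compared against Friedewald in the
#'   reclassification analysis (default: the requested equations among the
#'   historically top-performing set, excluding Friedewald itself).
#' @return An object of class `"ldl_evaluation"`: data frames
#'   `concordance`, `errors`, `reclassification`, the per-stratum
#'   record `accounting` (in/out/missing counts summing to the cohort
#'   size), and `meta` (package version, parameters).
#' @seealso [write_evaluation()] for the report files.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n = 2000, seed = 7))
#' ev <- evaluate_equations(cohort, equations = c("friedewald", "martin_hopkins"))
#' summary(ev)
evaluate_equations <- function(data,
                               equations = ldl_equations(primary_only = TRUE)$id,
                               strata = "tg_lt400",
                               scheme = ldl_category_scheme(),
                               tolerance = 5,
                               orientation = c("reference", "estimate"),
                               cutpoint = 70,
                               reclassify = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(is.data.frame(data))
  if (!"ldl_ref" %in% names(data)) {
    stop("evaluation requires a reference LDL-C column 'ldl_ref'",
         call. = FALSE)
  }
  reg <- ldl_equations()
  unknown <- setdiff(equations, c(reg$id, "martin_hopkins_auto"))
  if (length(unknown)) {
    stop("unknown equation id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(reclassify)) {
    reclassify <- setdiff(intersect(equations, .top_equations), "friedewald")
  }

  conc <- list(); errs <- list(); recl <- list(); acct <- list()
  for (s in strata) {
    sub <- stratum_filter(data, s)
    d <- sub$data
    # primary-analysis convention: all strata except the high-TG band are
    # evaluated in the TG < 400 mg/dL population
    if (s != "tg_400_799") d <- d[d$tg >= 0 & d$tg < 400, , drop = FALSE]
    acct[[s]] <- data.frame(
      stratum = s, n_in = sub$n_in, n_out = sub$n_out,
      n_missing = sub$n_missing, n_total = sub$n_total,
      n_analysis = nrow(d)
    )
    if (nrow(d) == 0L) next
    for (eq in equations) {
      est <- estimate_ldl(d, equation = eq, override_tg_domain = TRUE)
      cc <- concordance(est, d$ldl_ref, scheme, by = orientation)
      row <- data.frame(stratum = s, equation = eq, n = cc$n,
                        overall = cc$overall)
      per <- as.data.frame(as.list(stats::setNames(
        cc$by_category$proportion, paste0("cat_", seq_along(scheme$labels)))))
      conc[[paste(s, eq)]] <- cbind(row, per)
      es <- summarize_errors(est, d$ldl_ref, tolerance = tolerance)
      errs[[paste(s, eq)]] <- data.frame(
        stratum = s, equation = eq, n = es$n,
        median_error = es$median_error,
        q25_error = es$iqr_error[["q25"]], q75_error = es$iqr_error[["q75"]],
        median_relative_error = es$median_relative_error,
        q25_relative_error = es$iqr_relative_error[["q25"]],
        q75_relative_error = es$iqr_relative_error[["q75"]],
        frac_within = es$frac_within
      )
    }
    for (eq in reclassify) {
      tg_range <- if (s == "tg_150_399") c(150, 400)
        else if (s == "tg_400_799") c(400, 800)
        else c(0, 400)
      rc <- upward_reclassification(d, eq, tg_range = tg_range,
                                    cutpoint = cutpoint,
                                    override_tg_domain = TRUE)
      recl[[paste(s, eq)]] <- data.frame(
        stratum = s, equation = eq, denominator = rc$denominator,
        numerator = rc$numerator, incorrect = rc$incorrect,
        proportion = rc$proportion
      )
    }
  }

  bind <- function(lst) {
    if (length(lst)) do.call(rbind, c(lst, list(make.row.names = FALSE)))
    else NULL
  }
  out <- list(
    concordance = bind(conc),
    errors = bind(errs),
    reclassification = bind(recl),
    accounting = bind(acct),
    meta = list(
      package_version = as.character(utils::packageVersion("ldlcompare")),
      equations = equations, strata = strata, orientation = orientation,
      tolerance = tolerance, cutpoint = cutpoint,
      category_labels = scheme$labels,
      n_input = nrow(data)
    )
  )
  class(out) <- "ldl_evaluation"
  out
}

#' @export
print.ldl_evaluation <- function(x, ...) {
  cat(sprintf("<ldl_evaluation> %d equations x %d strata, %d input records\n",
              length(x$meta$equations), length(x$meta$strata),
              x$meta$n_input))
  cat("  strata:", paste(x$meta$strata, collapse = ", "), "\n")
  cat("  per-category orientation:", x$meta$orientation, "\n")
  invisible(x)
}

#' @export
summary.ldl_evaluation <- function(object, stratum = NULL, ...) {
  s <- if (is.null(stratum)) object$meta$strata[1] else stratum
  cc <- object$concordance[object$concordance$stratum == s, ]
  ee <- object$errors[object$errors$stratum == s, ]
  tab <- merge(cc[, c("equation", "n", "overall")],
               ee[, c("equation", "median_error", "q25_error", "q75_error")],
               by = "equation")
  tab <- tab[order(-tab$overall), ]
  row.names(tab) <- NULL
  cat(sprintf("LDL-C equation accuracy, stratum '%s' (n = %d):\n",
              s, cc$n[1]))
  cat(sprintf("  %-24s %9s   %s\n", "equation", "overall%", "median error (IQR), mg/dL"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-24s %8.1f%%   %5.1f (%.1f to %.1f)\n",
                tab$equation[i], 100 * tab$overall[i], tab$median_error[i],
                tab$q25_error[i], tab$q75_error[i]))
  }
  invisible(tab)
}

#' @export
plot.ldl_evaluation <- function(x, stratum = NULL, ...) {
  s <- if (is.null(stratum)) x$meta$strata[1] else stratum
  cc <- x$concordance[x$concordance$stratum == s, ]
  cc <- cc[order(cc$overall), ]
  graphics::barplot(100 * cc$overall, names.arg = cc$equation, horiz = TRUE,
                    las = 1, xlab = "overall concordance (%)",
                    main = sprintf("Guideline-category concordance (%s)", s),
                    cex.names = 0.7, ...)
  invisible(x)
}

#' Write evaluation reports to delimited text
#'
#' Emits the human-readable report files (percentages and mg/dL errors
#' rounded to 0.1) and a machine-readable JSON summary at full precision:
#' `concordance.tsv` (equations x categories + overall),
#' `errors.tsv` (median (IQR) error and relative error per equation),
#' `reclassification.tsv` (equation x TG stratum counts and percentage),
#' `accounting.tsv` (per-stratum record accounting) and `summary.json`.
#'
#' @param x an `"ldl_evaluation"`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_evaluation <- function(x, dir) {
  stopifnot(inherits(x, "ldl_evaluation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  cc <- x$concordance
  pct <- c("overall", grep("^cat_", names(cc), value = TRUE))
  cc[pct] <- lapply(cc[pct], function(p) round(100 * p, 1))
  w(cc, "concordance.tsv")

  ee <- x$errors
  num <- setdiff(names(ee), c("stratum", "equation", "n", "frac_within"))
  ee[num] <- lapply(ee[num], round, 1)
  ee$frac_within <- round(100 * ee$frac_within, 1)
  w(ee, "errors.tsv")

  if (!is.null(x$reclassification)) {
    rc <- x$reclassification
    rc$proportion <- round(100 * rc$proportion, 1)
    w(rc, "reclassification.tsv")
  }
  w(x$accounting, "accounting.tsv")
  jsonlite::write_json(
    list(meta = x$meta, concordance = x$concordance, errors = x$errors,
         reclassification = x$reclassification, accounting = x$accounting),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}
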