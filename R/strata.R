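# Declarative subgroup filters for the stratified accuracy analyses.
# Each stratum is a named predicate over the cohort's covariate columns;
# records missing a covariate required by the predicate are excluded from
# that stratum (and counted), never treated as satisfying it.

.strata_defs <- list(
  overall = function(d) rep(TRUE, nrow(d)),
  # age bands, years: [0,18), [18,60), [60,Inf)
  age_lt18 = function(d) d$age < 18,
  age_18_59 = function(d) d$age >= 18 & d$age < 60,
  age_ge60 = function(d) d$age >= 60,
  sex_female = function(d) d$sex == "female",
  sex_male = function(d) d$sex == "male",
  fasting = function(d) d$fasting == "fasting",
  non_fasting = function(d) d$fasting == "non_fasting",
  fasting_unknown = function(d) d$fasting == "unknown",
  # TG bands, mg/dL, half-open
  tg_lt400 = function(d) d$tg >= 0 & d$tg < 400,
  tg_150_399 = function(d) d$tg >= 150 & d$tg < 400,
  tg_400_799 = function(d) d$tg >= 400 & d$tg < 800,
  ascvd = function(d) d$ascvd,
  hypertension = function(d) d$hypertension,
  # kidney disease: eGFR < 60 mL/min/1.73 m^2 (strict)
  kidney_disease = function(d) d$egfr < 60,
  # diabetes: diagnosis flag OR A1c > 6.5% OR fasting glucose >= 126 mg/dL;
  # missing components count as FALSE but at least one must be observed
  diabetes = function(d) {
    obs <- !is.na(d$diabetes_dx) | !is.na(d$a1c) | !is.na(d$fasting_glucose)
    val <- (!is.na(d$diabetes_dx) & d$diabetes_dx) |
      (!is.na(d$a1c) & d$a1c > 6.5) |
      (!is.na(d$fasting_glucose) & d$fasting_glucose >= 126)
    ifelse(obs, val, NA)
  },
  # inflammation: hsCRP >= 2 mg/L (inclusive)
  inflammation = function(d) d$hscrp >= 2,
  # thyroid dysfunction: TSH < 0.5 or > 4.5 uIU/mL (both strict)
  thyroid_dysfunction = function(d) d$tsh < 0.5 | d$tsh > 4.5
)

.strata_columns <- list(
  overall = character(), age_lt18 = "age", age_18_59 = "age", age_ge60 = "age",
  sex_female = "sex", sex_male = "sex",
  fasting = "fasting", non_fasting = "fasting", fasting_unknown = "fasting",
  tg_lt400 = "tg", tg_150_399 = "tg", tg_400_799 = "tg",
  ascvd = "ascvd", hypertension = "hypertension",
  kidney_disease = "egfr",
  diabetes = c("diabetes_dx", "a1c", "fasting_glucose"),
  inflammation = "hscrp", thyroid_dysfunction = "tsh"
)

#' Available cohort strata
#'
#' Names of the declarative subgroup filters: age bands (`age_lt18`,
#' `age_18_59`, `age_ge60`), sex, fasting status, triglyceride bands
#' (`tg_lt400` = TG `[0, 400)`, `tg_150_399` = `[150, 400)`,
#' `tg_400_799` = `[400, 800)`), and clinical subgroups (ASCVD,
#' hypertension, kidney disease eGFR < 60, diabetes, inflammation
#' hsCRP >= 2, thyroid dysfunction TSH < 0.5 or > 4.5).
#'
#' @return Character vector of stratum names accepted by [stratum_filter()].
#' @export
cohort_strata <- function() names(.strata_defs)

#' Filter a cohort to a named stratum
#'
#' @param data cohort data frame (see [simulate_cohort()] for the covariate
#'   columns each stratum requires).
#' @param stratum a name from [cohort_strata()].
#' @return A list of class `"ldl_stratum"`: `data` (the sub-cohort),
#'   `stratum`, `n_in`, `n_missing` (records whose required covariate was
#'   missing, excluded and counted), `n_out` (covariate observed, predicate
#'   false) and `n_total`. `n_in + n_missing + n_out == n_total`.
#' @export
#' @examples
#' d <- data.frame(tc = 200, hdl = 50, tg = 120, age = c(17.9, 35, NA))
#' stratum_filter(d, "age_lt18")$n_in
stratum_filter <- function(data, stratum) {
  stopifnot(is.data.frame(data))
  if (!is.character(stratum) || length(stratum) != 1L ||
      !stratum %in% names(.strata_defs)) {
    stop("unknown stratum: ", paste(stratum, collapse = ", "),
         "\navailable: ", paste(cohort_strata(), collapse = ", "),
         call. = FALSE)
  }
  need <- .strata_columns[[stratum]]
  missing_cols <- setdiff(need, names(data))
  for (col in missing_cols) data[[col]] <- NA
  mask <- .strata_defs[[stratum]](data)
  n_missing <- sum(is.na(mask))
  mask[is.na(mask)] <- FALSE
  out <- list(
    data = data[mask, , drop = FALSE],
    stratum = stratum,
    n_in = sum(mask),
    n_missing = n_missing,
    n_out = nrow(data) - sum(mask) - n_missing,
    n_total = nrow(data)
  )
  class(out) <- "ldl_stratum"
  out
}

#' @export
print.ldl_stratum <- function(x, ...) {
  cat(sprintf("<ldl_stratum> %s: %d in, %d out, %d missing covariate (of %d)\n",
              x$stratum, x$n_in, x$n_out, x$n_missing, x$n_total))
  invisible(x)
}
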