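# Depletion-assay Rb estimation: per-replicate ratio of reference-plasma
# to equilibrated-plasma peak areas, replicate summaries, a
# concentration-dependence test and reference-substance validation.

check_depletion_measurements <- function(ms) {
  required <- c("compound", "concentration", "replicate_id",
                "area_reference_plasma", "area_equilibrated_plasma")
  missing_cols <- setdiff(required, names(ms))
  if (length(missing_cols) > 0) {
    pa_error(sprintf("measurement table is missing column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "papartition_usage_error")
  }
  if (any(!is.finite(ms$concentration) | ms$concentration <= 0)) {
    pa_error("concentrations must be strictly positive",
             "papartition_data_error")
  }
  bad <- !is.finite(ms$area_reference_plasma) | ms$area_reference_plasma <= 0 |
    !is.finite(ms$area_equilibrated_plasma) | ms$area_equilibrated_plasma <= 0
  if (any(bad)) {
    i <- which(bad)[1]
    pa_error(sprintf(
      "nonpositive peak area for compound '%s' at %g ng/mL, replicate %s",
      ms$compound[i], ms$concentration[i], ms$replicate_id[i]),
      "papartition_data_error")
  }
  key <- paste(ms$compound, ms$concentration, ms$replicate_id)
  if (anyDuplicated(key)) {
    pa_error(sprintf(
      "duplicate replicate_id within (compound, concentration): %s",
      key[anyDuplicated(key)]), "papartition_data_error")
  }
  invisible(ms)
}

#' Per-replicate blood-to-plasma ratio from the depletion assay
#'
#' Whole blood and a plasma reference receive identical spikes; after
#' equilibration with the red blood cells the plasma drawn from the blood
#' sample is depleted by exactly the blood-to-plasma ratio, so
#' \eqn{R_b = A_{reference} / A_{equilibrated}}.
#'
#' @param area_reference_plasma,area_equilibrated_plasma Peak areas
#'   (same units, strictly positive). Vectorized.
#'
#' @return Numeric vector of Rb estimates.
#' @examples
#' rb_single(200, 100)  # 2: half the compound left the plasma
#' @export
rb_single <- function(area_reference_plasma, area_equilibrated_plasma) {
  bad <- !is.finite(area_reference_plasma) | area_reference_plasma <= 0 |
    !is.finite(area_equilibrated_plasma) | area_equilibrated_plasma <= 0
  if (any(bad)) {
    pa_error(sprintf("nonpositive or non-finite peak area at position %d",
                     which(bad)[1]), "papartition_data_error")
  }
  area_reference_plasma / area_equilibrated_plasma
}

#' Replicate summary of depletion-assay Rb for one compound
#'
#' Mean and sample standard deviation (n-1 denominator) of the
#' per-replicate [rb_single()] values, either pooled at the primary
#' concentration level or grouped by concentration.
#'
#' @param ms Tibble of replicate measurements for one compound with
#'   columns `compound`, `concentration` (ng/mL), `replicate_id`,
#'   `area_reference_plasma`, `area_equilibrated_plasma`.
#' @param per_concentration If `TRUE`, return one summary row per
#'   concentration level; if `FALSE` (default), summarize at
#'   `primary_concentration` (all measurements are used when that level
#'   is absent).
#' @param primary_concentration Concentration (ng/mL) defining the
#'   headline estimate (default 1000).
#'
#' @return Tibble with `compound`, (`concentration`,) `mean`, `sd`
#'   (0 when n = 1), `n`.
#' @export
estimate_rb <- function(ms, per_concentration = FALSE,
                        primary_concentration = 1000) {
  check_depletion_measurements(ms)
  compound <- check_single_compound(ms)
  ms$rb <- rb_single(ms$area_reference_plasma, ms$area_equilibrated_plasma)
  summarize_vals <- function(v) {
    tibble(mean = mean(v), sd = if (length(v) == 1L) 0 else sd(v),
           n = length(v))
  }
  if (per_concentration) {
    ms |>
      dplyr::group_by(.data$concentration) |>
      dplyr::summarise(
        mean = mean(.data$rb),
        sd = if (dplyr::n() == 1L) 0 else sd(.data$rb),
        n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(compound = compound, .before = 1)
  } else {
    v <- if (primary_concentration %in% ms$concentration) {
      ms$rb[ms$concentration == primary_concentration]
    } else {
      ms$rb
    }
    dplyr::bind_cols(tibble(compound = compound), summarize_vals(v))
  }
}

#' Test Rb for concentration dependence
#'
#' Ordinary least-squares regression of the per-replicate Rb values on
#' log10 concentration; a slope with p < `alpha` flags a
#' concentration-dependent ratio (saturation of binding or uptake).
#'
#' @inheritParams estimate_rb
#' @param alpha Significance level (default 0.05).
#'
#' @return List of class `concentration_test`: `slope` (Rb per decade of
#'   concentration), `p_value`, `dependent`, `alpha`, `n_levels`.
#' @export
concentration_dependence <- function(ms, alpha = 0.05) {
  check_depletion_measurements(ms)
  check_single_compound(ms)
  counts <- table(ms$concentration)
  if (length(counts) < 3 || any(counts < 2)) {
    pa_error(
      "need >= 3 concentration levels with >= 2 replicates each",
      "papartition_insufficient_data_error")
  }
  rb <- rb_single(ms$area_reference_plasma, ms$area_equilibrated_plasma)
  fit <- lm(rb ~ log10(ms$concentration))
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(co[2, "Estimate"])
  p <- unname(co[2, "Pr(>|t|)"])
  if (is.nan(p)) p <- NA_real_  # zero-residual degenerate fit
  structure(list(slope = slope, p_value = p,
                 dependent = isTRUE(p < alpha), alpha = alpha,
                 n_levels = length(counts)),
            class = "concentration_test")
}

#' @export
print.concentration_test <- function(x, ...) {
  cat(sprintf(
    "<concentration_test> slope = %.3g Rb/decade, p = %.3g: %s\n",
    x$slope, if (is.na(x$p_value)) NA else x$p_value,
    if (x$dependent) "concentration-dependent" else
      "no concentration dependence"))
  invisible(x)
}

#' Validate the depletion assay against literature Rb values
#'
#' As [validate_logp_method()], but accuracy is judged on the percent
#' deviation `100 * |determined - literature| / literature`, passing at
#' `accuracy_limit_pct` (default 10%).
#'
#' @param determined Tibble of [estimate_rb()] rows: columns `compound`,
#'   `mean`, `sd`.
#' @param literature Named numeric vector or two-column data frame of
#'   literature Rb values.
#' @param accuracy_limit_pct Maximum percent deviation (default 10).
#' @param rsd_limit Maximum RSD in percent (default 10).
#'
#' @return A `method_validation` object.
#' @export
validate_rb_method <- function(determined, literature,
                               accuracy_limit_pct = 10, rsd_limit = 10) {
  validate_method(
    determined, literature, quantity = "rb",
    accuracy_fn = function(det, lit) {
      dev <- 100 * abs(det - lit) / lit
      list(deviation = dev, pass = dev <= accuracy_limit_pct)
    },
    accuracy_label = sprintf(
      "100 * |determined - literature| / literature <= %g%%",
      accuracy_limit_pct),
    rsd_limit = rsd_limit)
}
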