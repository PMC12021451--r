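# Shake-flask log P estimation from two-phase peak areas: per-replicate
# estimator, pooled bidirectional summary, direction-effect test and
# reference-substance method validation.

check_partition_measurements <- function(ms) {
  required <- c("compound", "direction", "replicate_id",
                "area_octanol", "area_water")
  missing_cols <- setdiff(required, names(ms))
  if (length(missing_cols) > 0) {
    pa_error(sprintf("measurement table is missing column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "papartition_usage_error")
  }
  bad_dir <- !ms$direction %in% c("from_organic", "from_aqueous")
  if (any(bad_dir)) {
    pa_error(sprintf("unknown direction '%s' (row %d)",
                     ms$direction[which(bad_dir)[1]], which(bad_dir)[1]),
             "papartition_data_error")
  }
  bad <- !is.finite(ms$area_octanol) | ms$area_octanol <= 0 |
    !is.finite(ms$area_water) | ms$area_water <= 0
  if (any(bad)) {
    i <- which(bad)[1]
    pa_error(sprintf(
      "nonpositive peak area for compound '%s', direction %s, replicate %s",
      ms$compound[i], ms$direction[i], ms$replicate_id[i]),
      "papartition_data_error")
  }
  key <- paste(ms$compound, ms$direction, ms$replicate_id)
  if (anyDuplicated(key)) {
    pa_error(sprintf("duplicate replicate_id within (compound, direction): %s",
                     key[anyDuplicated(key)]),
             "papartition_data_error")
  }
  invisible(ms)
}

check_single_compound <- function(ms) {
  cps <- unique(ms$compound)
  if (length(cps) != 1L) {
    pa_error(sprintf("expected measurements for a single compound, got: %s",
                     paste(cps, collapse = ", ")),
             "papartition_usage_error")
  }
  cps
}

#' Per-replicate shake-flask log P
#'
#' With equal phase volumes, peak areas are proportional to phase
#' concentrations, so each replicate yields
#' \eqn{\log P = \log_{10}(A_{octanol} / A_{water})}.
#'
#' @param area_octanol,area_water Peak areas (same arbitrary units,
#'   strictly positive). Vectorized.
#'
#' @return Numeric vector of log P estimates.
#' @examples
#' logp_single(100, 100)  # 0
#' logp_single(1, 100)    # -2
#' @export
logp_single <- function(area_octanol, area_water) {
  bad <- !is.finite(area_octanol) | area_octanol <= 0 |
    !is.finite(area_water) | area_water <= 0
  if (any(bad)) {
    pa_error(sprintf("nonpositive or non-finite peak area at position %d",
                     which(bad)[1]), "papartition_data_error")
  }
  log10(area_octanol / area_water)
}

#' Pooled bidirectional log P estimate for one compound
#'
#' Pools per-replicate [logp_single()] values across both equilibration
#' directions into a single mean and sample standard deviation (n-1
#' denominator), retaining the per-direction means so a direction effect
#' can still be inspected ([direction_effect()]).
#'
#' @param ms Tibble of replicate measurements for one compound with
#'   columns `compound`, `direction` (`from_organic`/`from_aqueous`),
#'   `replicate_id`, `area_octanol`, `area_water`.
#'
#' @return One-row tibble: `compound`, `mean`, `sd` (0 when n = 1), `n`,
#'   `mean_from_organic`, `mean_from_aqueous` (NA if a direction is
#'   absent).
#' @export
estimate_logp <- function(ms) {
  check_partition_measurements(ms)
  compound <- check_single_compound(ms)
  vals <- logp_single(ms$area_octanol, ms$area_water)
  dir_mean <- function(d) {
    v <- vals[ms$direction == d]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  tibble(
    compound = compound,
    mean = mean(vals),
    sd = if (length(vals) == 1L) 0 else sd(vals),
    n = length(vals),
    mean_from_organic = dir_mean("from_organic"),
    mean_from_aqueous = dir_mean("from_aqueous")
  )
}

#' Test for an equilibration-direction effect on log P
#'
#' Two-sided Welch two-sample t-test of the per-replicate log P values by
#' starting phase. A significant difference indicates incomplete
#' equilibration or a phase-specific bias; the bidirectional design
#' exists to detect exactly this.
#'
#' @inheritParams estimate_logp
#' @param alpha Significance level (default 0.05).
#'
#' @return List of class `direction_test`: `statistic`, `p_value`,
#'   `significant`, `alpha`, per-direction `n`.
#' @export
direction_effect <- function(ms, alpha = 0.05) {
  check_partition_measurements(ms)
  check_single_compound(ms)
  vals <- logp_single(ms$area_octanol, ms$area_water)
  g1 <- vals[ms$direction == "from_organic"]
  g2 <- vals[ms$direction == "from_aqueous"]
  if (length(g1) < 2 || length(g2) < 2) {
    pa_error("need at least 2 replicates per direction",
             "papartition_insufficient_data_error")
  }
  if (sd(g1) == 0 && sd(g2) == 0) {
    # degenerate noise-free case: t-test is undefined, decide on the means
    equal <- isTRUE(all.equal(mean(g1), mean(g2)))
    res <- list(statistic = if (equal) 0 else Inf,
                p_value = if (equal) 1 else 0)
  } else {
    tt <- t.test(g1, g2, var.equal = FALSE)
    res <- list(statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  structure(list(statistic = res$statistic, p_value = res$p_value,
                 significant = res$p_value < alpha, alpha = alpha,
                 n_from_organic = length(g1), n_from_aqueous = length(g2)),
            class = "direction_test")
}

#' @export
print.direction_test <- function(x, ...) {
  cat(sprintf(
    "<direction_test> t = %.3g, p = %.3g (alpha = %g): %s\n",
    x$statistic, x$p_value, x$alpha,
    if (x$significant) "direction effect detected" else "no direction effect"))
  invisible(x)
}

# shared OLS R^2 + per-compound accuracy/precision machinery for the two
# method-validation reports
validate_method <- function(determined, literature, quantity,
                            accuracy_fn, accuracy_label, rsd_limit) {
  if (is.data.frame(literature)) {
    lit <- setNames(literature[[2]], literature[[1]])
  } else {
    lit <- literature
  }
  if (is.null(names(lit))) {
    pa_error("`literature` must be a named vector or two-column data frame",
             "papartition_usage_error")
  }
  shared <- intersect(determined$compound, names(lit))
  if (length(shared) < 3) {
    pa_error("method validation needs at least 3 compounds with both values",
             "papartition_insufficient_data_error")
  }
  det <- determined[match(shared, determined$compound), ]
  fit <- lm(det$mean ~ lit[shared])
  # a perfect fit (noise-free panels) is legitimate here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  acc <- accuracy_fn(det$mean, unname(lit[shared]))
  rsd <- ifelse(abs(det$mean) < 1e-6, NA_real_, 100 * det$sd / abs(det$mean))
  results <- tibble(
    compound = shared,
    determined = det$mean,
    literature = unname(lit[shared]),
    deviation = acc$deviation,
    rsd_pct = rsd,
    accuracy_pass = acc$pass,
    precision_pass = ifelse(is.na(rsd), NA, rsd < rsd_limit)
  )
  structure(list(quantity = quantity, r_squared = r2, results = results,
                 accuracy_label = accuracy_label, rsd_limit = rsd_limit),
            class = "method_validation")
}

#' @export
print.method_validation <- function(x, ...) {
  cat(sprintf("<method_validation> %s: R^2 = %.3f (%d compounds)\n",
              x$quantity, x$r_squared, nrow(x$results)))
  cat(sprintf("  accuracy criterion: %s; precision: RSD < %g%%\n",
              x$accuracy_label, x$rsd_limit))
  print(x$results)
  invisible(x)
}

#' Validate the shake-flask method against literature log P values
#'
#' Regresses determined means on literature values (reporting the OLS
#' R-squared), flags accuracy per compound when the absolute deviation is
#' within `accuracy_limit` log units, and flags precision when the
#' relative standard deviation of the replicates is below `rsd_limit`
#' percent. For means within 1e-6 of zero the RSD is undefined and the
#' precision flag is `NA`.
#'
#' @param determined Tibble of [estimate_logp()] rows (one per compound):
#'   columns `compound`, `mean`, `sd`.
#' @param literature Named numeric vector (names = compounds) or a
#'   two-column data frame (compound, value) of literature log P values.
#' @param accuracy_limit Maximum absolute deviation in log units
#'   (default 0.2).
#' @param rsd_limit Maximum RSD in percent (default 10).
#'
#' @return A `method_validation` object: `r_squared` plus a per-compound
#'   results tibble with deviations, RSDs and pass flags.
#' @export
validate_logp_method <- function(determined, literature,
                                 accuracy_limit = 0.2, rsd_limit = 10) {
  validate_method(
    determined, literature, quantity = "logp",
    accuracy_fn = function(det, lit) {
      dev <- abs(det - lit)
      list(deviation = dev, pass = dev <= accuracy_limit)
    },
    accuracy_label = sprintf("|determined - literature| <= %g log units",
                             accuracy_limit),
    rsd_limit = rsd_limit)
}
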