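# Deviation-based evaluation of in-silico predictions against
# experimental values: signed/percent deviations, band classification,
# per-method band counts and experiment-level summaries.

.logp_bands <- c("lt_1_logunit", "ge_1_logunit_up", "ge_1_logunit_down")
.rb_bands <- c("lt_10pct", "10_to_50pct", "ge_50pct")

# accept either a wide fixture table or a tidy (compound, value) tibble
experimental_values <- function(experimental, quantity) {
  mean_col <- paste0(quantity, "_exp_mean")
  if (mean_col %in% names(experimental)) {
    tibble(compound = experimental$compound,
           experimental = experimental[[mean_col]])
  } else if (all(c("compound", "value") %in% names(experimental))) {
    tibble(compound = experimental$compound,
           experimental = experimental$value)
  } else {
    pa_error(sprintf(
      "experimental table needs columns (compound, %s) or (compound, value)",
      mean_col), "papartition_usage_error")
  }
}

#' Pivot a wide log P table into prediction records
#'
#' Turns the fixture layout (one column per in-silico method) into tidy
#' records with one row per available prediction; empty cells (methods
#' without a prediction for a compound) are dropped.
#'
#' @param tbl Wide table as returned by [pa_table1()]: columns
#'   `compound`, `logp_exp_mean`, `logp_exp_sd`, `kowwin`, `clogp`,
#'   `sparc`, `splogp`.
#'
#' @return Tibble with `compound`, `quantity` (`"logp"`), `method`,
#'   `value`.
#' @export
logp_predictions_from_table <- function(tbl) {
  methods <- intersect(c("kowwin", "clogp", "sparc", "splogp"), names(tbl))
  if (length(methods) == 0) {
    pa_error("no log P prediction columns found",
             "papartition_usage_error")
  }
  tbl |>
    dplyr::select("compound", dplyr::all_of(methods)) |>
    tidyr::pivot_longer(dplyr::all_of(methods), names_to = "method",
                        values_to = "value") |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::mutate(quantity = "logp", .after = "compound")
}

#' Pivot a wide Rb table into prediction records
#'
#' @param tbl Wide table as returned by [pa_table2()]: columns
#'   `compound`, `rb_exp_mean`, `rb_exp_sd`, `rb_acid_base`,
#'   `rb_mechanistic`.
#'
#' @return Tibble with `compound`, `quantity` (`"rb"`), `method`
#'   (`"acid_base"` / `"mechanistic"`), `value`.
#' @export
rb_predictions_from_table <- function(tbl) {
  methods <- intersect(c("rb_acid_base", "rb_mechanistic"), names(tbl))
  if (length(methods) == 0) {
    pa_error("no Rb prediction columns found", "papartition_usage_error")
  }
  tbl |>
    dplyr::select("compound", dplyr::all_of(methods)) |>
    tidyr::pivot_longer(dplyr::all_of(methods), names_to = "method",
                        values_to = "value") |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::mutate(method = sub("^rb_", "", .data$method),
                  quantity = "rb", .after = "compound")
}

#' Deviations of predicted from experimental log P
#'
#' Signed deviation `predicted - experimental` in log units, banded at
#' the 1-log-unit threshold with direction: `lt_1_logunit` (absolute
#' deviation strictly below 1), `ge_1_logunit_up` (overprediction by at
#' least 1, the threshold itself included) and `ge_1_logunit_down`.
#' Compounds without a prediction for a method are simply absent from
#' that method's records.
#'
#' @param experimental Wide table with `logp_exp_mean` (e.g.
#'   [pa_table1()]) or a tidy tibble (`compound`, `value`).
#' @param predictions Prediction records (`compound`, `method`,
#'   `value`), e.g. from [logp_predictions_from_table()].
#'
#' @return Tibble: `compound`, `method`, `quantity`, `experimental`,
#'   `predicted`, `signed_dev`, `band` (factor).
#' @export
logp_deviations <- function(experimental, predictions) {
  exp_vals <- experimental_values(experimental, "logp")
  preds <- predictions[is.finite(predictions$value), ]
  joined <- dplyr::inner_join(exp_vals, preds, by = "compound")
  if (nrow(joined) == 0) {
    pa_error("no compounds shared between experiment and predictions",
             "papartition_data_error")
  }
  signed <- joined$value - joined$experimental
  band <- ifelse(signed >= 1, "ge_1_logunit_up",
                 ifelse(signed <= -1, "ge_1_logunit_down", "lt_1_logunit"))
  tibble(compound = joined$compound, method = joined$method,
         quantity = "logp", experimental = joined$experimental,
         predicted = joined$value, signed_dev = signed,
         band = factor(band, levels = .logp_bands))
}

#' Deviations of predicted from experimental Rb
#'
#' Percent deviation `100 * |predicted - experimental| / experimental`,
#' banded strictly below 10% (`lt_10pct`), in \[10%, 50%)
#' (`10_to_50pct`) and at or above 50% (`ge_50pct`). The fold deviation
#' `max(pred/exp, exp/pred)` is reported alongside as an alternative
#' symmetric metric, but the bands use the percent form.
#'
#' @param experimental Wide table with `rb_exp_mean` (e.g.
#'   [pa_table2()]) or a tidy tibble (`compound`, `value`).
#' @param predictions Prediction records, e.g. from
#'   [rb_predictions_from_table()] or [predict_rb_table()].
#'
#' @return Tibble: `compound`, `method`, `quantity`, `experimental`,
#'   `predicted`, `signed_dev`, `pct_dev`, `fold_dev`, `band` (factor).
#' @export
rb_deviations <- function(experimental, predictions) {
  exp_vals <- experimental_values(experimental, "rb")
  if (any(!is.finite(exp_vals$experimental) | exp_vals$experimental <= 0)) {
    pa_error("experimental Rb values must be strictly positive",
             "papartition_data_error")
  }
  preds <- predictions[is.finite(predictions$value), ]
  joined <- dplyr::inner_join(exp_vals, preds, by = "compound")
  if (nrow(joined) == 0) {
    pa_error("no compounds shared between experiment and predictions",
             "papartition_data_error")
  }
  signed <- joined$value - joined$experimental
  pct <- 100 * abs(signed) / joined$experimental
  fold <- pmax(joined$value / joined$experimental,
               joined$experimental / joined$value)
  band <- ifelse(pct < 10, "lt_10pct",
                 ifelse(pct < 50, "10_to_50pct", "ge_50pct"))
  tibble(compound = joined$compound, method = joined$method,
         quantity = "rb", experimental = joined$experimental,
         predicted = joined$value, signed_dev = signed, pct_dev = pct,
         fold_dev = fold, band = factor(band, levels = .rb_bands))
}

#' Band counts for one prediction method
#'
#' Counts how many of a method's available predictions fall into each
#' deviation band; the denominator is the number of available
#' predictions for that method (compounds the method could not predict
#' never enter). For log P the upward >= 1 log-unit count is surfaced
#' separately since overprediction is the characteristic failure mode.
#'
#' @param reports Deviation tibble from [logp_deviations()] or
#'   [rb_deviations()] (may mix methods).
#' @param method Method name to count.
#' @param quantity `"logp"` or `"rb"`.
#'
#' @return List of class `band_counts`: `method`, `quantity`, `n`,
#'   `counts` (named integer vector over all bands) and, for log P,
#'   `upward_ge_1`.
#' @export
band_counts <- function(reports, method, quantity = c("logp", "rb")) {
  quantity <- match.arg(quantity)
  sub <- reports[reports$method == method & reports$quantity == quantity, ]
  if (nrow(sub) == 0) {
    pa_error(sprintf("no deviation records for method '%s' (%s)",
                     method, quantity), "papartition_usage_error")
  }
  bands <- if (quantity == "logp") .logp_bands else .rb_bands
  counts <- table(factor(sub$band, levels = bands))
  out <- list(method = method, quantity = quantity, n = nrow(sub),
              counts = setNames(as.integer(counts), bands))
  if (quantity == "logp") {
    out$upward_ge_1 <- out$counts[["ge_1_logunit_up"]]
  }
  structure(out, class = "band_counts")
}

#' @export
print.band_counts <- function(x, ...) {
  cat(sprintf("<band_counts> %s (%s), n = %d\n", x$method, x$quantity, x$n))
  for (b in names(x$counts)) {
    cat(sprintf("  %-18s %d\n", b, x$counts[[b]]))
  }
  invisible(x)
}

#' Summary statistics of an experimental value set
#'
#' Extremes with their compounds, the per-pair difference between each
#' N-oxide and its parent alkaloid (N-oxide minus alkaloid), and the
#' lipophilicity/partitioning ranking of the parent alkaloids in
#' ascending order of the experimental value. Pairing and the PA/PANO
#' split are resolved from the `" N-oxide"` name suffix.
#'
#' @param records Wide fixture table or tidy tibble (see
#'   [logp_deviations()]) of experimental values.
#' @param quantity `"logp"` or `"rb"`.
#'
#' @return List of class `experiment_summary`: `quantity`, `min`,
#'   `argmin`, `max`, `argmax`, `pair_differences` (tibble `pa`, `pano`,
#'   `difference`), `pa_ranking` (character vector, ascending).
#' @export
summarize_experiment <- function(records, quantity = c("logp", "rb")) {
  quantity <- match.arg(quantity)
  vals <- experimental_values(records, quantity)
  if (nrow(vals) < 2) {
    pa_error("need at least 2 experimental records to summarize",
             "papartition_insufficient_data_error")
  }
  is_pano <- grepl(" N-oxide$", vals$compound)
  pairs <- NULL
  if (any(is_pano)) {
    oxides <- vals[is_pano, ]
    parent <- pano_parent(oxides$compound)
    idx <- match(parent, vals$compound)
    keep <- !is.na(idx)
    pairs <- tibble(pa = parent[keep], pano = oxides$compound[keep],
                    difference = oxides$experimental[keep] -
                      vals$experimental[idx[keep]])
  }
  pas <- vals[!is_pano, ]
  ranking <- pas$compound[order(pas$experimental)]
  structure(list(
    quantity = quantity,
    min = min(vals$experimental),
    argmin = vals$compound[which.min(vals$experimental)],
    max = max(vals$experimental),
    argmax = vals$compound[which.max(vals$experimental)],
    pair_differences = pairs,
    pa_ranking = ranking
  ), class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("<experiment_summary> %s\n", x$quantity))
  cat(sprintf("  range: %.3g (%s) to %.3g (%s)\n",
              x$min, x$argmin, x$max, x$argmax))
  if (!is.null(x$pair_differences) && nrow(x$pair_differences) > 0) {
    cat("  N-oxide minus parent:\n")
    for (i in seq_len(nrow(x$pair_differences))) {
      cat(sprintf("    %-14s %+.3g\n", x$pair_differences$pa[i],
                  x$pair_differences$difference[i]))
    }
  }
  if (length(x$pa_ranking) > 0) {
    cat(sprintf("  ranking (ascending): %s\n",
                paste(x$pa_ranking, collapse = " < ")))
  }
  invisible(x)
}
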