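# File I/O: packaged compound tables, measurement CSV readers/writers
# with validation, atomic writes, and the full evaluation report.

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "papartition")
  if (!nzchar(path)) {
    pa_error(sprintf("packaged data file not found: %s", file),
             "papartition_io_error")
  }
  path
}

# read a CSV whose non-key columns must be numeric; empty cells become NA,
# anything else non-numeric is a malformed row
read_numeric_csv <- function(path, required, key_cols = "compound") {
  if (!file.exists(path)) {
    pa_error(sprintf("file not found: %s", path), "papartition_io_error")
  }
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, na.strings = "",
             colClasses = "character"),
    error = function(e) {
      pa_error(sprintf("could not parse %s: %s", path,
                       conditionMessage(e)), "papartition_io_error")
    })
  if (nrow(df) == 0) {
    pa_error(sprintf("no data rows in %s", path), "papartition_io_error")
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    pa_error(sprintf("%s is missing column(s): %s", path,
                     paste(missing_cols, collapse = ", ")),
             "papartition_io_error")
  }
  unknown <- setdiff(names(df), required)
  if (length(unknown) > 0) {
    warning(sprintf("ignoring unknown column(s) in %s: %s", path,
                    paste(unknown, collapse = ", ")))
    df <- df[required]
  }
  for (col in setdiff(required, key_cols)) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad) > 0) {
      pa_error(sprintf("%s row %d: '%s' is not numeric (column %s)",
                       path, bad[1], raw[bad[1]], col),
               "papartition_io_error")
    }
    df[[col]] <- num
  }
  for (col in key_cols) {
    bad <- which(is.na(df[[col]]) | !nzchar(df[[col]]))
    if (length(bad) > 0) {
      pa_error(sprintf("%s row %d: empty value in key column %s",
                       path, bad[1], col), "papartition_io_error")
    }
  }
  as_tibble(df)
}

#' Load a compound results table
#'
#' Reads and validates a wide per-compound results table. For
#' `quantity = "logp"` the columns are `compound`, `logp_exp_mean`,
#' `logp_exp_sd` and the four in-silico methods (`kowwin`, `clogp`,
#' `sparc`, `splogp`); for `"rb"` they are `compound`, `rb_exp_mean`,
#' `rb_exp_sd`, `rb_acid_base`, `rb_mechanistic`. Empty cells denote
#' unavailable predictions and are preserved as `NA`; malformed rows
#' raise an error naming the row, unknown columns raise a warning.
#'
#' @param path Path to a CSV file.
#' @param quantity `"logp"` or `"rb"`.
#'
#' @return A validated tibble.
#' @export
load_compound_table <- function(path, quantity = c("logp", "rb")) {
  quantity <- match.arg(quantity)
  required <- if (quantity == "logp") {
    c("compound", "logp_exp_mean", "logp_exp_sd",
      "kowwin", "clogp", "sparc", "splogp")
  } else {
    c("compound", "rb_exp_mean", "rb_exp_sd",
      "rb_acid_base", "rb_mechanistic")
  }
  read_numeric_csv(path, required)
}

#' Packaged experimental and predicted log P values of the study compounds
#'
#' Wide table of the eight study compounds: experimental shake-flask
#' mean and SD plus the KowWIN, CLOGP, SPARC and S+logP predictions
#' (`NA` where a method provides no prediction).
#'
#' @return A tibble, see [load_compound_table()].
#' @export
pa_table1 <- function() {
  load_compound_table(extdata_path("table1_logp.csv"), "logp")
}

#' Packaged experimental and predicted Rb values of the study compounds
#'
#' Wide table of the eight study compounds: experimental depletion-assay
#' mean and SD plus the acid/base-classification and mechanistic model
#' predictions.
#'
#' @return A tibble, see [load_compound_table()].
#' @export
pa_table2 <- function() {
  load_compound_table(extdata_path("table2_rb.csv"), "rb")
}

#' Read shake-flask measurement CSVs
#'
#' Columns: `compound`, `direction`, `replicate_id`, `area_octanol`,
#' `area_water`.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of measurements.
#' @export
read_partition_measurements <- function(path) {
  df <- read_numeric_csv(
    path, c("compound", "direction", "replicate_id", "area_octanol",
            "area_water"),
    key_cols = c("compound", "direction"))
  check_partition_measurements(df)
  df
}

#' Read depletion-assay measurement CSVs
#'
#' Columns: `compound`, `concentration_ng_ml`, `replicate_id`,
#' `area_reference_plasma`, `area_equilibrated_plasma` (a plain
#' `concentration` column is also accepted).
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of measurements (column `concentration`).
#' @export
read_depletion_measurements <- function(path) {
  header <- names(read.csv(path, nrows = 1, check.names = FALSE))
  conc_col <- if ("concentration_ng_ml" %in% header) {
    "concentration_ng_ml"
  } else "concentration"
  df <- read_numeric_csv(
    path, c("compound", conc_col, "replicate_id",
            "area_reference_plasma", "area_equilibrated_plasma"),
    key_cols = "compound")
  names(df)[names(df) == conc_col] <- "concentration"
  check_depletion_measurements(df)
  df
}

#' Write a data frame to CSV atomically
#'
#' Writes to a temporary file in the destination directory and renames
#' into place, so a failed run never leaves a truncated file.
#'
#' @param x Data frame to write.
#' @param path Destination path.
#'
#' @return `path`, invisibly.
#' @export
write_csv_atomic <- function(x, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".csv.tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write.csv(x, tmp, row.names = FALSE, na = "")
  if (!file.rename(tmp, path)) {
    pa_error(sprintf("could not move temporary file into place at %s",
                     path), "papartition_io_error")
  }
  invisible(path)
}

#' Run the full evaluation report over both quantities and all methods
#'
#' Computes deviation reports for every in-silico method against the
#' experimental values of both quantities, the per-method band counts
#' and the experiment summaries, and writes them to `out_dir`
#' (`logp_deviations.csv`, `rb_deviations.csv`, `band_counts.csv` and a
#' human-readable `summary.txt`); all writes are atomic. Failures in
#' individual stages are collected rather than aborting the run.
#'
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing and only returns the computed objects.
#' @param table1,table2 Wide results tables (default: the packaged
#'   study tables).
#' @param seed Optional integer recorded in the summary header (the
#'   evaluation itself is deterministic).
#'
#' @return List of class `papartition_report`: `logp_deviations`,
#'   `rb_deviations`, `band_counts` (long tibble), `logp_summary`,
#'   `rb_summary`, `errors` (tibble; zero rows on full success), `ok`.
#' @export
run_full_report <- function(out_dir = NULL, table1 = pa_table1(),
                            table2 = pa_table2(), seed = NULL) {
  errors <- list()
  collect <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      errors[[length(errors) + 1L]] <<- tibble(
        stage = stage, message = conditionMessage(e))
      NULL
    })
  }
  dev_logp <- collect("logp_deviations",
                      logp_deviations(table1,
                                      logp_predictions_from_table(table1)))
  dev_rb <- collect("rb_deviations",
                    rb_deviations(table2,
                                  rb_predictions_from_table(table2)))
  counts <- list()
  if (!is.null(dev_logp)) {
    for (m in unique(dev_logp$method)) {
      bc <- collect(paste0("band_counts_logp_", m),
                    band_counts(dev_logp, m, "logp"))
      if (!is.null(bc)) counts[[length(counts) + 1L]] <- tibble(
        quantity = "logp", method = m, band = names(bc$counts),
        count = unname(bc$counts), n_available = bc$n)
    }
  }
  if (!is.null(dev_rb)) {
    for (m in unique(dev_rb$method)) {
      bc <- collect(paste0("band_counts_rb_", m),
                    band_counts(dev_rb, m, "rb"))
      if (!is.null(bc)) counts[[length(counts) + 1L]] <- tibble(
        quantity = "rb", method = m, band = names(bc$counts),
        count = unname(bc$counts), n_available = bc$n)
    }
  }
  counts <- if (length(counts) > 0) dplyr::bind_rows(counts) else NULL
  sum_logp <- collect("logp_summary", summarize_experiment(table1, "logp"))
  sum_rb <- collect("rb_summary", summarize_experiment(table2, "rb"))
  errors <- if (length(errors) > 0) dplyr::bind_rows(errors) else
    tibble(stage = character(), message = character())

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (!is.null(dev_logp)) {
      write_csv_atomic(dev_logp, file.path(out_dir, "logp_deviations.csv"))
    }
    if (!is.null(dev_rb)) {
      write_csv_atomic(dev_rb, file.path(out_dir, "rb_deviations.csv"))
    }
    if (!is.null(counts)) {
      write_csv_atomic(counts, file.path(out_dir, "band_counts.csv"))
    }
    txt <- c(
      sprintf("papartition evaluation report (%s)",
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      if (!is.null(seed)) sprintf("seed: %d", as.integer(seed)),
      "",
      report_summary_lines(sum_logp, dev_logp, "log P"),
      "",
      report_summary_lines(sum_rb, dev_rb, "Rb"),
      if (nrow(errors) > 0) c("", "errors:",
                              sprintf("  [%s] %s", errors$stage,
                                      errors$message)))
    tmp <- tempfile(tmpdir = out_dir, fileext = ".txt.tmp")
    writeLines(txt, tmp)
    file.rename(tmp, file.path(out_dir, "summary.txt"))
  }
  structure(list(logp_deviations = dev_logp, rb_deviations = dev_rb,
                 band_counts = counts, logp_summary = sum_logp,
                 rb_summary = sum_rb, errors = errors,
                 ok = nrow(errors) == 0),
            class = "papartition_report")
}

report_summary_lines <- function(summ, dev, label) {
  if (is.null(summ)) return(sprintf("%s: summary unavailable", label))
  lines <- c(
    sprintf("%s experimental range: %.3g (%s) to %.3g (%s)", label,
            summ$min, summ$argmin, summ$max, summ$argmax))
  if (length(summ$pa_ranking) > 0) {
    lines <- c(lines, sprintf("  alkaloid ranking (ascending): %s",
                              paste(summ$pa_ranking, collapse = " < ")))
  }
  if (!is.null(dev)) {
    for (m in unique(dev$method)) {
      sub <- dev[dev$method == m, ]
      tab <- table(sub$band)
      lines <- c(lines, sprintf(
        "  %s: n = %d; %s", m, nrow(sub),
        paste(sprintf("%s = %d", names(tab), as.integer(tab)),
              collapse = ", ")))
    }
  }
  lines
}

#' @export
print.papartition_report <- function(x, ...) {
  cat("<papartition_report>",
      if (x$ok) "(complete)" else
        sprintf("(%d stage error(s))", nrow(x$errors)), "\n")
  if (!is.null(x$logp_summary)) print(x$logp_summary)
  if (!is.null(x$rb_summary)) print(x$rb_summary)
  invisible(x)
}
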