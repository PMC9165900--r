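# numeric parser tolerant of decimal commas ("0,4" -> 0.4)
parse_number <- function(x) {
  out <- suppressWarnings(as.numeric(gsub(",", ".", trimws(as.character(x)),
                                          fixed = TRUE)))
  out
}

#' Read a raw-data spreadsheet of plate observations
#'
#' Parses a delimited file with one row per agar plate (columns `lab_id`,
#' `cycle`, `condition`, `run_index`, `strain`, `medium`, `role`,
#' `carrier`, `dilution_factor`, `plated_volume_ml`, `cfu`; `carrier`
#' may be omitted and defaults to 1). Numeric cells may use either the
#' decimal point or the decimal comma. Every invalid row is reported
#' with its row number and offending field.
#'
#' @param path CSV path (as written by [make_fixture_spreadsheet()]).
#' @return validated plate-observation data.frame for [quantify_runs()].
#' @export
read_raw_data <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, na.strings = character(0))
  required <- setdiff(plate_columns, "carrier")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("'", path, "' lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"carrier" %in% names(raw)) raw$carrier <- "1"
  num <- c("run_index", "carrier", "dilution_factor", "plated_volume_ml", "cfu")
  for (col in num) raw[[col]] <- parse_number(raw[[col]])
  bad <- which(rowSums(is.na(raw[num])) > 0)
  if (length(bad))
    stop("non-numeric cells in '", path, "':\n  ",
         paste0("row ", bad, ": one of ", paste(num, collapse = "/"),
                collapse = "\n  "), call. = FALSE)
  validate_plates(raw)
}

#' Reported ring-trial precision statistics
#'
#' The per-endpoint precision statistics reported for the prEN 17658
#' international ring trial (main wash, conditions A-C, 7 laboratories;
#' rinse cycle, conditions D-F, 6 laboratories): printed mean, 95%
#' confidence interval, reproducibility and repeatability standard
#' deviations, relative standard deviation and systematic-difference
#' class for each of the 9 endpoints x 6 conditions. Values are the
#' published 2-decimal renderings; the underlying raw laboratory data
#' were never deposited, so these rows serve as transcription input for
#' [summarize_precision()], not as recomputable ground truth.
#'
#' @return data.frame with columns `cycle`, `condition`, `endpoint`,
#'   `mean`, `ci_low`, `ci_high`, `S_R`, `S_r`, `rsd_percent`,
#'   `ratio_class`.
#' @export
reported_precision <- function() {
  path <- system.file("extdata", "reported_precision.csv",
                      package = "ringtrial", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(out) == 54L)
  out
}

#' Cross-table summary statistics
#'
#' Pools precision rows (normally both cycles, 54 rows) and computes the
#' headline summary of an interlaboratory report: the share of
#' endpoint x condition comparisons in each systematic-difference class,
#' the count of `considerable` comparisons, the share of determinations
#' strictly below 30% RSD, and the largest RSD, S_R and S_r. Class
#' shares are rounded to 1 decimal and the RSD share to the nearest
#' integer, the conventional display precisions.
#'
#' @param rows data.frame of precision rows ([precision_table()] output
#'   or [reported_precision()]); rows with `NA` statistics are dropped.
#' @return object of class `summary_stats`: list with `pct_minor`,
#'   `pct_clear`, `pct_considerable`, `n_considerable`,
#'   `pct_rsd_below_30`, `max_rsd`, `max_S_R`, `max_S_r`, `n_rows`.
#' @export
summarize_precision <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L,
            all(c("S_R", "S_r", "rsd_percent", "ratio_class") %in% names(rows)))
  rows <- rows[!is.na(rows$ratio_class), ]
  if (nrow(rows) == 0L) stop("no usable precision rows")
  n <- nrow(rows)
  cls <- table(factor(rows$ratio_class,
                      levels = c("minor", "clear", "considerable")))
  structure(list(
    pct_minor = round(100 * cls[["minor"]] / n, 1),
    pct_clear = round(100 * cls[["clear"]] / n, 1),
    pct_considerable = round(100 * cls[["considerable"]] / n, 1),
    n_considerable = unname(cls[["considerable"]]),
    pct_rsd_below_30 = round(100 * sum(rows$rsd_percent < 30) / n),
    max_rsd = max(rows$rsd_percent),
    max_S_R = max(rows$S_R),
    max_S_r = max(rows$S_r),
    n_rows = n), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("Ring-trial summary over", x$n_rows, "endpoint x condition rows\n")
  cat(sprintf("  systematic differences: %.1f%% minor, %.1f%% clear, %.1f%% considerable (n = %d)\n",
              x$pct_minor, x$pct_clear, x$pct_considerable, x$n_considerable))
  cat(sprintf("  %d%% of determinations below 30%% RSD; max RSD %.2f%%\n",
              x$pct_rsd_below_30, x$max_rsd))
  cat(sprintf("  max S_R = %.2f, max S_r = %.2f\n", x$max_S_R, x$max_S_r))
  invisible(x)
}

#' Render a precision table to CSV
#'
#' Writes the report layout (VARIABLE, Mean, CI95 low/high, S_R, S_r,
#' RSD %, ratio class) with 2-decimal numeric rendering and the ratio
#' class encoded as its footnote string. [parse_precision_csv()] reads
#' such a file back; a render/parse round trip is lossless at the
#' 2-decimal precision.
#'
#' @param x a [precision_table()].
#' @param path output CSV path.
#' @return invisibly, the rendered data.frame.
#' @export
render_precision_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  df <- as.data.frame(x)
  num <- c("mean", "ci_low", "ci_high", "S_R", "S_r", "rsd_percent")
  df[num] <- lapply(df[num], function(v) sprintf("%.2f", v))
  df$ratio_class <- ifelse(is.na(df$ratio_class), "NA",
                           ratio_class_labels[df$ratio_class])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' @rdname render_precision_csv
#' @export
parse_precision_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  num <- c("mean", "ci_low", "ci_high", "S_R", "S_r", "rsd_percent")
  df[num] <- lapply(df[num], parse_number)
  df$n <- as.integer(df$n)
  inv <- stats::setNames(names(ratio_class_labels), ratio_class_labels)
  df$ratio_class <- unname(inv[df$ratio_class])
  class(df) <- c("precision_table", "data.frame")
  df
}

#' Run the full ring-trial analysis pipeline
#'
#' Orchestrates quantification, precision estimation, outlier screening
#' and summary for one dataset: raw plates are quantified into per-run
#' endpoints, a precision table is computed per cycle, Cochran/Grubbs
#' screening removes flagged data and the table is recomputed, and the
#' cross-table summary statistics are assembled. All tables are written
#' to `out_dir` (precision pre/post outlier removal, outlier report,
#' plain-text summary block and machine-readable `results.json`).
#'
#' @param input either a path to a raw-data CSV ([read_raw_data()]), a
#'   plate-observation data.frame, or a [sim_config()] (the synthetic
#'   trial is then generated and analysed).
#' @param out_dir output directory, created if needed; `NULL` skips
#'   file output.
#' @param method variance-component estimator.
#' @param alpha significance level for the outlier tests.
#' @return invisibly, a list with `records`, `precision` (pre-removal),
#'   `screen` (output of [screen_and_reanalyze()]) and `summary`.
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         method = c("anova_mom", "reml"), alpha = 0.05) {
  method <- match.arg(method)
  plates <- NULL
  if (inherits(input, "sim_config")) {
    plates <- simulate_plate_counts(input)$plates
  } else if (is.character(input)) {
    plates <- read_raw_data(input)
  } else if (is.data.frame(input) && "cfu" %in% names(input)) {
    plates <- validate_plates(input)
  } else if (is.data.frame(input) && "endpoint" %in% names(input)) {
    records <- input  # pre-quantified run records
  } else stop("input must be a path, plate data.frame, run records or sim_config")
  if (!is.null(plates)) {
    records <- quantify_runs(plates)
    message(sum(records$censored, na.rm = TRUE),
            " endpoint values censored at a detection limit")
  }
  precision <- precision_table(records, method)
  screen <- screen_and_reanalyze(records, alpha = alpha, method = method)
  summary <- summarize_precision(precision)
  message(screen$n_removed, " observations removed by outlier screening")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    render_precision_csv(precision, file.path(out_dir, "precision.csv"))
    render_precision_csv(screen$after,
                         file.path(out_dir, "precision_post_outliers.csv"))
    utils::write.csv(screen$report, file.path(out_dir, "outlier_report.csv"),
                     row.names = FALSE)
    s <- utils::capture.output(print(summary))
    writeLines(s, file.path(out_dir, "summary.txt"))
    jsonlite::write_json(
      list(summary = unclass(summary),
           n_removed_outliers = screen$n_removed,
           n_records = nrow(records)),
      file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(records = records, precision = precision, screen = screen,
                 summary = summary))
}
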