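#' @name ringtrial-endpoints
#' @title Endpoint layout of the laundering carrier test
#' @description
#' Each laboratory x condition x run yields nine log10-scale endpoints:
#' five log reductions (one per test strain: *P. aeruginosa* PA,
#' *E. coli* EC, *S. aureus* SA, *E. hirae* EH, *C. albicans* CA), the
#' cross-contamination recovery on initially sterile carriers per medium
#' (RI-TSA, RI-MEA) and the wash-water recovery per medium (WW-TSA,
#' WW-MEA).
NULL

endpoint_names <- function() {
  c("LR-PA", "LR-EC", "LR-SA", "LR-EH", "LR-CA",
    "RI-TSA", "RI-MEA", "WW-TSA", "WW-MEA")
}

strain_names <- function() c("PA", "EC", "SA", "EH", "CA")

strain_class <- function(strain) {
  ifelse(strain == "CA", "yeast", "bacteria")
}

run_key_cols <- c("lab_id", "cycle", "condition", "run_index")

plate_columns <- c("lab_id", "cycle", "condition", "run_index", "strain",
                   "medium", "role", "carrier", "dilution_factor",
                   "plated_volume_ml", "cfu")

# Validate a plate-observation data.frame; returns it with canonical
# column order and types, or stops with row-numbered diagnostics.
validate_plates <- function(plates) {
  stopifnot(is.data.frame(plates))
  if (!"carrier" %in% names(plates)) plates$carrier <- 1L
  missing_cols <- setdiff(plate_columns, names(plates))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  plates <- plates[plate_columns]
  problems <- character(0)
  note <- function(rows, msg) {
    if (any(rows)) c(problems, paste0("row ", which(rows), ": ", msg)) else problems
  }
  problems <- note(!plates$cycle %in% c("main_wash", "rinse"),
                   "cycle must be main_wash or rinse")
  problems <- note(!plates$condition %in% LETTERS[1:6],
                   "condition must be one of A-F")
  problems <- note(!plates$role %in% c("N0", "Na", "RI", "WW"),
                   "role must be one of N0, Na, RI, WW")
  problems <- note(!plates$medium %in% c("TSA", "MEA"),
                   "medium must be TSA or MEA")
  problems <- note(plates$role %in% c("N0", "Na") &
                     !plates$strain %in% strain_names(),
                   "N0/Na plates need a strain (PA, EC, SA, EH, CA)")
  problems <- note(!is.finite(plates$cfu) | plates$cfu < 0 |
                     plates$cfu != round(plates$cfu),
                   "cfu must be a non-negative integer")
  problems <- note(!is.finite(plates$dilution_factor) |
                     plates$dilution_factor <= 0 | plates$dilution_factor > 1,
                   "dilution_factor must be in (0, 1]")
  problems <- note(!is.finite(plates$plated_volume_ml) |
                     plates$plated_volume_ml <= 0,
                   "plated_volume_ml must be positive")
  problems <- note(!is.finite(plates$run_index) | plates$run_index < 1,
                   "run_index must be a positive integer")
  if (length(problems))
    stop("invalid plate observations:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  plates$run_index <- as.integer(plates$run_index)
  plates$cfu <- as.integer(plates$cfu)
  plates
}

# Mean log10 load over the carriers of one role/strain/medium within a run.
# Carrier counts are computed per carrier eluate, then averaged on the log
# scale; the censor flag is set when any contributing carrier was censored.
pool_carriers <- function(sub, role, limits) {
  per_carrier <- lapply(split(sub, sub$carrier), function(pl) {
    carrier_count(pl$cfu, pl$dilution_factor, pl$plated_volume_ml,
                  role = role, limits = limits)
  })
  logs <- vapply(per_carrier, `[[`, numeric(1), "log10_count")
  cens <- vapply(per_carrier, `[[`, logical(1), "censored")
  list(log10 = mean(logs), censored = any(cens))
}

#' Derive per-run endpoints from raw plate observations
#'
#' Groups the plate table by laboratory, cycle, condition and run, applies
#' the dilution-weighted quantification with detection-limit censoring to
#' every carrier eluate and wash-water sample, and assembles the nine
#' log10-scale endpoints per run. Log reductions use the run's own control
#' carriers (`LR = N0 - Na`, carrier log10 counts averaged within a run
#' before subtraction).
#'
#' @param plates data.frame of plate observations with columns `lab_id`,
#'   `cycle`, `condition`, `run_index`, `strain`, `medium`, `role`
#'   (N0/Na/RI/WW), `carrier`, `dilution_factor`, `plated_volume_ml`,
#'   `cfu`; see [read_raw_data()].
#' @param limits detection-limit constants, see [detection_limits()].
#' @return data.frame of run records in long form: the run key columns
#'   plus `endpoint`, `value` (log10 scale; `NA` when the endpoint is
#'   missing from the raw data) and `censored`.
#' @seealso [precision_table()], [simulate_plate_counts()]
#' @export
quantify_runs <- function(plates, limits = detection_limits()) {
  plates <- validate_plates(plates)
  key <- interaction(plates[run_key_cols], drop = TRUE, lex.order = TRUE)
  out <- lapply(split(plates, key), function(run) {
    rec <- as.list(run[1L, run_key_cols])
    vals <- stats::setNames(rep(NA_real_, 9L), endpoint_names())
    cens <- stats::setNames(rep(NA, 9L), endpoint_names())
    for (st in strain_names()) {
      n0 <- run[run$role == "N0" & run$strain == st, ]
      na <- run[run$role == "Na" & run$strain == st, ]
      if (nrow(n0) && nrow(na)) {
        n0q <- pool_carriers(n0, "N0", limits)
        naq <- pool_carriers(na, "Na", limits)
        ep <- paste0("LR-", st)
        vals[ep] <- log_reduction(n0q$log10, naq$log10)
        cens[ep] <- naq$censored
      }
    }
    for (med in c("TSA", "MEA")) {
      ri <- run[run$role == "RI" & run$medium == med, ]
      if (nrow(ri)) {
        q <- pool_carriers(ri, "RI", limits)
        vals[paste0("RI-", med)] <- q$log10
        cens[paste0("RI-", med)] <- q$censored
      }
      ww <- run[run$role == "WW" & run$medium == med, ]
      if (nrow(ww)) {
        q <- wash_water_count(ww$cfu, ww$dilution_factor, limits = limits)
        vals[paste0("WW-", med)] <- q$log10_count
        cens[paste0("WW-", med)] <- q$censored
      }
    }
    data.frame(rec, endpoint = endpoint_names(), value = unname(vals),
               censored = unname(cens), row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
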