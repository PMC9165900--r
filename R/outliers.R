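#' Critical value of Cochran's variance-homogeneity test
#'
#' Exact upper critical value of Cochran's C (the largest of p variances
#' over their sum, each on n - 1 degrees of freedom) via the F-quantile
#' identity
#' \deqn{C_{crit} = \left[1 + (p-1)/F_{1-\alpha/p}(n-1, (p-1)(n-1))\right]^{-1}}
#' which reproduces the classical printed tables (e.g. 0.8709 for
#' p = 3 laboratories, n = 3 replicates, alpha = 0.05).
#'
#' @param alpha significance level.
#' @param p number of variances (laboratories).
#' @param n replicates per laboratory.
#' @return numeric critical value in (0, 1).
#' @export
cochran_critical <- function(alpha, p, n) {
  stopifnot(p >= 2, n >= 2)
  1 / (1 + (p - 1) / stats::qf(1 - alpha / p, n - 1, (p - 1) * (n - 1)))
}

#' Cochran test for abnormal laboratory variance
#'
#' Screens the per-laboratory variances of one endpoint for a laboratory
#' whose within-run scatter is abnormally large:
#' `C = max(s_i^2) / sum(s_i^2)`, compared with [cochran_critical()].
#' With unequal replication the critical value for the largest
#' replication count is used (the more permissive bound), with a note.
#'
#' @param lab_variances data.frame with columns `lab_id`, `s2`
#'   (within-laboratory variance) and `n_reps` (replicates); needs at
#'   least 3 laboratories.
#' @param alpha significance level, default 0.05.
#' @return list with `C`, `critical`, `flagged_lab` (`NA` if none),
#'   `alpha`, `note`.
#' @export
cochran_test <- function(lab_variances, alpha = 0.05) {
  stopifnot(is.data.frame(lab_variances),
            all(c("lab_id", "s2", "n_reps") %in% names(lab_variances)))
  p <- nrow(lab_variances)
  if (p < 3L) stop("Cochran test needs at least 3 laboratories")
  stopifnot(all(lab_variances$s2 >= 0), all(lab_variances$n_reps >= 2))
  total <- sum(lab_variances$s2)
  if (total == 0) {
    return(list(C = NA_real_, critical = NA_real_, flagged_lab = NA,
                alpha = alpha, note = "all variances zero; test undefined"))
  }
  note <- NA_character_
  n <- lab_variances$n_reps[1L]
  if (length(unique(lab_variances$n_reps)) > 1L) {
    n <- max(lab_variances$n_reps)
    note <- "unequal replication: critical value taken at the largest n"
  }
  C <- max(lab_variances$s2) / total
  crit <- cochran_critical(alpha, p, n)
  flagged <- if (C > crit)
    lab_variances$lab_id[which.max(lab_variances$s2)] else NA
  list(C = C, critical = crit, flagged_lab = flagged, alpha = alpha,
       note = note)
}

#' Grubbs test for a single outlying observation
#'
#' Two-sided single-outlier Grubbs test: `G = max|x_i - mean| / s` with
#' the critical value
#' \deqn{\frac{n-1}{\sqrt n}\sqrt{\frac{t^2}{n-2+t^2}},\quad
#'       t = t_{1-\alpha/(2n),\,n-2}.}
#' G is algebraically bounded by \eqn{(n-1)/\sqrt n}.
#'
#' @param values numeric vector, n >= 3, non-degenerate (s > 0).
#' @param alpha significance level, default 0.05.
#' @return list with `G`, `critical`, `flagged_index` (`NA` if none),
#'   `alpha`.
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L) stop("Grubbs test needs at least 3 observations")
  s <- stats::sd(values)
  if (s == 0) stop("degenerate sample: zero standard deviation")
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  crit <- grubbs_critical(alpha, n)
  list(G = G, critical = crit,
       flagged_index = if (G > crit) which.max(dev) else NA_integer_,
       alpha = alpha)
}

#' @rdname grubbs_test
#' @param n sample size.
#' @export
grubbs_critical <- function(alpha, n) {
  t <- stats::qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Outlier screening with re-analysis
#'
#' Applies, per endpoint x condition cell, the Cochran test to the
#' per-laboratory variances and then the Grubbs test to the pooled
#' observations, removes flagged data (the whole laboratory for a
#' Cochran flag; a single observation per pass for a Grubbs flag, at
#' most `max_passes` passes), and recomputes the precision table on the
#' cleaned records. Removal is skipped with a warning whenever it would
#' leave fewer than two laboratories in a cell.
#'
#' @param records run records as returned by [quantify_runs()] or
#'   [simulate_endpoints()].
#' @param alpha significance level for both tests, default 0.05.
#' @param method variance-component estimator for the precision tables.
#' @param max_passes maximum screening passes per cell, default 2.
#' @return list with `report` (one row per test performed: cycle,
#'   condition, endpoint, pass, test, statistic, critical, flagged lab /
#'   run, action), `cleaned` (records after removal), `before` and
#'   `after` ([precision_table()] on the original and cleaned records),
#'   and `n_removed`.
#' @export
screen_and_reanalyze <- function(records, alpha = 0.05,
                                 method = c("anova_mom", "reml"),
                                 max_passes = 2L) {
  method <- match.arg(method)
  cleaned <- records
  report <- list()
  log_row <- function(cell, pass, test, stat, crit, lab, run, action) {
    data.frame(cycle = cell$cycle, condition = cell$condition,
               endpoint = cell$endpoint, pass = pass, test = test,
               statistic = stat, critical = crit,
               flagged_lab = as.character(lab),
               flagged_run = if (is.na(run)) NA_integer_ else as.integer(run),
               action = action)
  }
  cells <- unique(records[c("cycle", "condition", "endpoint")])
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    for (pass in seq_len(max_passes)) {
      sel <- cleaned$cycle == cell$cycle &
        cleaned$condition == cell$condition &
        cleaned$endpoint == cell$endpoint & !is.na(cleaned$value)
      sub <- cleaned[sel, ]
      if (nrow(sub) < 3L || length(unique(sub$lab_id)) < 3L) break
      removed <- FALSE

      # Cochran on per-lab variances (labs with >= 2 runs)
      by_lab <- split(sub$value, sub$lab_id)
      by_lab <- by_lab[vapply(by_lab, length, 1L) >= 2L]
      if (length(by_lab) >= 3L && stats::var(sub$value) > 0) {
        lv <- data.frame(lab_id = names(by_lab),
                         s2 = vapply(by_lab, stats::var, 1),
                         n_reps = vapply(by_lab, length, 1L))
        ct <- cochran_test(lv, alpha)
        if (!is.na(ct$flagged_lab)) {
          if (length(unique(sub$lab_id)) <= 2L) {
            report[[length(report) + 1L]] <-
              log_row(cell, pass, "cochran", ct$C, ct$critical,
                      ct$flagged_lab, NA, "kept (too few labs to remove)")
            warning("Cochran flag not removed for ", cell$endpoint,
                    " (", cell$condition, "): would leave < 2 labs",
                    call. = FALSE)
          } else {
            drop <- sel & cleaned$lab_id == ct$flagged_lab
            cleaned <- cleaned[!drop, ]
            report[[length(report) + 1L]] <-
              log_row(cell, pass, "cochran", ct$C, ct$critical,
                      ct$flagged_lab, NA, "laboratory removed")
            removed <- TRUE
          }
        } else if (!is.na(ct$C)) {
          report[[length(report) + 1L]] <-
            log_row(cell, pass, "cochran", ct$C, ct$critical, NA, NA, "none")
        }
      }

      # Grubbs on the pooled observations (at most one removal per pass)
      sel <- cleaned$cycle == cell$cycle &
        cleaned$condition == cell$condition &
        cleaned$endpoint == cell$endpoint & !is.na(cleaned$value)
      sub <- cleaned[sel, ]
      if (nrow(sub) >= 3L && stats::sd(sub$value) > 0) {
        gt <- grubbs_test(sub$value, alpha)
        if (!is.na(gt$flagged_index)) {
          hit <- sub[gt$flagged_index, ]
          others <- unique(sub$lab_id[-gt$flagged_index])
          if (length(others) < 2L) {
            report[[length(report) + 1L]] <-
              log_row(cell, pass, "grubbs", gt$G, gt$critical, hit$lab_id,
                      hit$run_index, "kept (too few labs to remove)")
            warning("Grubbs flag not removed for ", cell$endpoint,
                    " (", cell$condition, "): would leave < 2 labs",
                    call. = FALSE)
          } else {
            drop <- sel & cleaned$lab_id == hit$lab_id &
              cleaned$run_index == hit$run_index
            cleaned <- cleaned[!drop, ]
            report[[length(report) + 1L]] <-
              log_row(cell, pass, "grubbs", gt$G, gt$critical, hit$lab_id,
                      hit$run_index, "observation removed")
            removed <- TRUE
          }
        } else {
          report[[length(report) + 1L]] <-
            log_row(cell, pass, "grubbs", gt$G, gt$critical, NA, NA, "none")
        }
      }
      if (!removed) break
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(cycle = character(0), condition = character(0),
               endpoint = character(0), pass = integer(0), test = character(0),
               statistic = numeric(0), critical = numeric(0),
               flagged_lab = character(0), flagged_run = integer(0),
               action = character(0))
  rownames(report) <- NULL
  rownames(cleaned) <- NULL
  list(report = report, cleaned = cleaned,
       before = precision_table(records, method),
       after = precision_table(cleaned, method),
       n_removed = sum(!is.na(records$value)) - sum(!is.na(cleaned$value)))
}
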