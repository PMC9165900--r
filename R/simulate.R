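#' Default endpoint means of the synthetic ring trial
#'
#' Per-condition endpoint means (log10 scale) used by [sim_config()].
#' The presets mirror the magnitudes reported for the prEN 17658 ring
#' trial — water-only washes around 1.3–2.4 log10 reduction, detergent
#' plus active around 5 log10, wash-water recoveries piling up at the
#' 1.15 detection limit under the efficacious rinse dose — so synthetic
#' reports are visually comparable with real ones. They are presets, not
#' ground truth.
#'
#' @param cycle `"main_wash"` (conditions A-C) or `"rinse"` (D-F).
#' @return data.frame with columns `condition`, `endpoint`, `mu`.
#' @export
default_endpoint_means <- function(cycle = c("main_wash", "rinse")) {
  cycle <- match.arg(cycle)
  ep <- endpoint_names()
  if (cycle == "main_wash") {
    mus <- list(
      A = c(2.37, 1.79, 1.31, 1.84, 1.80, 3.35, 3.20, 4.58, 4.40),
      B = c(3.13, 3.61, 2.27, 2.61, 2.13, 2.95, 2.71, 3.29, 3.37),
      C = c(5.51, 4.91, 5.05, 4.85, 2.97, 1.72, 1.76, 1.92, 2.31))
  } else {
    mus <- list(
      D = c(1.86, 1.50, 0.92, 1.38, 1.64, 3.60, 2.91, 4.84, 4.29),
      E = c(2.63, 3.13, 3.06, 2.94, 3.14, 2.02, 1.88, 1.45, 1.38),
      F = c(5.16, 5.06, 5.11, 5.00, 4.27, 1.61, 1.55, 1.00, 1.00))
  }
  do.call(rbind, lapply(names(mus), function(cond) {
    data.frame(condition = cond, endpoint = ep, mu = mus[[cond]])
  }))
}

#' Configuration of a synthetic ring trial
#'
#' Parameterises the generator for one cycle of the interlaboratory
#' design: 7 laboratories for the main wash (conditions A-C) or 6 for
#' the rinse cycle (D-F), 3 runs per condition, normal between-
#' laboratory effects (sd `sigma_B`) and residual run noise (sd
#' `sigma_r`) added to per-endpoint means on the log10 scale, with
#' detection-limit censoring of the Na/RI/WW levels. An optional Poisson
#' layer forward-models agar plates over a 10-fold dilution series.
#'
#' @param cycle `"main_wash"` or `"rinse"`.
#' @param n_labs number of laboratories (default 7 main wash, 6 rinse).
#' @param n_runs runs per laboratory per condition, default 3.
#' @param conditions test conditions (default A-C or D-F by cycle).
#' @param endpoint_means data.frame `condition`/`endpoint`/`mu`; default
#'   [default_endpoint_means()].
#' @param sigma_B,sigma_r between-laboratory and repeatability standard
#'   deviations on the log10 scale; defaults 0.4 and 0.35, mid-range of
#'   the reported reproducibility and repeatability components.
#' @param n0_mean control-carrier inoculum per strain (log10
#'   cfu/carrier); default 6.5 for bacteria, 5.5 for the yeast CA —
#'   inside the method's validity windows and countable within the
#'   default dilution series.
#' @param limits detection-limit constants, see [detection_limits()].
#' @param shared_lab_effect if `TRUE`, one laboratory effect is shared
#'   across endpoints instead of drawn independently per endpoint.
#' @param poisson_layer draw Poisson plate counts in
#'   [simulate_plate_counts()] (`TRUE`) or use rounded expected counts
#'   (`FALSE`, the noiseless variant).
#' @param dilution_scheme dilution factors of the series, duplicate
#'   0.4-ml plates each; default `10^(0:-4)`.
#' @param seed integer seed; every generator call is reproducible.
#' @return object of class `sim_config` (a named list).
#' @export
sim_config <- function(cycle = c("main_wash", "rinse"),
                       n_labs = NULL, n_runs = 3L, conditions = NULL,
                       endpoint_means = NULL, sigma_B = 0.4, sigma_r = 0.35,
                       n0_mean = NULL, limits = detection_limits(),
                       shared_lab_effect = FALSE, poisson_layer = TRUE,
                       dilution_scheme = 10^(0:-4), seed = 1L) {
  cycle <- match.arg(cycle)
  if (is.null(n_labs)) n_labs <- if (cycle == "main_wash") 7L else 6L
  if (is.null(conditions))
    conditions <- if (cycle == "main_wash") c("A", "B", "C") else c("D", "E", "F")
  if (is.null(endpoint_means)) endpoint_means <- default_endpoint_means(cycle)
  if (is.null(n0_mean))
    n0_mean <- c(PA = 6.5, EC = 6.5, SA = 6.5, EH = 6.5, CA = 5.5)
  stopifnot(n_labs >= 2, n_runs >= 2, sigma_B >= 0, sigma_r >= 0,
            all(conditions %in% endpoint_means$condition),
            all(dilution_scheme > 0), all(dilution_scheme <= 1))
  structure(list(cycle = cycle, n_labs = as.integer(n_labs),
                 n_runs = as.integer(n_runs), conditions = conditions,
                 endpoint_means = endpoint_means, sigma_B = sigma_B,
                 sigma_r = sigma_r, n0_mean = n0_mean, limits = limits,
                 shared_lab_effect = shared_lab_effect,
                 poisson_layer = poisson_layer,
                 dilution_scheme = sort(dilution_scheme, decreasing = TRUE),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic ring-trial config: %s, %d labs x %d runs x conditions {%s}\n",
    x$cycle, x$n_labs, x$n_runs, paste(x$conditions, collapse = ", ")))
  cat(sprintf("  sigma_B = %.3g, sigma_r = %.3g, poisson_layer = %s, seed = %d\n",
              x$sigma_B, x$sigma_r, x$poisson_layer, x$seed))
  invisible(x)
}

# Underlying per-run levels (log10) implied by the endpoint draws; LR
# endpoints are realised through N0 and Na so that censoring acts on the
# Na level, never on the LR directly.
simulate_levels <- function(config) {
  set.seed(config$seed)
  labs <- sprintf("Lab%d", seq_len(config$n_labs))
  eps <- endpoint_names()
  out <- list()
  for (cond in config$conditions) {
    mu <- config$endpoint_means
    mu <- stats::setNames(mu$mu[mu$condition == cond], mu$endpoint[mu$condition == cond])
    for (lab in labs) {
      b <- if (config$shared_lab_effect)
        rep(stats::rnorm(1, 0, config$sigma_B), length(eps))
      else stats::rnorm(length(eps), 0, config$sigma_B)
      names(b) <- eps
      for (run in seq_len(config$n_runs)) {
        e <- stats::setNames(stats::rnorm(length(eps), 0, config$sigma_r), eps)
        y <- mu[eps] + b + e
        out[[length(out) + 1L]] <-
          data.frame(lab_id = lab, cycle = config$cycle, condition = cond,
                     run_index = run, endpoint = eps, y_raw = unname(y))
      }
    }
  }
  do.call(rbind, out)
}

#' Simulate per-run endpoint records
#'
#' Draws the nine endpoints of every laboratory x condition x run from
#' the one-way random-effects model (one between-laboratory effect per
#' laboratory per endpoint, plus residual run noise) and applies the
#' detection-limit censoring the quantification stage would apply: RI
#' and WW levels are floored at their limits; LR endpoints are realised
#' as `N0 - Na` with the Na level floored at the carrier limit, so low
#' residual loads pile up at `n0_mean - 1.54`.
#'
#' @param config a [sim_config()].
#' @return run records in the format of [quantify_runs()], plus the
#'   uncensored latent value in `value_raw`.
#' @export
simulate_endpoints <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lv <- simulate_levels(config)
  lim <- config$limits
  value <- numeric(nrow(lv))
  censored <- logical(nrow(lv))
  kind <- substr(lv$endpoint, 1, 2)
  for (i in seq_len(nrow(lv))) {
    y <- lv$y_raw[i]
    if (kind[i] == "LR") {
      st <- sub("LR-", "", lv$endpoint[i])
      n0 <- config$n0_mean[[st]]
      na <- apply_detection_limit(n0 - y, "Na", lim)
      value[i] <- log_reduction(n0, na$log10)
      censored[i] <- na$censored
    } else {
      role <- if (kind[i] == "RI") "RI" else "WW"
      r <- apply_detection_limit(y, role, lim)
      value[i] <- r$log10
      censored[i] <- r$censored
    }
  }
  out <- data.frame(lv[c(run_key_cols, "endpoint")], value = value,
                    censored = censored, value_raw = lv$y_raw)
  rownames(out) <- NULL
  out
}

#' Forward-model agar plates from a synthetic ring trial
#'
#' Expands the latent per-run levels into raw plate observations the
#' quantification stage can consume: per strain one Na carrier, three N0
#' control carriers and (per medium) two RI carriers are plated in
#' duplicate 0.4-ml samples across the dilution series; wash water is
#' plated on five direct 2-ml plates per medium. The expected count of a
#' carrier plate at true load `y` (log10 cfu/carrier) and dilution `d`
#' is `10^y * 0.4 * d`; a wash-water plate at level `y` (log10
#' cfu/plate) expects `10^y`. Counts are Poisson draws, or rounded
#' expectations when `config$poisson_layer` is `FALSE`; dilutions with
#' expected counts above 1e6 are skipped (they would be uncountable).
#'
#' @param config a [sim_config()].
#' @return list with `plates` (data.frame accepted by [quantify_runs()])
#'   and `truth` (the latent run records from [simulate_endpoints()]).
#' @export
simulate_plate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- simulate_endpoints(config)
  # reseed independently of the endpoint draws so the two layers are
  # reproducible separately
  set.seed(config$seed + 10007L)
  draw <- function(lambda) {
    if (config$poisson_layer) stats::rpois(length(lambda), lambda)
    else as.integer(round(lambda))
  }
  plate_rows <- list()
  add_carrier <- function(meta, role, strain, medium, carrier, y) {
    for (d in config$dilution_scheme) {
      lambda <- 10^y * 0.4 * d
      if (lambda > 1e6) next
      cnt <- draw(rep(lambda, 2L))
      plate_rows[[length(plate_rows) + 1L]] <<-
        data.frame(meta, strain = strain, medium = medium, role = role,
                   carrier = carrier, dilution_factor = d,
                   plated_volume_ml = 0.4, cfu = cnt)
    }
  }
  keys <- unique(truth[run_key_cols])
  for (i in seq_len(nrow(keys))) {
    meta <- as.list(keys[i, ])
    rec <- truth[truth$lab_id == meta$lab_id & truth$condition == meta$condition &
                   truth$run_index == meta$run_index, ]
    val <- stats::setNames(rec$value, rec$endpoint)
    for (st in strain_names()) {
      med <- if (st == "CA") "MEA" else "TSA"
      n0 <- config$n0_mean[[st]]
      na <- n0 - val[[paste0("LR-", st)]]
      for (k in 1:3) add_carrier(meta, "N0", st, med, k, n0)
      add_carrier(meta, "Na", st, med, 1L, na)
    }
    for (med in c("TSA", "MEA")) {
      for (k in 1:2) add_carrier(meta, "RI", "", med, k, val[[paste0("RI-", med)]])
      for (d in config$dilution_scheme) {
        lambda <- 10^val[[paste0("WW-", med)]] * d
        if (lambda > 1e6) next
        plate_rows[[length(plate_rows) + 1L]] <-
          data.frame(meta, strain = "", medium = med, role = "WW",
                     carrier = 1L, dilution_factor = d, plated_volume_ml = 2,
                     cfu = draw(rep(lambda, 5L)))
      }
    }
  }
  plates <- do.call(rbind, plate_rows)
  rownames(plates) <- NULL
  list(plates = plates, truth = truth)
}

#' Write a synthetic raw-data spreadsheet
#'
#' Emits the plate observations of a simulated ring trial as the CSV
#' dialect [read_raw_data()] consumes, together with a JSON companion
#' file (`<path>.config.json`) recording the generating configuration
#' and seed for provenance.
#'
#' @param config a [sim_config()].
#' @param path output CSV path.
#' @return invisibly, the plate data.frame written.
#' @export
make_fixture_spreadsheet <- function(config, path) {
  sim <- simulate_plate_counts(config)
  ok <- tryCatch({
    utils::write.csv(sim$plates, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("could not write fixture to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  cfg <- config
  cfg$limits <- unclass(cfg$limits)
  jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim$plates)
}
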