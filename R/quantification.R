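#' Plate-count admissibility window
#'
#' Colony counts outside the countable window are discarded before
#' quantification: crowded plates undercount overlapping colonies and
#' sparse plates carry too much Poisson noise. The window used throughout
#' the prEN 17658 ring-trial analysis is 14--330 cfu, both ends inclusive.
#'
#' @param cfu integer vector of colony counts (non-negative).
#' @param lower,upper inclusive bounds of the countable window.
#' @return logical vector, `TRUE` where the plate is countable.
#' @examples
#' plate_admissible(c(0, 13, 14, 200, 330, 331))
#' @export
plate_admissible <- function(cfu, lower = 14L, upper = 330L) {
  stopifnot(is.numeric(cfu), all(is.finite(cfu)), all(cfu >= 0),
            all(cfu == round(cfu)))
  cfu >= lower & cfu <= upper
}

#' Detection-limit constants
#'
#' Below-limit recoveries are recorded at a fixed censoring constant:
#' 1.54 log10 for per-carrier counts (Na, RI; 14 cfu on a direct 0.4-ml
#' plate corresponds to 35 cfu/carrier, log10 = 1.54) and 1.15 log10 for
#' wash-water plates (14 cfu on a direct 2-ml plate). Other plated
#' volumes can supply their own constants.
#'
#' @param carrier censoring constant for Na/RI endpoints (log10 cfu/carrier).
#' @param wash_water censoring constant for WW endpoints (log10 cfu/plate).
#' @return named list with elements `carrier` and `wash_water`.
#' @export
detection_limits <- function(carrier = 1.54, wash_water = 1.15) {
  stopifnot(is.numeric(carrier), length(carrier) == 1L,
            is.numeric(wash_water), length(wash_water) == 1L)
  list(carrier = carrier, wash_water = wash_water)
}

#' Apply detection-limit censoring to a log10 value
#'
#' Values below the role's detection limit, and undefined values (`NA`,
#' e.g. zero recovery), are replaced by the censoring constant; values at
#' or above the limit pass through unchanged.
#'
#' @param raw_log10 numeric scalar on the log10 scale, or `NA` for an
#'   undefined (zero-count) result.
#' @param role one of `"Na"`, `"RI"`, `"WW"`.
#' @param limits detection-limit constants, see [detection_limits()].
#' @return list with elements `log10` (numeric) and `censored` (logical).
#' @examples
#' apply_detection_limit(NA, "Na")   # 1.54, censored
#' apply_detection_limit(3.2, "RI")  # passes through
#' @export
apply_detection_limit <- function(raw_log10, role, limits = detection_limits()) {
  role <- match.arg(role, c("Na", "RI", "WW"))
  limit <- if (role == "WW") limits$wash_water else limits$carrier
  if (is.null(raw_log10) || length(raw_log10) == 0L || is.na(raw_log10) ||
      raw_log10 < limit) {
    list(log10 = limit, censored = TRUE)
  } else {
    list(log10 = raw_log10, censored = FALSE)
  }
}

# Pick the dilution level(s) entering the weighted count: the least dilute
# level with at least one countable plate, plus the next (10x more dilute)
# level when it is also countable. Returns indices into `dilution`.
select_countable <- function(dilution, admissible) {
  levels <- sort(unique(dilution[admissible]), decreasing = TRUE)
  if (length(levels) == 0L) return(integer(0))
  use <- levels[1L]
  if (length(levels) > 1L && abs(levels[1L] / levels[2L] - 10) < 1e-6) {
    use <- levels[1:2]
  } else if (length(levels) > 1L) {
    stop("admissible plates at non-consecutive dilutions (",
         paste(signif(levels, 3), collapse = ", "),
         "); supply at most two consecutive dilution levels", call. = FALSE)
  }
  which(admissible & dilution %in% use)
}

#' Weighted per-carrier count from a dilution series
#'
#' Combines the countable plates of one carrier eluate into a single
#' cfu/carrier estimate using the dilution-weighted mean
#' \deqn{N = c / (V (n_1 + 0.1 n_2) d)}
#' where \eqn{c} is the summed count over countable plates, \eqn{n_1} and
#' \eqn{n_2} the numbers of countable plates at the lower (less dilute)
#' and higher dilution, \eqn{d} the lower dilution factor and \eqn{V} the
#' plated volume (0.4 ml for carrier eluates). When no plate is countable
#' and every count sits below the floor, the result is censored at the
#' role's detection limit (the count is recorded as 14 cfu/plate at the
#' direct dilution, i.e. 35 cfu/carrier at 0.4 ml).
#'
#' @param cfu integer vector of plate counts.
#' @param dilution_factor dilution factor per plate (1 = direct, 0.1, ...),
#'   at most two consecutive levels among countable plates.
#' @param plated_volume_ml plated volume per plate in ml; must be uniform.
#' @param role `"N0"`, `"Na"` or `"RI"` — controls censoring (N0 is never
#'   censored: an uncountably low control invalidates the run).
#' @param limits detection-limit constants, see [detection_limits()].
#' @return list with elements `count_per_carrier`, `log10_count`,
#'   `censored`, `n1`, `n2`, `d`.
#' @examples
#' # duplicates at 10^-2 with 120 and 80 cfu -> 25000 cfu/carrier
#' carrier_count(c(120, 80), c(0.01, 0.01))$count_per_carrier
#' @export
carrier_count <- function(cfu, dilution_factor, plated_volume_ml = 0.4,
                          role = c("Na", "N0", "RI"),
                          limits = detection_limits()) {
  role <- match.arg(role)
  stopifnot(length(cfu) >= 1L, length(dilution_factor) == length(cfu),
            all(dilution_factor > 0), all(dilution_factor <= 1))
  if (length(plated_volume_ml) == 1L)
    plated_volume_ml <- rep(plated_volume_ml, length(cfu))
  if (length(unique(plated_volume_ml)) != 1L)
    stop("plated volume must be uniform across the plates of one eluate")
  vol <- plated_volume_ml[1L]
  stopifnot(vol > 0)

  ok <- plate_admissible(cfu)
  if (!any(ok)) {
    if (any(cfu > 330)) {
      stop("uncountable-high: no countable plate and counts above 330 cfu",
           call. = FALSE)
    }
    # every plate below the countable floor: censor at the detection limit
    if (role == "N0")
      stop("control carrier (N0) below the countable range; run invalid",
           call. = FALSE)
    return(list(count_per_carrier = 14 / vol, log10_count = limits$carrier,
                censored = TRUE, n1 = 0L, n2 = 0L, d = 1))
  }

  idx <- select_countable(dilution_factor, ok)
  d_used <- sort(unique(dilution_factor[idx]), decreasing = TRUE)
  d <- d_used[1L]
  n1 <- sum(dilution_factor[idx] == d)
  n2 <- length(idx) - n1
  cc <- sum(cfu[idx])
  N <- cc / (vol * (n1 + 0.1 * n2) * d)
  list(count_per_carrier = N, log10_count = log10(N), censored = FALSE,
       n1 = as.integer(n1), n2 = as.integer(n2), d = d)
}

#' Wash-water count per plate
#'
#' Averages the countable plates of one wash-water sample (five 2-ml
#' platings per medium): \eqn{WW = c / n} over the countable plates of
#' the direct dilution. When the sample was additionally plated from a
#' 10-fold dilution series, the least dilute level with countable plates
#' is used and the mean count is scaled back by its dilution factor
#' (`WW = c / (n d)`; `d = 1` reproduces the direct-plating formula
#' exactly). When every plate is below the countable floor (including
#' zero counts) the value is censored at the wash-water detection limit
#' (14 cfu/plate, 1.15 log10).
#'
#' @param cfu integer vector of plate counts (typically five per level).
#' @param dilution_factor dilution factor per plate; default direct (1).
#' @param limits detection-limit constants, see [detection_limits()].
#' @return list with elements `count_per_plate`, `log10_count`,
#'   `censored`, `n_plates`, `d`.
#' @examples
#' wash_water_count(c(20, 22, 18, 20, 20))  # 20 cfu/plate
#' @export
wash_water_count <- function(cfu, dilution_factor = 1,
                             limits = detection_limits()) {
  if (length(cfu) == 0L) stop("no wash-water plates supplied")
  if (length(dilution_factor) == 1L)
    dilution_factor <- rep(dilution_factor, length(cfu))
  stopifnot(length(dilution_factor) == length(cfu),
            all(dilution_factor > 0), all(dilution_factor <= 1))
  ok <- plate_admissible(cfu)
  if (!any(ok)) {
    if (any(cfu > 330))
      stop("uncountable-high: no countable wash-water plate and counts above 330 cfu",
           call. = FALSE)
    return(list(count_per_plate = 14, log10_count = limits$wash_water,
                censored = TRUE, n_plates = 0L, d = 1))
  }
  d <- max(dilution_factor[ok])
  use <- ok & dilution_factor == d
  ww <- sum(cfu[use]) / (sum(use) * d)
  list(count_per_plate = ww, log10_count = log10(ww), censored = FALSE,
       n_plates = as.integer(sum(use)), d = d)
}

#' Log reduction
#'
#' The efficacy endpoint of the carrier test: the difference of the
#' common logarithms of the control load and the post-treatment load,
#' `LR = N0 - Na`, combining inactivation and detachment. `na_log10` must
#' already be censoring-resolved (a censored Na enters at its detection
#' limit, so the LR is then a lower bound).
#'
#' @param n0_log10,na_log10 loads on the log10 scale.
#' @return numeric, the log reduction.
#' @examples
#' log_reduction(6.50, 1.54)  # 4.96
#' @export
log_reduction <- function(n0_log10, na_log10) {
  stopifnot(is.numeric(n0_log10), is.numeric(na_log10))
  n0_log10 - na_log10
}

#' Validate the control-carrier inoculum
#'
#' The method requires the dried recovery on control carriers to fall in
#' a fixed window — 6.15 to 8.15 log10 for bacteria, 5.15 to 7.15 log10
#' for yeast (both inclusive) — so that several decades of reduction
#' remain measurable above the detection limit.
#'
#' @param n0_log10 control load, log10 cfu/carrier.
#' @param organism_class `"bacteria"` or `"yeast"`.
#' @return logical.
#' @export
validate_inoculum <- function(n0_log10, organism_class = c("bacteria", "yeast")) {
  organism_class <- match.arg(organism_class)
  stopifnot(is.finite(n0_log10))
  rng <- if (organism_class == "bacteria") c(6.15, 8.15) else c(5.15, 7.15)
  n0_log10 >= rng[1L] & n0_log10 <= rng[2L]
}
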