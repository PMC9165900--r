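#' Repeatability and reproducibility variance components
#'
#' Decomposes per-endpoint measurements from several laboratories under
#' the one-way random-effects model
#' \deqn{Y_{ij} = \mu + B_i + \epsilon_{ij},\quad
#'       B_i \sim N(0, \sigma_B),\ \epsilon_{ij} \sim N(0, \sigma_r)}
#' into the between-laboratory variance \eqn{\sigma_B^2}, the
#' repeatability (within-laboratory) variance \eqn{\sigma_r^2} and the
#' reproducibility variance \eqn{\sigma_R^2 = \sigma_B^2 + \sigma_r^2}.
#'
#' Two estimators are available. `"anova_mom"` is the ISO 5725-2 ANOVA
#' method of moments: \eqn{\hat\sigma_r^2} is the within-laboratory mean
#' square and \eqn{\hat\sigma_B^2 = \max(0, (MS_B - MS_W)/n_0)} where
#' \eqn{n_0} is the per-laboratory replication (balanced) or the
#' effective replication \eqn{(N - \sum n_i^2/N)/(p-1)} (unbalanced).
#' `"reml"` maximises the restricted likelihood of the same model over
#' \eqn{\sigma_B^2 \ge 0} by profiling the variance ratio. Both report
#' the ANOVA F-test p-value for \eqn{H_0: \sigma_B^2 = 0}; a negative
#' moment estimate is truncated at zero.
#'
#' @param values numeric vector of measurements on the log10 scale.
#' @param labs laboratory identifier per measurement.
#' @param method `"anova_mom"` (default) or `"reml"`.
#' @return object of class `variance_components`: a list with
#'   `sigma2_B`, `sigma2_r`, `sigma2_R`, `S_R`, `S_r`, `method`,
#'   `p_lab_effect`, `n`, `n_labs`.
#' @examples
#' vc <- variance_components(c(0, 0, 2, 2), c("L1", "L1", "L2", "L2"))
#' vc$S_R  # sqrt(2)
#' @export
variance_components <- function(values, labs,
                                method = c("anova_mom", "reml")) {
  method <- match.arg(method)
  stopifnot(length(values) == length(labs), all(is.finite(values)))
  labs <- as.character(labs)
  ni <- table(labs)
  p <- length(ni)
  N <- length(values)
  if (p < 2L) stop("insufficient design: need at least 2 laboratories")
  if (N == p) stop("insufficient design: every laboratory is a singleton")

  zero <- function(p_val) {
    structure(list(sigma2_B = 0, sigma2_r = 0, sigma2_R = 0,
                   S_R = 0, S_r = 0, method = method,
                   p_lab_effect = p_val, n = N, n_labs = p),
              class = "variance_components")
  }
  if (stats::var(values) == 0) return(zero(1))

  lab_means <- tapply(values, labs, mean)
  grand <- mean(values)
  ss_b <- sum(ni * (lab_means - grand)^2)
  ss_w <- sum((values - lab_means[labs])^2)
  ms_b <- ss_b / (p - 1)
  ms_w <- ss_w / (N - p)
  p_val <- if (ms_w == 0) {
    if (ms_b > 0) 0 else 1
  } else {
    stats::pf(ms_b / ms_w, p - 1, N - p, lower.tail = FALSE)
  }
  n0 <- if (length(unique(ni)) == 1L) unname(ni[1L])
        else (N - sum(ni^2) / N) / (p - 1)

  if (method == "anova_mom") {
    s2r <- ms_w
    s2B <- max(0, (ms_b - ms_w) / n0)
  } else {
    est <- reml_oneway(values, labs, ni, ss_w)
    s2r <- est$sigma2_r
    s2B <- est$sigma2_B
  }
  structure(list(sigma2_B = s2B, sigma2_r = s2r, sigma2_R = s2B + s2r,
                 S_R = sqrt(s2B + s2r), S_r = sqrt(s2r), method = method,
                 p_lab_effect = unname(p_val), n = N, n_labs = p),
            class = "variance_components")
}

# Profiled one-way REML. With lambda = sigma2_B/sigma2_r, the group
# weights are u_i = n_i/(1 + n_i lambda); for fixed lambda the GLS mean
# is sum(u_i ybar_i)/sum(u_i), the residual quadratic form is
# Q(lambda) = SSW + sum u_i (ybar_i - mu)^2 and sigma2_r profiles to
# Q/(N-1), giving the criterion
#   (N-1) log Q + sum log(1 + n_i lambda) + log sum(u_i)
# (constants dropped), minimised over lambda >= 0.
reml_oneway <- function(values, labs, ni, ss_w) {
  lab_means <- tapply(values, labs, mean)
  ni <- as.numeric(ni[names(lab_means)])
  N <- length(values)
  crit <- function(lambda) {
    u <- ni / (1 + ni * lambda)
    mu <- sum(u * lab_means) / sum(u)
    Q <- ss_w + sum(u * (lab_means - mu)^2)
    (N - 1) * log(Q) + sum(log1p(ni * lambda)) + log(sum(u))
  }
  # bracket generously: lambda rarely exceeds MSB/MSW-based bounds
  upper <- 1e6
  opt <- stats::optimize(crit, c(0, upper), tol = 1e-10)
  lambda <- if (crit(0) <= opt$objective) 0 else opt$minimum
  u <- ni / (1 + ni * lambda)
  mu <- sum(u * lab_means) / sum(u)
  s2r <- (ss_w + sum(u * (lab_means - mu)^2)) / (N - 1)
  list(sigma2_r = s2r, sigma2_B = lambda * s2r)
}

#' @export
print.variance_components <- function(x, ...) {
  cat("One-way random-effects variance components (", x$method, ")\n",
      sep = "")
  cat(sprintf("  labs: %d  observations: %d\n", x$n_labs, x$n))
  cat(sprintf("  sigma2_B = %.6g  sigma2_r = %.6g  sigma2_R = %.6g\n",
              x$sigma2_B, x$sigma2_r, x$sigma2_R))
  cat(sprintf("  S_R = %.4f  S_r = %.4f  p(lab effect) = %.4g\n",
              x$S_R, x$S_r, x$p_lab_effect))
  invisible(x)
}

#' Relative standard deviation
#'
#' `RSD = 100 * S_R / mean`, the reproducibility standard deviation as a
#' percentage of the endpoint mean. Only defined for positive means (the
#' log10-scale endpoint means of this method are positive).
#'
#' @param mean endpoint mean (log10 scale), must be > 0.
#' @param s_R reproducibility standard deviation.
#' @return percentage.
#' @export
rsd <- function(mean, s_R) {
  stopifnot(is.finite(mean), is.finite(s_R), s_R >= 0)
  if (mean <= 0) stop("RSD is undefined for non-positive means")
  100 * s_R / mean
}

#' Classify the reproducibility-to-repeatability ratio
#'
#' Interlaboratory practice grades systematic between-laboratory
#' differences by the ratio `S_R / S_r`: `minor` when `S_R < 2 S_r`,
#' `clear` when `2 S_r <= S_R <= 4 S_r`, `considerable` when
#' `S_R > 4 S_r`. Degenerate cases: both zero is `minor` (no variability
#' at all); `S_r = 0` with `S_R > 0` is `considerable` (all variability
#' is between laboratories).
#'
#' @param s_R,s_r non-negative standard deviations, vectorised.
#' @return character vector in `{"minor", "clear", "considerable"}`.
#' @export
classify_ratio <- function(s_R, s_r) {
  stopifnot(all(s_R >= 0), all(s_r >= 0))
  out <- ifelse(s_r == 0,
                ifelse(s_R == 0, "minor", "considerable"),
                ifelse(s_R < 2 * s_r, "minor",
                       ifelse(s_R <= 4 * s_r, "clear", "considerable")))
  unname(out)
}

# display strings used in rendered reports (table-footnote notation)
ratio_class_labels <- c(minor = "SR<2.Sr", clear = "4.Sr>SR>2.Sr",
                        considerable = "SR>4.Sr")

#' Mean with t-based 95% confidence interval
#'
#' Arithmetic mean of all observations with the pooled t interval
#' `mean +/- t(1-(1-level)/2, n-1) * s / sqrt(n)`. A single observation
#' or a zero-variance sample collapses the interval to the mean (with a
#' warning for n = 1).
#'
#' @param values numeric vector, at least one value.
#' @param level confidence level, default 0.95.
#' @return named numeric vector `c(mean, low, high)`.
#' @export
mean_ci <- function(values, level = 0.95) {
  if (length(values) == 0L) stop("no values supplied")
  m <- mean(values)
  if (length(values) == 1L) {
    warning("single observation: confidence interval collapses to the mean")
    return(c(mean = m, low = m, high = m))
  }
  s <- stats::sd(values)
  half <- stats::qt(1 - (1 - level) / 2, length(values) - 1L) *
    s / sqrt(length(values))
  c(mean = m, low = m - half, high = m + half)
}

#' Per-endpoint precision table
#'
#' Assembles the ring-trial report: for every endpoint x condition cell
#' (nine endpoints, typically three conditions per cycle) it computes the
#' mean with its 95% confidence interval, the reproducibility and
#' repeatability standard deviations from [variance_components()], the
#' relative standard deviation and the systematic-difference class from
#' [classify_ratio()].
#'
#' @param records run records as returned by [quantify_runs()] or
#'   [simulate_endpoints()].
#' @param method variance-component estimator, see [variance_components()].
#' @return data.frame of class `precision_table` with columns `cycle`,
#'   `condition`, `endpoint`, `n`, `mean`, `ci_low`, `ci_high`, `S_R`,
#'   `S_r`, `rsd_percent`, `ratio_class`. Cells without data carry `NA`
#'   statistics.
#' @export
precision_table <- function(records, method = c("anova_mom", "reml")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(records),
            all(c(run_key_cols, "endpoint", "value") %in% names(records)))
  cells <- unique(records[c("cycle", "condition")])
  cells <- cells[order(cells$cycle, cells$condition), ]
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- records[records$cycle == cells$cycle[i] &
                      records$condition == cells$condition[i], ]
    for (ep in endpoint_names()) {
      sub <- cell[cell$endpoint == ep & !is.na(cell$value), ]
      row <- data.frame(cycle = cells$cycle[i], condition = cells$condition[i],
                        endpoint = ep, n = nrow(sub), mean = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, S_R = NA_real_,
                        S_r = NA_real_, rsd_percent = NA_real_,
                        ratio_class = NA_character_)
      if (nrow(sub) == 0L) {
        warning("no data for endpoint ", ep, " in condition ",
                cells$condition[i], call. = FALSE)
      } else {
        ci <- mean_ci(sub$value)
        vc <- variance_components(sub$value, sub$lab_id, method)
        row$mean <- ci[["mean"]]
        row$ci_low <- ci[["low"]]
        row$ci_high <- ci[["high"]]
        row$S_R <- vc$S_R
        row$S_r <- vc$S_r
        row$rsd_percent <- if (ci[["mean"]] > 0) rsd(ci[["mean"]], vc$S_R)
                           else NA_real_
        row$ratio_class <- classify_ratio(vc$S_R, vc$S_r)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("precision_table", "data.frame")
  out
}

#' @export
print.precision_table <- function(x, ...) {
  cat("Ring-trial precision table:", nrow(x), "endpoint x condition rows\n")
  df <- as.data.frame(x)
  num <- c("mean", "ci_low", "ci_high", "S_R", "S_r", "rsd_percent")
  df[num] <- lapply(df[num], round, digits = 2)
  print(df, row.names = FALSE, ...)
  invisible(x)
}
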