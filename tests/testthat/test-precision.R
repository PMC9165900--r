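test_that("variance components reproduce a hand one-way ANOVA", {
  # 2 labs x 2 runs, all variability between labs
  vc <- variance_components(c(0, 0, 2, 2), c("L1", "L1", "L2", "L2"))
  expect_equal(vc$sigma2_B, 2)
  expect_equal(vc$sigma2_r, 0)
  expect_equal(vc$S_R, sqrt(2))
  expect_equal(vc$S_r, 0)

  # degenerate: identical values give all-zero components, p = 1
  vc <- variance_components(rep(1.15, 9), rep(c("L1", "L2", "L3"), each = 3))
  expect_equal(c(vc$sigma2_B, vc$sigma2_r, vc$sigma2_R), c(0, 0, 0))
  expect_equal(vc$p_lab_effect, 1)

  expect_error(variance_components(1:4, rep("L1", 4)), "2 laboratories")
  expect_error(variance_components(1:3, c("L1", "L2", "L3")), "singleton")
})

test_that("moment estimator equals the sums-of-squares oracle, balanced and not", {
  withr::with_seed(101, {
    for (i in 1:25) {
      p <- sample(3:8, 1)
      ni <- if (i %% 2) rep(sample(2:4, 1), p) else sample(2:5, p, replace = TRUE)
      lab <- rep(sprintf("L%d", 1:p), ni)
      y <- rnorm(p, 2, 0.6)[rep(1:p, ni)] + rnorm(sum(ni), 0, 0.3)
      vc <- variance_components(y, lab, "anova_mom")
      or <- oracle_oneway(y, lab)
      expect_equal(vc$sigma2_r, or$sigma2_r, tolerance = 1e-12)
      expect_equal(vc$sigma2_B, or$sigma2_B, tolerance = 1e-12)
      # exact additivity and ordering hold for every draw
      expect_identical(vc$sigma2_R, vc$sigma2_B + vc$sigma2_r)
      expect_gte(vc$S_R, vc$S_r)
    }
  })
})

test_that("REML matches the moment estimator on balanced data and lme4 generally", {
  skip_if_not_installed("lme4")
  withr::with_seed(202, {
    for (i in 1:10) {
      d <- draw_trial(p = 6, n = 3)
      mom <- variance_components(d$y, d$lab, "anova_mom")
      reml <- variance_components(d$y, d$lab, "reml")
      if (mom$sigma2_B > 0) {
        expect_equal(reml$sigma2_B, mom$sigma2_B, tolerance = 1e-6)
        expect_equal(reml$sigma2_r, mom$sigma2_r, tolerance = 1e-6)
      }
    }
    # unbalanced: agree with lme4's REML fit
    ni <- c(2, 3, 4, 2, 5)
    lab <- rep(sprintf("L%d", 1:5), ni)
    y <- rnorm(5, 3, 0.5)[rep(1:5, ni)] + rnorm(sum(ni), 0, 0.25)
    mine <- variance_components(y, lab, "reml")
    fit <- lme4::lmer(y ~ 1 + (1 | lab), REML = TRUE)
    v <- as.data.frame(lme4::VarCorr(fit))$vcov
    expect_equal(mine$sigma2_B, v[1], tolerance = 1e-5)
    expect_equal(mine$sigma2_r, v[2], tolerance = 1e-5)
  })
})

test_that("estimators recover simulated variance components in expectation", {
  withr::with_seed(303, {
    est <- replicate(200, {
      d <- draw_trial(p = 3, n = 3, sigma_B = 0.5, sigma_r = 0.3)
      vc <- variance_components(d$y, d$lab)
      c(vc$sigma2_B, vc$sigma2_r)
    })
    # medians near truth (small-sample medians of chi-square-ish spreads)
    expect_equal(median(est[2, ]), 0.09, tolerance = 0.35)
    expect_gt(median(est[1, ]), 0.05)
  })
})

test_that("relative standard deviation follows 100 * S_R / mean", {
  expect_equal(rsd(1.15, 0), 0)
  expect_equal(rsd(2, 0.5), 25)
  expect_equal(rsd(4.58, 0.61), 13.32, tolerance = 1e-3)
  expect_error(rsd(0, 0.5))
  expect_error(rsd(-1, 0.5))
})

test_that("ratio classification uses the 2x / 4x boundaries", {
  expect_equal(classify_ratio(0.61, 0.26), "clear")
  expect_equal(classify_ratio(0.38, 0.04), "considerable")
  expect_equal(classify_ratio(0.00, 0.00), "minor")
  expect_equal(classify_ratio(0.5, 0), "considerable")
  # ties on either boundary land in the middle class
  expect_equal(classify_ratio(0.8, 0.4), "clear")
  expect_equal(classify_ratio(1.6, 0.4), "clear")
  expect_error(classify_ratio(-0.1, 0.1))
  # scale invariance
  withr::with_seed(7, {
    sR <- runif(50, 0, 2); sr <- runif(50, 0, 1)
    for (k in c(0.01, 3, 1000)) {
      expect_identical(classify_ratio(k * sR, k * sr), classify_ratio(sR, sr))
    }
  })
})

test_that("t-based confidence intervals match the closed form", {
  ci <- mean_ci(c(1, 2, 3))
  expect_equal(ci[["mean"]], 2)
  expect_equal(ci[["high"]] - ci[["mean"]], qt(0.975, 2) / sqrt(3))
  expect_equal(mean_ci(rep(1.15, 9)), c(mean = 1.15, low = 1.15, high = 1.15))
  expect_warning(ci1 <- mean_ci(5), "single")
  expect_equal(ci1, c(mean = 5, low = 5, high = 5))
  expect_error(mean_ci(numeric(0)))
})

test_that("precision tables assemble one row per endpoint and condition", {
  cfg <- sim_config("main_wash", sigma_B = 0, sigma_r = 0, seed = 5,
                    poisson_layer = FALSE)
  rec <- simulate_endpoints(cfg)
  pt <- precision_table(rec)
  expect_s3_class(pt, "precision_table")
  expect_equal(nrow(pt), 27)  # 9 endpoints x 3 conditions
  expect_equal(unique(pt$n), 21)  # 7 labs x 3 runs per cell
  # noiseless input: zero spread, minor class everywhere, mean = mu
  expect_true(all(pt$S_R == 0))
  expect_true(all(pt$S_r == 0))
  expect_true(all(pt$ratio_class == "minor"))
  # cells untouched by detection-limit censoring recover mu exactly
  cens <- aggregate(censored ~ condition + endpoint, rec, any)
  names(cens)[3] <- "any_censored"
  mu <- default_endpoint_means("main_wash")
  m <- merge(merge(as.data.frame(pt), mu, by = c("condition", "endpoint")),
             cens, by = c("condition", "endpoint"))
  expect_true(any(m$any_censored))      # the low-Na cells do pile up
  m <- m[!m$any_censored, ]
  expect_gt(nrow(m), 15)
  expect_equal(m$mean, m$mu)
})

test_that("balanced noisy designs without lab effects stay in the minor class", {
  cfg <- sim_config("main_wash", sigma_B = 0, sigma_r = 0.3, seed = 31,
                    n_labs = 12, n_runs = 6, poisson_layer = FALSE)
  pt <- precision_table(simulate_endpoints(cfg))
  ok <- !is.na(pt$ratio_class) & pt$S_r > 0
  expect_gt(mean(pt$ratio_class[ok] == "minor"), 0.85)
  expect_true(all(pt$S_R[ok] >= pt$S_r[ok]))
})
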