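test_that("the countable window is 14-330 cfu, inclusive", {
  expect_equal(plate_admissible(c(0, 13, 14, 200, 330, 331)),
               c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_error(plate_admissible(-1))
  expect_error(plate_admissible(2.5))
})

test_that("dilution-weighted carrier counts match hand-evaluated cases", {
  # duplicates at one dilution
  q <- carrier_count(c(120, 80), c(0.01, 0.01))
  expect_equal(q$count_per_carrier, 25000)
  expect_equal(q$n1, 2L)
  expect_equal(q$n2, 0L)
  expect_false(q$censored)

  # duplicates at two consecutive dilutions, weighted 1 + 0.1
  q <- carrier_count(c(300, 280, 30, 28), c(0.1, 0.1, 0.01, 0.01))
  expect_equal(q$count_per_carrier, 638 / (0.4 * 2.2 * 0.1))
  expect_equal(q$count_per_carrier, 7250)
  expect_equal(c(q$n1, q$n2), c(2L, 2L))
  expect_equal(q$d, 0.1)

  # only the more dilute level countable: it becomes the sole dilution
  q <- carrier_count(c(600, 590, 60, 59), c(0.1, 0.1, 0.01, 0.01))
  expect_equal(q$count_per_carrier, 119 / (0.4 * 2 * 0.01))
  expect_equal(c(q$n1, q$n2), c(2L, 0L))
})

test_that("carrier quantification censors at 1.54 and errors when uncountable", {
  # direct duplicates at the floor count are countable and sit at the limit
  q <- carrier_count(c(14, 14), c(1, 1))
  expect_equal(q$count_per_carrier, 35)
  expect_equal(round(q$log10_count, 2), 1.54)
  expect_false(q$censored)

  # everything below the floor: censored at the bit-exact constant
  q <- carrier_count(c(5, 0), c(1, 1))
  expect_true(q$censored)
  expect_identical(q$log10_count, 1.54)
  expect_equal(q$count_per_carrier, 35)

  expect_error(carrier_count(c(400, 500), c(0.01, 0.01)), "uncountable-high")
  expect_error(carrier_count(c(200, 20), c(0.1, 0.001)), "non-consecutive")
  expect_error(carrier_count(c(5, 3), c(1, 1), role = "N0"))
})

test_that("wash-water counts average countable plates and censor at 1.15", {
  q <- wash_water_count(c(20, 22, 18, 20, 20))
  expect_equal(q$count_per_plate, 20)
  expect_equal(q$log10_count, log10(20))

  q <- wash_water_count(rep(14, 5))
  expect_equal(q$count_per_plate, 14)
  expect_equal(round(q$log10_count, 2), 1.15)
  expect_false(q$censored)

  q <- wash_water_count(rep(0, 5))
  expect_true(q$censored)
  expect_identical(q$log10_count, 1.15)

  # partial admissibility: only countable plates enter the mean
  q <- wash_water_count(c(10, 20, 30, 400, 20))
  expect_equal(q$count_per_plate, 70 / 3)

  # diluted plating scales back by the dilution factor
  q <- wash_water_count(c(100, 110, 90, 100, 100), 0.01)
  expect_equal(q$count_per_plate, 10000)

  expect_error(wash_water_count(integer(0)))
  expect_error(wash_water_count(rep(500L, 5)), "uncountable-high")
})

test_that("detection-limit substitution is role-specific and bit-exact", {
  expect_identical(apply_detection_limit(NA, "Na"),
                   list(log10 = 1.54, censored = TRUE))
  expect_identical(apply_detection_limit(NA, "WW"),
                   list(log10 = 1.15, censored = TRUE))
  expect_identical(apply_detection_limit(3.20, "RI"),
                   list(log10 = 3.20, censored = FALSE))
  expect_identical(apply_detection_limit(1.0, "RI"),
                   list(log10 = 1.54, censored = TRUE))
  expect_error(apply_detection_limit(1.0, "N0"))
  # configurable constants follow other plated volumes
  lim <- detection_limits(carrier = 2.0, wash_water = 0.5)
  expect_identical(apply_detection_limit(NA, "Na", lim)$log10, 2.0)
})

test_that("log reduction subtracts censoring-resolved Na from N0", {
  expect_equal(log_reduction(6.50, 1.54), 4.96)
  expect_equal(log_reduction(7.00, 2.00), 5.00)
  expect_equal(log_reduction(3.3, 3.3), 0)
  # monotone in N0 with a censored Na
  na <- apply_detection_limit(NA, "Na")$log10
  a <- seq(2, 8, by = 0.25)
  expect_true(all(diff(log_reduction(a, na)) > 0))
})

test_that("inoculum validity windows are organism-specific and inclusive", {
  expect_true(validate_inoculum(6.15, "bacteria"))
  expect_true(validate_inoculum(8.15, "bacteria"))
  expect_false(validate_inoculum(9.0, "bacteria"))
  expect_false(validate_inoculum(5.00, "yeast"))
  expect_true(validate_inoculum(5.15, "yeast"))
  expect_false(validate_inoculum(7.2, "yeast"))
})

test_that("carrier counts are linear in counts and inverse in dilution", {
  withr::with_seed(11, {
    for (i in 1:20) {
      n_pl <- sample(1:2, 1)
      cfu <- sample(14:110, n_pl, replace = TRUE)
      d <- sample(c(1, 0.1, 0.01), 1)
      base <- carrier_count(cfu, rep(d, n_pl))$count_per_carrier
      # degree-1 homogeneity in the counts (keep scaled counts in-window)
      expect_equal(carrier_count(cfu * 3L, rep(d, n_pl))$count_per_carrier,
                   3 * base)
      # inverse proportionality to the dilution factor
      expect_equal(carrier_count(cfu, rep(d / 10, n_pl))$count_per_carrier,
                   10 * base)
    }
  })
})

test_that("noiseless plates invert exactly for any admissible configuration", {
  for (C in c(100, 3500, 82000, 6e5)) {
    for (d in c(1, 0.1, 0.01, 1e-3)) {
      cnt <- C * 0.4 * d
      if (cnt < 14 || cnt > 330 || cnt != round(cnt)) next
      expect_equal(carrier_count(rep(cnt, 2), rep(d, 2))$count_per_carrier, C)
    }
  }
})
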