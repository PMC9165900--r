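# Independent oracles used across tests. These deliberately avoid the
# package's code paths: plain double loops over first-principles formulas.

# One-way ANOVA variance components from explicit sums of squares.
oracle_oneway <- function(y, lab) {
  labs <- unique(lab)
  p <- length(labs)
  N <- length(y)
  grand <- sum(y) / N
  ss_b <- 0; ss_w <- 0; sum_ni2 <- 0
  for (l in labs) {
    yi <- y[lab == l]
    ni <- length(yi)
    mi <- sum(yi) / ni
    ss_b <- ss_b + ni * (mi - grand)^2
    for (v in yi) ss_w <- ss_w + (v - mi)^2
    sum_ni2 <- sum_ni2 + ni^2
  }
  ms_b <- ss_b / (p - 1)
  ms_w <- ss_w / (N - p)
  ni_all <- table(lab)
  n0 <- if (length(unique(ni_all)) == 1) ni_all[[1]] else
    (N - sum_ni2 / N) / (p - 1)
  list(sigma2_r = ms_w, sigma2_B = max(0, (ms_b - ms_w) / n0),
       ms_b = ms_b, ms_w = ms_w)
}

# Balanced lab x run dataset drawn from the one-way random model.
draw_trial <- function(p, n, mu = 3, sigma_B = 0.5, sigma_r = 0.3) {
  lab <- rep(sprintf("L%d", seq_len(p)), each = n)
  b <- rnorm(p, 0, sigma_B)
  data.frame(lab = lab, y = mu + b[rep(seq_len(p), each = n)] +
               rnorm(p * n, 0, sigma_r))
}

# Minimal hand-built plate table for one run covering all nine endpoints.
# Counts are chosen so quantification has a closed-form expected value.
toy_run_plates <- function(lab_id = "L1", condition = "A", run_index = 1) {
  rows <- list()
  add <- function(role, strain, medium, carrier, d, vol, cfu) {
    rows[[length(rows) + 1]] <<- data.frame(
      lab_id = lab_id, cycle = "main_wash", condition = condition,
      run_index = run_index, strain = strain, medium = medium, role = role,
      carrier = carrier, dilution_factor = d, plated_volume_ml = vol,
      cfu = cfu)
  }
  for (st in c("PA", "EC", "SA", "EH", "CA")) {
    med <- if (st == "CA") "MEA" else "TSA"
    # N0: duplicates at 1e-4 with 100 cfu -> 2.5e6/carrier (log10 6.39794)
    add("N0", st, med, 1L, 1e-4, 0.4, c(100, 100))
    # Na: duplicates direct 40 cfu -> 100/carrier (log10 2)
    add("Na", st, med, 1L, 1, 0.4, c(40, 40))
  }
  for (med in c("TSA", "MEA")) {
    # RI: duplicates at 1e-1, 80 cfu -> 2000/carrier (log10 3.30103)
    add("RI", "", med, 1L, 0.1, 0.4, c(80, 80))
    add("WW", "", med, 1L, 1, 2, c(20, 22, 18, 20, 20))  # 20/plate
  }
  do.call(rbind, rows)
}
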