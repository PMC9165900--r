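---
title: "Interlaboratory precision analysis for quantitative laundering carrier tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interlaboratory precision analysis for quantitative laundering carrier tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringtrial)
```

## The measurement problem

Quantitative carrier tests for laundry disinfection, such as the
prEN 17658 laboratory-scale method, measure how many viable
microorganisms survive a simulated wash. Cotton carriers inoculated with
one of five reference strains (*P. aeruginosa*, *E. coli*, *S. aureus*,
*E. hirae*, *C. albicans*) are laundered in a closed canister; the
surviving load on treated carriers (Na), the cross-contamination of
initially sterile carriers (RI) and the transfer to the wash water (WW)
are recovered and counted on agar (TSA for bacteria, MEA for yeast). Each
laboratory × condition × run therefore yields nine log10-scale endpoints:
five log reductions LR = N0 − Na (one per strain), RI per medium and WW
per medium.

Before a method becomes a standard, a ring trial must show that different
laboratories, running the same protocol on the same materials, agree. This
package implements the complete data pathway of such a trial: plate-count
quantification with censoring, per-endpoint precision statistics under the
one-way random-effects model, Cochran/Grubbs outlier screening with
re-analysis, and a synthetic trial generator that stands in for the raw
laboratory spreadsheets (which were never deposited for the original
study).

## From plates to endpoints

**Countable window.** Plates with fewer than 14 or more than 330 cfu are
discarded (`plate_admissible()`): sparse plates are dominated by counting
noise, crowded plates undercount merged colonies. Whether the 2-ml
wash-water plates share the same window is not stated by the method; the
package assumes they do.

**Dilution-weighted carrier counts.** Carrier eluates are plated in
duplicate 0.4-ml samples across a 10-fold dilution series. The countable
plates of at most two consecutive dilutions are pooled as

$$N = \frac{c}{V\,(n_1 + 0.1\,n_2)\,d}$$

with $c$ the summed count, $n_1, n_2$ the numbers of countable plates at
the lower (less dilute, factor $d$) and higher dilution, and $V = 0.4$ ml
(`carrier_count()`). When only the more dilute level is countable it is
treated as the sole dilution — the $0.1 n_2$ weight only makes sense
relative to a countable lower level. Wash water is plated on five 2-ml
plates and averaged per plate, $WW = c/n$ (`wash_water_count()`); the
implementation optionally scales by a dilution factor ($WW = c/(nd)$,
direct plating $d = 1$ reproducing the per-plate formula exactly) because
recoveries of 4–5 log10 per plate, which the method does produce in water
controls, are uncountable undiluted.

**Censoring.** When every plate sits below the countable floor, the value
is recorded at a fixed detection-limit constant: 1.54 log10 for carrier
counts (14 cfu on a direct 0.4-ml plate ≙ 35 cfu/carrier) and 1.15 log10
for wash water (14 cfu/plate). These constants are configuration values
(`detection_limits()`) so other plated volumes remain usable; the defaults
reproduce the standard's values, and censored outputs carry them
bit-exactly. Log reductions are then computed against the censored Na, so
a censored LR is a lower bound. An *uncountably high* carrier (all plates
above 330) is an error, not a censoring — there is no defensible upper
substitute value. When some plates are below 14 and others above 330 with
none countable, the package also errors (the high plates dominate the
ambiguity). Control carriers (N0) are never censored; an uncountable
control invalidates the run, and `validate_inoculum()` checks the required
recovery windows (6.15–8.15 log10 for bacteria, 5.15–7.15 for yeast).

**Carrier replication.** The canister layout provides one contaminated
carrier per strain plus sterile carriers for RI; control counts are run in
triplicate. Where several carriers contribute to one endpoint in one run,
their log10 counts are averaged *before* the LR subtraction — the
reporting convention is one value per endpoint per run, and averaging on
the log scale keeps the LR a difference of log-means.

## Precision model

Each endpoint × condition cell is analysed under the one-way
random-effects model

$$Y_{ij} = \mu + B_i + \varepsilon_{ij}, \qquad
  B_i \sim N(0, \sigma_B), \quad \varepsilon_{ij} \sim N(0, \sigma_r),$$

with laboratory effects $B_i$ independent of the run noise. The
repeatability variance is $\sigma_r^2$, the reproducibility variance
$\sigma_R^2 = \sigma_B^2 + \sigma_r^2$ (an identity the package asserts
exactly), and the reported statistics are $S_R = \hat\sigma_R$,
$S_r = \hat\sigma_r$, the relative standard deviation
$RSD = 100\,S_R/\text{mean}$ and the systematic-difference class of
$S_R/S_r$: *minor* below 2, *clear* between 2 and 4, *considerable* above
4. Boundary ties land in the middle class (the footnote inequalities are
strict on both sides, leaving ties undefined); $S_r = 0$ with $S_R > 0$
is *considerable* (all variability between laboratories) and the fully
degenerate $S_R = S_r = 0$ is *minor*.

Two estimators are provided (`variance_components()`):

* **`anova_mom`** — the ISO 5725-2 ANOVA method of moments:
  $\hat\sigma_r^2 = MS_W$ and
  $\hat\sigma_B^2 = \max(0, (MS_B - MS_W)/n_0)$. Balanced designs use
  $n_0 = n$; unbalanced panels (one laboratory could not run the rinse
  cycle) use the effective replication
  $n_0 = (N - \sum_i n_i^2/N)/(p-1)$.
* **`reml`** — restricted maximum likelihood of the same model, computed
  by profiling both $\mu$ and $\sigma_r^2$ out of the restricted
  likelihood and minimising a one-dimensional criterion in the variance
  ratio $\lambda = \sigma_B^2/\sigma_r^2$ over $[0, \infty)$ (bounded
  scalar optimisation, tolerance 1e-10). On balanced data with a strictly
  positive moment estimate the two estimators coincide; the test suite
  verifies both this identity and agreement with an independent
  mixed-model fit.

Both report the ANOVA F-test p-value for $H_0: \sigma_B^2 = 0$. The
negative-moment case is truncated at zero regardless of the test outcome
— reporting the p-value but always truncating subsumes the test-gated
rule and keeps $\sigma_R^2 \ge \sigma_r^2$. Confidence intervals for the
cell mean are pooled-observation t intervals,
$\bar y \pm t_{0.975, n-1} s/\sqrt n$; the source report does not state
its interval construction, so no result is made to depend on interval
agreement beyond the degenerate all-constant case, where any construction
collapses to the mean.

## Outlier screening

Per cell, the Cochran test screens the per-laboratory variances,
$C = \max_i s_i^2 / \sum_i s_i^2$, against the exact critical value

$$C_{crit} = \Big[1 + \frac{p-1}{F_{1-\alpha/p}(n-1,\,(p-1)(n-1))}\Big]^{-1},$$

which reproduces the classical printed tables (0.8709 at $p = 3$,
$n = 3$, $\alpha = 0.05$) and is cross-checked in the tests against a
Monte-Carlo regeneration. Unequal replication uses the critical value at
the largest $n$ (the permissive choice), with a note. The two-sided
single-outlier Grubbs test, $G = \max_i |x_i - \bar x|/s$ with critical
value $\frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$, $t = t_{1-\alpha/(2n),
n-2}$, screens the pooled observations.

`screen_and_reanalyze()` applies Cochran first (removing the flagged
laboratory's runs for that cell), then Grubbs (removing at most one
observation per pass), for at most two passes, then recomputes the
precision table — mirroring the flag-remove-reanalyse cycle of
collaborative studies. Both tests default to $\alpha = 0.05$; the
standard's convention of 5% stragglers / 1% outliers is available by
passing a different `alpha`. Removal never proceeds when fewer than two
laboratories would remain. With triplicate runs the Cochran test has
limited power (variance estimates on 2 degrees of freedom): at 5-fold
within-laboratory inflation its flag rate is roughly 65–75%, reaching
\>90% only from about five replicates — a design property worth knowing
when interpreting a clean screening report.

## The synthetic ring trial

`sim_config()` encodes the study design: 7 laboratories × 3 conditions
(A water, B detergent, C detergent + oxygen-bleach disinfectant) × 3 runs
for the main wash, 6 laboratories × 3 conditions (D water, E 0.04% DDAC,
F 0.4% DDAC) × 3 runs for the rinse cycle — 63 and 54 run blocks. Default
endpoint means are the reported per-condition means, so synthetic tables
are visually comparable with published ones (presets, not ground truth);
the condition-F wash-water means are set below the detection limit so the
generator reproduces the complete censoring pile-up (all values exactly
1.15, $S_R = S_r = RSD = 0$) that the efficacious rinse dose shows.
Default components $\sigma_B = 0.4$, $\sigma_r = 0.35$ sit mid-range of
the reported $S_R$/$S_r$ values. Lab effects are drawn independently per
endpoint (the shared-per-lab alternative is a config switch for
sensitivity work). Censoring is applied to the Na/RI/WW *levels*, never
to LR directly; LR is then N0 − Na as in the analysis pathway.

`simulate_plate_counts()` adds the counting layer: expected count
$\lambda = 10^y \cdot 0.4 \cdot d$ per carrier plate (dilution series 1
to $10^{-4}$, duplicates) and $10^y d$ per 2-ml wash-water plate (five
plates per level), with Poisson draws or rounded expectations
(`poisson_layer = FALSE`). Control inocula default to 6.5 log10
(bacteria) and 5.5 (yeast): inside the method's validity windows and, at
0.4 ml, countable within the default series, whose upper countable load
is about 6.9 log10. Dilutions implying more than $10^6$ expected cfu are
skipped as uncountable anyway.

What the generator deliberately does *not* emulate: device effects
confounded with laboratories, run-order or day effects, non-normal lab
effects, cross-endpoint correlation (beyond the optional shared lab
effect) and plate-to-plate overdispersion beyond Poisson. Passing tests
therefore validate the *computational pathway* under the stated model,
not the field behaviour of any laboratory.

## Numerical notes and limitations

* **Count quantization.** Integer plate counts below 22 cfu quantize the
  log10 scale coarser than 0.01 ($\log_{10}(1 + 0.5/21) \approx 0.0102$),
  and such counts occur only on direct platings in the band just above
  the 14-cfu floor (a countable level with a countable 10× less dilute
  neighbour always yields ≥ 33 cfu). Round-trip recovery to 0.01 log10 is
  therefore asserted only for loads at least 0.2 log10 above the
  censoring floor; nearer the floor the limit value itself is recovered
  to within 0.01 by construction.
* **Rounding.** All statistics are computed at full precision; report
  rendering (`render_precision_csv()`) rounds to 2 decimals, class shares
  to 1 decimal and the RSD share to an integer. Published tables rounded
  the same way, which is why printed RSD or ratio-class entries can
  disagree with values recomputed from the printed (rounded) $S_R$, $S_r$
  and means; transcriptions are kept verbatim and never forced into
  consistency — including one printed row where rounding makes
  $S_R < S_r$.
* **Degenerate cells.** All-identical observations return all-zero
  components with the lab-effect p-value reported as 1; zero-variance
  samples make Grubbs undefined (an error) and all-zero variances make
  Cochran undefined (no flag, with a note).
* **REML at the boundary.** With zero within-laboratory scatter the
  restricted likelihood degenerates; the profiled optimiser then returns
  the boundary fit. The moment estimator is the default and the estimator
  used for reported tables.
* **Problem sizes.** The simulation-based tests use the trial's own
  design (7 × 3, and 200 replicates for parameter recovery, 500 for
  false-positive rates) plus one 50-laboratory × 50-run dataset for the
  variance-decomposition identity; these sizes make the Monte-Carlo error
  small relative to the asserted tolerances while keeping the suite fast.

## A worked pass through the pipeline

```{r}
cfg <- sim_config("main_wash", seed = 42)
res <- run_pipeline(cfg)
head(as.data.frame(res$precision), 3)
res$summary
```

The summary block reports the share of endpoint × condition comparisons
per systematic-difference class, the share of determinations strictly
below 30% RSD, and the largest RSD, $S_R$ and $S_r$ — the headline
robustness numbers of a ring-trial report. `reported_precision()` ships
the published 54-row precision table of the prEN 17658 trial as a
transcription fixture; feeding it to `summarize_precision()` reproduces
the published cross-table percentages (74.1% minor, 24.1% clear, one
considerable comparison, 63% below 30% RSD).
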