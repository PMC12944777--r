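---
title: "Choosing AI rule-out thresholds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing AI rule-out thresholds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruleout)
```

## The error-accounting model

A rule-out policy with threshold $t$ removes every exam with AI score
$s \le t$ from the reading worklist. For exam-level data carrying the
triple (score, standard-practice recall, cancer outcome), each threshold
induces eight cells: the ruled-out arm splits into $B, C, D, E$ and the
retained arm into $G, H, I, J$ by (recall, cancer), with totals
$F = B{+}C{+}D{+}E$, $K = G{+}H{+}I{+}J$, $N = F{+}K$.

The framework's central quantities are conditional *omission* rates in
the ruled-out arm rather than population false-negative rates, because
they answer the operational question "if we stop reading these exams,
what fraction of them carries a cancer we will now miss?":

* gross: $\mathrm{GFOR}(t) = (C+E)/F$;
* net: $\mathrm{NFOR}(t) = E/F$, deducting cell $C$ — interval cancers
  the radiologist missed in standard practice too, which rule-out does
  not cause;
* adjusted net: $\mathrm{ANFOR}_f(t) = (E - f\,H)/F$, crediting a
  scenario fraction $f$ of cell $H$ — cancers the radiologist missed in
  standard practice but might catch when the retained pool is smaller,
  prevalence-enriched, and known to be triaged.

$\mathrm{ANFOR}_f$ is deliberately signed: a negative value means the
policy is expected to *reduce* total missed cancers relative to standard
practice. The benefit axis is the caseload reduction rate
$\mathrm{CRR}(t) = F/N$, and the retained-side cost is tracked by
$\mathrm{FDR}(t) = (G+I)/K$; in sub-1% prevalence screening the FDR
stays in the high 90s at every threshold, so the false-negative side
dominates the trade-off.

Key modelling assumptions, inherited from the data the framework is
designed for: exams are exchangeable (no per-patient clustering), the
recall flag reflects radiologist behaviour *without* triage, the cancer
flag is a complete outcome within a fixed follow-up window, and the
scenario fraction $f$ is a hypothetical — the package evaluates a grid
of scenarios (default 10/30/50/70%) rather than asserting any of them.

## Threshold selection

Two policies are implemented.

**Youden's J.** `select_youden()` maximises
$J(t) = \text{sensitivity}(t) + \text{specificity}(t) - 1$, treating
"retained" as test-positive. Candidates default to all distinct observed
scores — every achievable empirical operating point — rather than a
rounded grid, because grid-level counts can peak at a neighbouring grid
point when the underlying optimum lies between grid lines; a
grid-restricted mode exists for fixture work, and the full $J$ profile
is always returned as a diagnostic. Ties break toward the smaller
threshold, the conservative side (fewer exams ruled out).

**Adjusted-net zero.** `select_anfor_zero()` returns the *largest* grid
threshold with $\mathrm{ANFOR}_f(t) \le$ target (default 0): the most
caseload reduction available without a net increase in missed cancers
under scenario $f$. The selected row and its successor are reported as
a bracket, so a user can see the sign change. A grid on which no row
qualifies yields a flagged no-crossing result, not an error: with small
$f$ and an informative score the adjusted rate can be positive
everywhere.

## Numerical conventions

* **Tie at the threshold.** A score exactly equal to the threshold is
  ruled out ($s \le t$). This matters for grid-valued fixtures where
  scores sit exactly on grid lines.
* **Undefined metrics.** At thresholds where an arm is empty
  ($F = 0$ or $K = 0$) the affected rates are `NA_real_`, carried
  through sweeps and rendered blank by the CSV writer — never zero and
  never an exception.
* **Rounding.** Reported percentages round half *away from zero* to two
  decimals (`round_half_up()`), the convention of the clinical tables
  this framework interoperates with; base R's round-half-to-even
  disagrees exactly on the boundary cases. Internal computation is full
  double precision.
* **Clamping.** Signed adjusted-net values flow into sweep tables and
  curves; only the headline count `net_missed_count(..., clamp = TRUE)`
  floors at zero, since "−9 missed cancers" is reported as "no
  additional missed cancers".
* **Bootstrap quantiles.** Percentile intervals use inclusive linear
  interpolation between order statistics (R `quantile` type 7), stated
  here so bands are bit-reproducible across platforms given the seed.
  Replicates in which a metric is undefined at a threshold are dropped
  from that cell's percentiles and counted in `n_defined`.

## Reconstructing cohorts from published cell tables

Because ruled-out cells are cumulative in the threshold, a published
per-threshold cell table determines an exam-level cohort up to the exact
score values. `cohort_from_cells()` realises each cell increment between
consecutive thresholds as records scored at the bin's upper threshold
and the final retained cells as records above the last threshold;
`stratify()` on the result reproduces the printed table exactly. The
packaged `reference_sweep_counts()` table (a 114,229-exam screening
cohort with 864 cancers) is shipped in this form and doubles as the
package's golden fixture: all 84 complete rows of its printed derived
columns recompute exactly under the stated rounding rule.

## The synthetic generator

`simulate_cohort()` draws independent exams: cancer
$\sim\mathrm{Bernoulli}(p)$ with default $p = 0.0076$; scores from
class-conditional Beta distributions (support $[0,1]$ matches risk
scores); recall $\sim\mathrm{Bernoulli}$ with class rates — default
0.081 for non-cancers (the screening recall / false-positive rate) and
0.829 for cancers (radiologist detection). Default Beta shapes —
non-cancer $(0.62, 3.78)$, cancer $(0.90, 1.05)$ — were fit once by
least squares so the class CDFs at thresholds 0.05/0.20/0.50
qualitatively match the reference cohort's profile (about 36%/75% of
non-cancers below 0.05/0.20, about 26% of cancers below 0.20); they are
a modelling choice, not a claim about any particular AI model's score
distribution.

An optional per-class log-odds slope couples recall to the score,
$\Pr(\text{recall}) = \mathrm{logit}^{-1}(\mathrm{logit}(r) +
\beta\,(s - \bar s))$, reproducing the empirical phenomenon that
low-score cancers are disproportionately the radiologist-missed ones.
The slope defaults to 0 (independence) because that is the regime with
closed-form expectations: `expected_metrics()` gives analytic
sensitivity/specificity from the Beta tails, $\mathrm{GFOR}$ via Bayes'
theorem, $\mathrm{NFOR} = d \cdot \mathrm{GFOR}$ for detection rate
$d$, and the adjusted family from the same components. These closed
forms are the oracle for the simulator's parameter-recovery tests.

Recalled non-cancers receive biopsy labels (benign 10%, high-risk 2%,
else none — typical screening work-up proportions) and cancers a
malignant label, enabling the avoided-biopsy tally; simulated cancers
are invasive with probability 0.8.

What the generator does *not* emulate: per-patient correlation across
rounds, age/density covariate structure, drift in technology or
prevalence over an accrual period, and any dependence of the scenario
fraction $f$ on the threshold. Tests passing on synthetic cohorts
therefore validate the estimators and their algebra, not the clinical
transportability of any particular operating point.

## Uncertainty

`bootstrap_bands()` resamples exam records with replacement at cohort
size (the resampling unit is the exam, matching the exchangeability
assumption), recomputes the entire sweep per replicate, and forms
percentile bands; 1000 replicates is the default, and the point
estimate, replicate dispersion, and defined-replicate count accompany
every (threshold, metric) cell. Percentile intervals were chosen over
BCa deliberately: they are the plainest method consistent with a
generic survey-resampling workflow, and the method name is recorded in
the output attributes so downstream consumers know what they are
plotting. For very rare events (a handful of ruled-out cancers) the
percentile band inherits the discreteness of the count and its coverage
is only approximately nominal — the package's coverage test sizes this
at roughly nine expected events and nominal 95%.

## Problem sizes used by the test suite

The suite exercises: the full 85-row reference table and its 114k-record
reconstruction (exact, deterministic); simulator checks at $n$ between
2\,000 and 400\,000 with 3-standard-error Monte-Carlo tolerances; and a
bootstrap coverage study of 200 independent draws of $n = 5\,000$ with
200 replicates each. These sizes keep the whole suite within a couple of
minutes on one core while leaving the stochastic tolerances meaningful.

## Known limitations

* The invasive-only analysis (`invasive_only()`) defaults to recoding
  in-situ cancers as negatives, keeping the caseload denominator
  identical to the all-cancers analysis so CRR axes remain comparable;
  the drop mode changes denominators and is available behind the flag.
  Which convention a published subanalysis used is often ambiguous —
  both are provided for that reason.
* The scenario fraction $f$ is treated as constant across thresholds; in
  reality the enrichment effect plausibly grows with CRR.
* No utility weighting: the framework reports error *rates and counts*
  and leaves the cost trade-off to the analyst, rather than collapsing
  it into an expected-utility scalar that would require defensible
  per-outcome utilities.
* Duplicate exam identifiers warn rather than fail by default
  (retrospective extracts legitimately contain re-reads); strict mode
  escalates.
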