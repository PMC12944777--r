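# ruleout

Statistical evaluation of AI "rule-out" (triage) thresholds for
population screening programs.

## The problem

When an AI risk model scores every screening exam, a natural way to cut
radiologist workload is to *rule out* exams whose score falls at or below
a threshold: those exams are never read, everything above the threshold
is *retained* for normal interpretation. Picking that threshold is a
risk–benefit decision, and conventional accuracy metrics (sensitivity,
specificity, AUC) do not express it well, because they ignore two
counterfactuals of the radiologist–AI interaction:

* some cancers ruled out by AI would have been **missed by the
  radiologist anyway** (interval cancers), so triage does not cause those
  misses; and
* radiologists reading a smaller, higher-prevalence retained pool may
  **catch cancers they would otherwise have missed**, crediting back part
  of the triage error.

`ruleout` implements an error-accounting framework for this setting. For
a cohort of exams with AI score, standard-practice recall flag, and
cancer outcome, every threshold `t` induces the stratification

|          | ruled out (score ≤ t) | retained (score > t) |
|----------|----------------------|----------------------|
| not recalled, no cancer | B | G |
| not recalled, cancer    | C | H |
| recalled, no cancer     | D | I |
| recalled, cancer        | E | J |

with `F = B+C+D+E` ruled out, `K = G+H+I+J` retained, `N = F+K`. The
package computes, per threshold:

* **CRR** (caseload reduction rate) `F/N` — the workload benefit;
* **G-FOR** (gross false omission rate) `(C+E)/F = 1 − NPV` — probability
  a ruled-out exam harbours cancer;
* **N-FOR** (net FOR) `E/F` — counting only cancers the radiologist would
  have caught in standard practice;
* **AN-FOR(f)** (adjusted net FOR) `(E − f·H)/F` — crediting a scenario
  fraction `f` of radiologist misses that triage turns into detections;
  may be negative;
* **FDR/PPV** among retained exams, AI-level sensitivity/specificity,
  Youden's J, and Bayes-theorem predictive values.

Two threshold-selection policies are provided: classical Youden's J
maximisation, and the outcome-based rule that picks the largest threshold
with `AN-FOR(f) ≤ 0` — the most workload reduction achievable with no net
increase in missed cancers under scenario `f`. Percentile bootstrap bands
quantify uncertainty, and a synthetic cohort simulator (with closed-form
expected metrics) supports validation without patient data.

It is aimed at radiology informatics and screening-program analysts
evaluating triage operating points on local retrospective data, and at
methodologists studying rule-out policies for low-prevalence screening
(mammography, lung CT, AAA ultrasound).

## Worked example

The package ships a reference stratification table from a published
retrospective cohort (114,229 screening mammograms, 864 cancers, scored
by an open-source 1-year-risk model), from which an exam-level
pseudo-cohort can be reconstructed exactly:

```r
library(ruleout)

cells <- reference_sweep_counts()
co <- cohort_from_cells(cells)
co
#> <ruleout_cohort> 114,229 exams, 864 cancers (prevalence 0.76%), recall rate 8.7%

sc <- stratify(co, 0.20)      # the Youden-level operating point
sc
#> <ruleout_counts> threshold 0.2: ruled out 85220 (B=79194 C=82 D=5803 E=141),
#>                  retained 29009 (G=24995 H=66 I=3373 J=575), N=114229
```

At threshold 0.20, three quarters of the caseload is ruled out, at the
cost of 223 ruled-out cancers, of which 141 would have been recalled in
standard practice; crediting 30% of the 66 retained radiologist misses
leaves a net balance of 121 missed cancers:

```r
round_half_up(100 * gross_for(sc))            # 0.26  (% of ruled-out exams)
round_half_up(100 * net_for(sc))              # 0.17
round_half_up(100 * adjusted_net_for(sc, 0.30)) # 0.14
round_half_up(100 * caseload_reduction_rate(sc)) # 74.60
net_missed_count(sc, 0.30)                    # 121
```

The outcome-based policy instead finds the largest threshold at which the
30%-scenario adjusted net rate is non-positive:

```r
sw <- run_sweep(co, grid = cells$threshold)
select_anfor_zero(sw, f = 0.30)
#> <ruleout_selection> policy anfor_zero (f = 0.3): threshold 0.05
#>   CRR 36.00%  G-FOR 0.12%  N-FOR 0.07%  FDR 98.89%
```

i.e. a 36% caseload reduction with no expected net increase in missed
cancers under that scenario (the signed balance at 0.05 is −9, clamped to
0 for reporting). `bootstrap_bands()` adds percentile confidence bands,
`plot_for_curves()` / `plot_fdr_curve()` draw the rate-vs-CRR trade-off
curves, and `simulate_cohort(simulation_config(...))` generates synthetic
cohorts with the same joint structure.

A command-line interface wraps the same functions
(`exec/ruleout sweep|select|bootstrap|simulate`), reading cohort CSVs and
writing CSV/JSON/PDF artifacts.

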