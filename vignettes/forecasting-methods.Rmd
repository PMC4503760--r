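---
title: "Methods: forecasting liver-transplantation demand and costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forecasting liver-transplantation demand and costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltecon)
```

## The model

`ltecon` is a deterministic cohort model of the U.S. liver-transplantation
system with a probabilistic layer on top. It has two coupled parts:

1. **Epidemiology.** Annual cohorts of newly wait-listed patients over a
   20-year horizon (Year 1 = calendar 2014 through Year 20 = 2033),
   stratified by MELD score (`<9`, `10–19`, `20–29`, `30–39`, `>40`). Each
   cohort is followed through waitlist attrition (death or severe illness,
   or not proceeding to transplant), the transplant admission, and ten
   post-transplant years.
2. **Treatment costs.** Discounted per-patient costs in three phases —
   pre-transplant (per MELD category), hospital admission, and ten years
   post-transplant — combined with demand into national expenditure.

There is no individual-level microsimulation: the model is cohort
arithmetic on aggregate registry fractions, which is exactly the structure
of the published spreadsheet analyses it is designed to reproduce and make
testable.

### Demand and case mix

New listings compound from the 2012 registry count (10,143) at the annual
listings growth rate (1.1 %/yr). Because the registry data year is 2012
while the first simulated cohort is 2014, the exponent for model year $t$
is the elapsed calendar time $t + 1$; this convention is what reproduces
10,367 listings in 2014 and 12,763 in 2033. The same convention applies to
all share trajectories.

MELD category shares start from the 2012 waitlist mix (3.6 %, 52.4 %,
31.9 %, 8.6 %, 3.5 %) and compound at per-category annual changes
(−2.7 %, −0.3 %, +2.2 %, +3.4 %, +4.5 %), after which the five shares are
renormalized to sum to one. Renormalization is not cosmetic: compounded
shares drift away from a unit sum within a few years, and the published
category counts are only reproduced from renormalized shares applied to
the with-MELD cohort totals.

Patients with no reported MELD score (9.4 % in 2012, growing 7.6 %/yr) and
inactive listings (12.9 %, −0.5 %/yr) are excluded from the
MELD-stratified cohort. Compounding those exclusion shares cannot
reproduce the published with-MELD totals in late years (the published
series peaks at 8,006 in 2020 and falls to 7,600 in 2033, implying
time-varying rates that were not published), so the projection has two
modes: `computed` (compounded shares, agrees with the 2014 value within
1 %) and `anchored` (the published 2014/2020/2033 totals). Category-count
comparisons against published 20-year changes use the anchors; everything
else defaults to `computed`.

### Waitlist attrition

Each category's waiting time is the median of its waiting-time band
(1,776 / 639 / 106 / 20 / 20 days, with the 6-day status-1 band available
as an override for MELD >40), grown by the annual change in
time-to-transplant (+1.7 %/yr) for later cohorts. Cumulative
death-or-severe-illness schedules are applied over that waiting duration
with linear interpolation between printed horizons, through the origin
below the first horizon (3 months), and held flat beyond the last printed
horizon — the simplest monotone completion of the published tables. Of
patients surviving the wait, 21.3 % do not proceed to transplant; the
remainder are transplanted. The three outcomes partition each cohort
exactly; fractional persons are carried unrounded through the pipeline
and rounded only at report time, avoiding 20 years of compounding
rounding drift.

Admission deaths are 6 % of operated patients and re-transplants 3 %;
post-transplant survival follows the fixed 10-year schedule (90 % at
Year 1 down to 63 % at Year 10).

Mean age at listing uses age-group shares compounded at their annual
changes with fixed group midpoints 26 / 42 / 57 / 72 years; the open-ended
65+ group's midpoint of 72 was chosen so the 2014 mean lands near the
published 57.7 years. Midpoints are a reporting convenience only — nothing
downstream consumes age.

### Costs, escalation and discounting

All monetary inputs are 2014 USD (adjusted before entering the model; no
deflator runs at compute time). Prices escalate at $r$ = 4.9 %/yr and are
discounted to present value at $d$ = 3 %/yr, composed as one net factor
per elapsed year from Year 1:

$$F(y) = \left(\frac{1+r}{1+d}\right)^{y}.$$

The exact Year-20/Year-1 ratios of the published severe-category and
post-transplant costs pin down this composition.

**Pre-transplant.** Categories whose waiting time is under one year
(MELD ≥ 20) are "severely ill": their cost is the 12 months preceding
transplant at the category's monthly spending, so the MELD >40 Year-1 cost
is exactly 12 × \$51,085 = \$613,020. Categories waiting longer than a
year (MELD <9, 10–19) instead accrue monthly spending over the full
waiting duration, each month escalated at the net monthly rate
$F(1)^{1/12}$ from the listing date (a geometric series, evaluated in
closed form and verified month-by-month in the tests), plus the
last-30-days cost adjustment (\$26,469) escalated to the transplant date.
Two deliberate conventions here:

* The last-30-days adjustment is applied only to the waiting-time-costed
  categories. Its source labels it as applying below MELD 30, but adding
  it to the 20–29 severe-illness cost overshoots the published weighted
  Year-1 average by about 4 %, while omitting it lands within 1 %; the
  12-month window for severe categories evidently subsumes it.
* Months are 365/12 days, keeping monthly accrual consistent with annual
  escalation.

The published Year-20 values for the two low-MELD categories (\$71,621 and
the Year-1 \$49,407) depend on an accrual-versus-growth interaction that
was not published; this implementation lands within ~2 % at Year 1 and
~18 % at Year 20 and deliberately does not force-fit them (tests check
±20 % there, and exact values elsewhere).

**Admission.** Organ procurement (\$73,989) plus physician fees
(\$48,562) plus the hospital admission component (\$330,242) uplifted by
the expected case mix: seven patient/donor characteristics (frequency ×
percent uplift summing to +36.74 %), applied to the hospital component
only. Applying the uplift to all components overshoots the published
\$588,580 by ~5 %; hospital-only lands within ~2.5 %, the closest
reconstruction among the candidate bases. The published Year-20 admission
value exceeds Year-1 × $F(19)$ by ~0.5 % for unstated reasons; this model
keeps the exact scaling law.

**Post-transplant.** First-90-days base (\$139,746) plus the expected
complication add-on $\sum_i f_i c_i$ over 15 complications (≈ \$131,993;
the superficial-skin-infection row has a *negative* cost and is retained
as printed) plus ten years of immunosuppression (\$36,708/yr, each year
escalated at the net rate). The metric is conditional on 10-year survival,
so no survival weighting is applied.

National expenditure multiplies the per-patient three-phase total by total
new listings (all listed patients, not only the with-MELD cohort — demand
for organs is not reduced by a reporting artifact), assuming every patient
completes all phases.

## Uncertainty analysis

`run_monte_carlo()` samples every uncertain input of each Year-20 cost
metric independently: triangular distributions by inverse CDF with the
base as mode (the convention of the spreadsheet PSA tools this mirrors;
whether "base" was mode or median was not stated — mode is adopted),
uniforms on their bounds, fixed inputs at base. Rows whose bounds were
published only as "variable" are resolved to triangulars carrying the
relative spread of their nearest fully specified analogue (MELD 30–39
spending for the MELD >40 spending row; the nearest general share-change
row for the per-category share changes). Epidemiology growth rates are
held at base during the cost PSA — the metrics are per-patient costs, not
national totals — though nothing prevents sampling them through the same
machinery.

Summaries per metric: certainty-to-base (fraction of draws at or above the
deterministic base case), mean, median, and the 10th/90th percentiles. The
base case is computed through the same vectorized kernels as the draws, so
collapsing every distribution to fixed reproduces the base case bit-exactly
(a property test). With 30,000 draws the binomial standard error of a
~37 % certainty is about 0.3 points; the dominant mechanism pushing means
below base is the right-skewed escalation-rate triangular (mean 4.51 % vs
mode 4.9 %) raised to the 19th power.

Sensitivity uses contribution-to-variance: signed, normalized squared
Spearman rank correlation of each varied input with the output,
$s_i = \mathrm{sign}(\rho_i)\,\rho_i^2 / \sum_j \rho_j^2$, the convention
under which published indices sum to roughly ±100 %. Constant inputs are
dropped; a constant output yields `NA` indices with a warning.

## The bioengineered-liver ledger

A separate catalog-price calculator: reprogramming a patient's somatic
cells to iPSCs (\$15,000, independent of graft size) plus, for each cell
line (hepatocytes 1.5×10¹¹ cells/liver at 9×10⁶ cells and \$1,500 per
vial; endothelial cells 40 % of the hepatocyte count; fibroblasts 10 %),
`fraction × cells_required / cells_per_vial × price_per_vial`. Vials are
*not* rounded up: the published totals imply exact proportional pricing
(rounding up would add \$500 to the hepatocyte line). Totals are therefore
linear in the liver fraction with a fixed reprogramming intercept:
\$27,715,000 whole, \$9,710,000 at 35 %, \$4,170,000 at 15 %.
`price_decline_scenario()` rescales per-line vial prices to explore
economies of scale.

## Synthetic scenarios

`random_scenario(seed, scale)` perturbs every base value by an independent
uniform factor in $[1-s, 1+s]$, rescales distribution bounds by the same
factor (preserving shape and ordering), renormalizes share vectors, clamps
fractions to $[0,1]$ and restores monotone schedules by sorting — an O(1),
deterministic repair rather than rejection sampling. Generated scenarios
pass full validation and run end-to-end (a 50-seed smoke property in the
tests). What they do **not** emulate: correlation between inputs,
registry microdata, structural change in listing practice, or
time-varying rates — so passing property tests demonstrates numerical and
structural robustness, not epidemiological realism beyond the baseline.

## Problem sizes and numerical choices

The test suite runs the full 20-year deterministic pipeline and a 30,000
draw Monte Carlo (a few seconds; the binomial SE at that size is well
under the tolerances being checked), plus 50 smoke scenarios at 64 draws
each. Degenerate inputs are handled explicitly: zero-width triangulars
sample as point masses; equal escalation and discount rates give a net
factor of exactly 1; a single-draw PSA is a warned, non-fatal degenerate
summary; unknown or missing configuration keys are errors, never warnings,
because a silently dropped parameter corrupts a 20-year forecast.

## Known limitations

* The with-MELD exclusion shares cannot reproduce the published late-year
  totals by pure compounding; `anchored` mode exists for exactly the three
  published values.
* Low-MELD Year-20 pre-transplant costs are convention-dependent
  (see above) and are treated as approximate.
* Costs beyond 10 years post-transplant, MELD stratification of admission
  and post-transplant costs, and quality-adjusted outcomes are out of
  scope, as in the source analyses.
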