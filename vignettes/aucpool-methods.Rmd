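---
title: "The pooled-plasma AUC method: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pooled-plasma AUC method: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aucpool)
```

## The problem

Multi-component medicines — herbal formulations in particular — expose a
subject to tens or hundreds of constituents and metabolites at once. A full
non-compartmental workup (serial plasma samples, one AUC per compound per
subject) multiplies quickly: 12 time points × 3 replicates × every compound
of interest. When most constituents also lack reference standards, only
semi-quantification by LC-MS peak area is possible in the first place.

The pooled-plasma AUC method collapses the serial arm into a single
measurement per compound. Plasma aliquots from each collection time are
mixed in carefully chosen proportions so that the concentration of the
mixture, multiplied by the sampling span, *is* the linear trapezoidal AUC.
One injection then yields exposure estimates for every detectable compound
simultaneously, which is exactly what an exposure-ranking /
quality-marker screen needs.

## Pooling weights and the central identity

For collection times $t_0 < t_1 < \dots < t_n$ the linear trapezoidal AUC is

$$\mathrm{AUC}_{0\text{-}t_n} = \sum_{i=0}^{n-1} \frac{C_i + C_{i+1}}{2}\,(t_{i+1} - t_i)
  \;=\; \sum_{k=0}^{n} w_k C_k,$$

with the half-interval weights

$$w_0 = \tfrac{t_1 - t_0}{2},\qquad
  w_k = \tfrac{t_{k+1} - t_{k-1}}{2}\ (0 < k < n),\qquad
  w_n = \tfrac{t_n - t_{n-1}}{2},$$

which telescope to $\sum_k w_k = t_n - t_0$. If aliquot volumes are chosen
proportional to these weights, $v_k = V_\text{tot}\, w_k / \sum_j w_j$, the
pooled concentration is

$$C_\text{pool} = \frac{\sum_k v_k C_k}{\sum_k v_k}
  = \frac{\sum_k w_k C_k}{t_n - t_0},$$

so that $C_\text{pool}\,(t_n - t_0) = \mathrm{AUC}_{0\text{-}t_n}$ exactly —
for *any* profile, not just well-behaved ones. `hamilton_weights()` and
`pooling_volumes()` implement the design; `pool_concentration()` and
`pooled_auc()` the in-silico counterpart. The identity is the package's
backbone and is verified to $10^{-10}$ relative error over 1,000 random
profiles on random schedules in the test suite.

Two consequences of the derivation are worth spelling out:

* **The pre-dose sample is part of the pool**, with weight
  $(t_1 - t_0)/2$. On the standard 12-point 0–24 h schedule with a 480 µL
  pool this is the familiar 2.5 µL aliquot, and the full design is
  2.5, 5, 7.5, 15, 20, 20, 30, 40, 40, 40, 140, 120 µL.
* **The identity holds only for the linear trapezoid.** No log-linear
  variant is offered: a pooled sample physically computes a weighted
  arithmetic mean, nothing else.

```{r}
sched <- sampling_schedule(c(0, 0.25, 0.5, 1, 2, 3, 4, 6, 8, 10, 12, 24))
pooling_volumes(sched, total_volume = 480)
```

Volumes are rounded to a pipettable increment (default 0.1 µL; the 480 µL
design above is exact at that increment). Rounding that moves any aliquot
more than 1% from its exact value attaches a warning diagnostic; rounding
that zeroes an aliquot is an error, since a missing time point silently
re-weights the whole integral.

Method agreement is summarised by the unsigned relative difference
$|\mathrm{AUC}_\text{pooled} - \mathrm{AUC}_\text{serial}| /
\mathrm{AUC}_\text{serial} \times 100$, with the serial (traditional)
estimate as the reference denominator (`percent_difference()`).

## What the synthetic cohort generator emulates

No concentration data or PK constants accompany the screening design this
package targets, so every downstream stage is validated against a synthetic
cohort generator (`simulate_cohort()`) whose structure mirrors the study
type: oral dosing, a 12-point 0–24 h schedule, parent compounds plus
phase-II conjugates, three species, triplicate pooled measurements,
multiplicative assay noise, LLOQ censoring.

**Kinetics.** Parents follow a one-compartment oral model,
$C(t) = \frac{F D k_a}{V (k_a - k_e)} (e^{-k_e t} - e^{-k_a t})$ — the
minimal model producing the single-peak profiles typical of oral dosing.
Metabolites follow the catenary extension (gut → parent → metabolite, all
first order), solved in closed form; when the metabolite elimination rate
$k_m$ collides with $k_a$ or $k_e$ the Bateman denominators vanish and the
implementation switches to `deSolve::lsoda` rather than returning NaN.
Under this model the metabolite-to-parent AUC$_{0\text{-}\infty}$ ratio is
$f_m k_e / k_m$ ($f_m$ = formation fraction), which the tests check by
dense numerical integration.

**Default panel.** Two parents and eight conjugates. The first parent
(`rhein_like`: D = 100, F = 0.8, $k_a$ = 1.2 /h, $k_e$ = 0.25 /h, V = 10)
dominates exposure, as the anthraquinone prototype does in the real system.
Conjugate elimination rates are set to 1.6–2.4 /h, well above the parent
$k_e$: phase-II conjugates are typically cleared much faster than they are
formed, making their plasma profiles formation-rate-limited — they track
the parent's shape. That property is what makes a shape-correlation screen
against the parent meaningful at all, and it is the regime the screening
literature reports. Pathway totals are species-specific — human settings
prefer sulfation (0.45 vs 0.20 glucuronidation), rodent settings the
reverse — so cross-species comparisons have real structure to detect.

**Assay.** Measured area = response factor × concentration ×
log-normal noise. The log-scale draw has $\sigma^2/2$ subtracted, so the
noise is mean-preserving and its CV is exactly the stated `cv` (default
0.10, a routine LC-MS between-replicate figure). Censoring applies to the
back-calculated concentration: points below `lloq` are flagged and zeroed,
and the flags propagate. The default LLOQ of 0.005 concentration units sits
near 0.1% of the leading parent's $C_\text{max}$, leaving the panel's
conjugates quantifiable over most of the curve — the situation of a screen
whose top compounds are, by construction of the instrument method, all
measurable. One deliberate exception remains: the smallest panel compound
(`emodin_oxide`, $C_\text{max} \approx 2\times$ LLOQ) exercises the heavy-
censoring path in every default run.

**What is deliberately not emulated**: enterohepatic recirculation (which
produces secondary peaks), nonlinear or saturable kinetics, inter-compound
conversion, plasma-protein binding, chromatographic interferences and
matrix effects, between-subject variability (the cohort is one "average
subject" measured in replicate). Passing tests therefore certify the
*arithmetic* of pooling, ranking and screening under realistic noise — not
robustness to kinetic phenomena outside the linear one-compartment world.

## EIC quantification

`extract_eic()` sums, per spectrum, all centroid intensities within a
closed ppm window $[m/z\,(1 - \text{ppm}\times 10^{-6}),\; m/z\,(1 +
\text{ppm}\times 10^{-6})]$ (default 5 ppm, the conventional
high-resolution setting); boundary ties are included, which makes the
window bit-exactly testable. Every spectrum contributes one point — zeros
are kept — so trace times always match the acquisition grid.
`integrate_eic()` is a plain trapezoid over a user-supplied retention-time
window: no smoothing, baseline model or peak detection, matching the
targeted semi-quantification use where retention windows are known inputs.
Internal-standard normalization (`normalize_to_is()`) is provided but off
by default, since semi-quantitative screens often report raw areas. The
deprotonated-adduct helper `mz_mh_neg()` (monoisotopic mass − 1.007276) is
never auto-applied.

## Exposure ranking and the Q-marker screen

`exposure_table()` defines exposure as the mean replicate pooled area ×
the schedule span. Multiplying by the fixed span changes no rank; it keeps
values on the AUC scale. Ranks are per species, descending, ties broken by
compound id so the table is a deterministic function of its contents
regardless of row order. `cumulative_fraction()` and `species_share()`
answer the two screening questions — how concentrated is exposure in the
top N, and how much of another species' exposure the screening species'
top set carries. Both support a `basis = "count"` reading (fraction of
compounds rather than of exposure) because published shares are sometimes
stated either way; exposure-fraction is the default and the more
informative of the two.

Correlation screening works on *time-percentage profiles*
(`percent_profile()`: each time point as a share of the profile total),
which makes compounds on very different absolute scales shape-comparable.
Pearson r and its two-sided p (t transform on $n-2$ degrees of freedom) come
from `stats::cor.test`; an independent definitional-sum oracle pins the
implementation in the tests. Raw-value correlation is available behind
`normalize = FALSE`.

`select_qmarker()` encodes the screening rule: the candidate is the
highest-ranked compound with an obtainable reference substance, and it
qualifies when every other top-$k$ compound has $r >$ 0.8 and $p <$ 0.001
against it — the conventional strong-correlation bounds, which are the
defaults. No multiple-testing correction is applied; all p-values are
recorded in the report so users can impose their own procedure. Failure is
always explicit: a missing reference, a missing correlation or a weak
companion produces named fail flags and a reason, never a silent pass.

## Numerical and degenerate-input choices

* Times in hours, retention times in minutes, volumes in microliters;
  unit labels ride along in headers so accidental mixing is detectable.
* Below-LLOQ values are zeroed before any integration or pooling (the
  conservative reading when no imputation rule is given); flags propagate.
* A compound entirely below LLOQ has serial AUC 0: `percent_difference()`
  refuses a zero reference, so `run_pipeline()` reports NA for that
  compound and excludes zero-exposure compounds from the correlation
  screen rather than aborting.
* Degenerate rate equalities ($k_m \approx k_a$ or $k_e$, relative
  tolerance $10^{-8}$) switch the metabolite solution to `lsoda`
  (rtol $10^{-10}$); $k_a = k_e$ in the parent model is an error rather
  than a silently applied limiting form.
* All randomness flows through explicit seeds; sub-seeds are derived
  arithmetically (kept below $2^{31}$) and the caller's RNG stream is
  saved and restored, so reruns are byte-identical.

## Validation problem sizes

The test suite checks the pooling identity on 1,000 random
profile/schedule pairs (and 200 more against the rounded 480 µL design),
the Pearson oracle on 1,000 random pairs, noise-bias on 200 simulated
cohorts (mean pooled AUC within 2% of truth), and pooled-vs-serial
agreement on 200 noisy triplicate cohorts (≤ 15% difference in ≥ 95% of
cohorts; the observed median difference is about 2%). These sizes give
stable Monte-Carlo estimates at sub-minute runtimes and are stated here as
the package's validation design.

## Known limitations

* The pooled method estimates *only* AUC$_{0\text{-}t_n}$: $C_\text{max}$,
  $T_\text{max}$, half-life and extrapolation to infinity are out of scope.
* Near the LLOQ, censoring noise can push the pooled-vs-serial difference
  of a single compound well past the usual 15% agreement band (the default
  panel's smallest compound exceeds it at some seeds); this is a property
  of censored measurement, not of the pooling arithmetic.
* Shape correlation on 12 time points has limited power; with the default
  thresholds a true $r = 0.8$ companion will sit on the boundary, and
  replicate noise decides marginal cases.
* The generator's linear, single-subject world is a validation harness.
  Conclusions about real cohorts require real serial data, for which the
  package's serial-arm functions (`trapezoid_auc()`, `compare_methods()`)
  are the entry point.
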