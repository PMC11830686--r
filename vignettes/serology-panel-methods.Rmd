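---
title: "Methods: autoantibody screening and panel selection for multiplex serology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autoantibody screening and panel selection for multiplex serology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seropanel)
```

## The problem

Sjögren's disease (SjD) patients who lack anti-Ro/SSA antibodies are hard
to diagnose serologically: classification then rests on an invasive
salivary-gland biopsy. Multiplex bead arrays (Luminex-type) measure IgG
and IgA reactivity against dozens of candidate autoantigens per serum
sample as median fluorescence intensities (MFI). `seropanel` implements
the complete analysis path from raw MFI matrices to (i) a univariate
candidate screen, (ii) control-anchored binarization with per-marker
cutoffs, (iii) prevalence and co-prevalence estimation, (iv) greedy
forward selection of an OR-rule diagnostic panel for the Ro/SSA-negative
subgroup, and (v) a logistic screen of marker–clinical-manifestation
associations — together with a synthetic-cohort generator whose ground
truth supports recovery and calibration studies.

## Analysis scale

All statistics operate on `log2(MFI)` after **sample-wise median
centering**: each sample's median log2 intensity across its marker panel
is subtracted, removing per-sample scaling and plate/batch offsets
(`log2_transform()`, `median_center()`). Centering is idempotent and
removes any additive offset shared by all markers of a sample exactly.
One consequence worth remembering: after centering, row medians are
zero, so absolute thresholds only make sense *before* centering. The
low-reactivity pre-filter (`prefilter_low_reactivity()`) therefore runs
on the uncentered log2 scale, dropping markers whose 75% quantile across
all samples does not exceed log2 MFI 10. The pipeline pre-filters first
and centers on the retained panel; the alternative order changes row
medians only marginally but is not what this package does.

**Quantile convention.** Every quantile in the package is the empirical
nearest-rank (type-1) quantile — the smallest observed value whose
cumulative fraction reaches the level. Cutoffs are therefore always
attained data values, which makes the cutoff-escalation scan over
observed values well defined and tie-free by construction.

## Univariate screen

Per marker and isotype channel (`screen_markers()`):

* **Mann–Whitney U** (exact for combined n ≤ 12 without ties, otherwise
  normal approximation with tie and continuity correction);
* **fold change** `2^(median(case) − median(control))`;
* **SAM d-statistic** `d = (mean(case) − mean(control)) / (s + s0)` with
  `s` the pooled standard error of the difference and the fudge factor
  `s0` defaulting to the median pooled standard error across all
  screened markers (a standard SAM choice); significance by two-sided
  label-permutation (exhaustive when feasible, otherwise 1000 shared
  permutations across markers);
* **quantile span**: the largest absolute difference between case and
  control 25/50/75% quantiles, in log2 units. The discovery criterion
  "at least one quantile with absolute span ≥ 1" is under-specified in
  the field; this package fixes it to the three quartiles and keeps the
  criterion switchable via the config.

Screen p-values are reported raw at α = 0.05, matching how such
discovery/validation screens are usually reported; false-discovery-rate
adjustment is reserved for the clinical-association stage (users can of
course apply `bh_adjust()` to any p-value column).

## Binarization and cutoff escalation

`calibrate_cutoff()` anchors each marker's cutoff on healthy controls
(HC): the base cutoff is the nearest-rank 98% quantile of the HC values,
and a call is positive only when the value is **strictly greater** than
the cutoff. With n HC samples this pins in-sample HC positivity at
`n − ceiling(0.98 n)` samples (2/118 ≈ 1.7% at the cohort size typical
of such studies), operationalizing "at most 2% positive controls".

Escalation then scans the sorted distinct observed values (HC and case
pooled) above the base cutoff and accepts the largest candidate that
leaves the case positives unchanged while strictly reducing HC
positives — specificity can only improve, sensitivity cannot change.
Restricting candidates to observed values makes the rule deterministic
without a step-size parameter. Calibration uses HC only; sicca (NSS) and
disease controls are evaluation-only. Both the base and the escalated
cutoff are persisted, so prevalences can be reported under either.

## Panel selection

The diagnostic rule is a logical OR over binarized IgG markers
(`predict_panel()`): a sample is predicted SjD if any panel marker is
positive. `forward_select_panel()` seeds with the most prevalent marker
in the target subgroup (Ro/SSA-negative SjD) and, at each later step,
adds — among markers keeping the panel's HC specificity at or above the
floor (default 0.95) — the marker covering the most not-yet-covered
target samples. Maximal marginal union coverage is the operational form
of "high sensitivity and low co-prevalence with the previous markers":
under fixed marker prevalence the two objectives coincide, and marginal
coverage makes the greedy step a single well-defined criterion. Ties
break by higher panel specificity, then lexicographic marker key, so
selection is deterministic. Union coverage is submodular, so the greedy
panel is within (1 − 1/e) of the exhaustive optimum and exactly optimal
for disjoint responder sets; both properties are tested against
brute-force search. Cutoffs are calibrated once per marker and kept
fixed as the panel grows.

Panel metrics (sensitivity in the target, specificity vs HC and vs NSS,
with exact Clopper–Pearson 95% intervals) are reported on the selection
cohort, as such studies do. **In-sample metrics are optimistically
biased**: the same HC samples fix the cutoffs and score specificity, and
the same target samples drive selection and score sensitivity.
`evaluate_panel()` accepts any cohort, so a holdout evaluation is one
call away, and the package's own calibration studies use holdout
cohorts for exactly this reason.

## Clinical associations

`association_screen()` regresses each binary clinical flag (ESSDAI
domains, laboratory flags, biopsy grade) on the continuous centered
log2 marker level by maximum-likelihood logistic regression (IRLS,
deviance tolerance 1e-8, 100 iterations), complete cases only. The
predictor is continuous — reported coefficient magnitudes around
0.45–1 per log2 unit are consistent with that reading, and "dichotomous"
refers to the outcome; a binarized-predictor mode is available.
Completely separated fits are flagged non-estimable rather than
returning a diverging coefficient. Within each outcome, p-values are
Benjamini–Hochberg adjusted across markers (each clinical question is
its own family); the association filter is `p ≤ 0.05` **and**
`|coefficient| ≥ 0.45`, applied to the absolute value because negative
associations are meaningful (e.g. a marker elevated in the absence of a
manifestation). Models are unadjusted for covariates by design; the fit
interface accepts any predictor vector if users want to build adjusted
analyses.

## The synthetic cohort generator

`sim_truth()` fixes the generative law on the log2 scale:

    log2 MFI_ij = mu_i + delta_ij * e_i + c_j + b_batch(j) + eps_ij

with responder indicators `delta_ij ~ Bernoulli(pi_{i, group(j)})`,
noise `eps ~ N(0, sigma_i)`, sample offsets `c_j ~ N(0, 0.4)` and one
additive batch offset per recruiting center (three centers for SjD with
mix 0.625/0.207/0.168 echoing the Hannover/Berlin/Udine head counts;
offsets 0/+0.2/−0.2). A responder is a location shift — matching the
threshold-based binarization — and the emitted matrix is `2^value`,
i.e. log-normal linear MFI. Defaults chosen once as realistic for this
assay class: backgrounds `mu ~ U(10.5, 12.5)` log2 MFI with a 10% share
of low-reactivity markers (`U(8.5, 9.8)`) to exercise the pre-filter,
`sigma ~ U(0.3, 0.7)` log2 units, signal effects of 5 sigma,
SjD responder prevalences `U(0.05, 0.19)` (novel autoantibodies in such
cohorts reach ~19%), background seropositivity 0.01 everywhere else,
and an anti-Ro60 IgG channel at prevalence 0.60 in SjD whose responder
indicator defines the Ro/SSA status of every simulated sample.
Heavier-tailed noise is deliberately not the default. Clinical outcomes
are attached per an association ledger:
`outcome ~ Bernoulli(plogis(beta0 + beta * x))` with `x` the centered
log2 level, plus a configurable missingness fraction.

What the generator does **not** emulate: polyreactive sera (cross-marker
correlated positivity in controls), antigen cross-reactivity, titer
drift over time, and heavy-tailed single-marker outliers. Passing
recovery tests on this generator therefore shows the *procedures* are
correct and calibrated under the stated model — not that real cohorts
will reproduce any particular published marker list, which would require
the original sera.

## Validation studies and their problem sizes

The package's validation studies (the test suite and
`scripts/acceptance.R`) use cohort sizes typical of this study class:
200 Ro/SSA-negative patients, 118 healthy controls, 50 null markers,
planted complementary prevalences 0.12/0.10/0.08, 100 simulation seeds;
associations at n = 2000 with β = 1; estimator calibration against
large-sample (n = 10,000) Monte-Carlo operating points on held-out
cohorts. The end-to-end determinism check runs a 500-sample × 100-marker
cohort and replays it from its manifest.

Two findings from these studies deserve emphasis because they are
properties of the *method*, not implementation artifacts:

1. **In-sample cutoff artifacts.** The 98%-quantile rule forces ~1.7%
   in-sample HC positivity per marker regardless of the marker's true
   specificity, and the cutoff is a noisy order statistic (sd ≈ 0.26
   sigma at n = 118). Apparent prevalence in cases is therefore inflated
   by roughly the order-statistic exceedance (n+1−k)/(n+1) ≈ 2.5%, and
   occasional null markers show 5–12% apparent prevalence purely by
   cutoff noise.
2. **Exact panel recovery is fragile at realistic scale.** A 3-marker
   union already sits at the 0.95 HC-specificity floor (6/118 > 5%), and
   lucky null markers can out-gain the weakest planted marker. At the
   sizes above, greedy selection returns a panel whose union sensitivity
   matches the exhaustive 3-subset optimum in ≈95% of seeds, but returns
   *exactly* the planted trio in only ≈50% — complementary-panel
   composition should be treated as one near-optimal solution among
   several, not as uniquely identified. Holdout evaluation of whatever
   panel is selected remains well calibrated (exact binomial CI coverage
   at nominal level).

## Numerical and degenerate-input choices

* Fisher's exact two-sided p sums hypergeometric probabilities no more
  probable than the observed table (relative tolerance 1 + 1e-7);
  degenerate margins give p = 1 with a warning.
* `sam_d()` refuses a zero denominator (`s + s0 = 0`); permutation
  p-values include the observed labeling, `(1 + b)/(1 + B)`, when
  sampled rather than enumerated.
* Median centering refuses single-marker panels; linear-scale matrices
  must be strictly positive (enforced at ingest, naming the offending
  cell).
* ELISA titers interpolate piecewise log-linearly between the five
  standards on the (log2 concentration, response) plane — five points
  under-constrain a four-parameter logistic, so 4PL is intentionally not
  the default — and out-of-range readings are censored (`"<2.5"`,
  `">40"`), never extrapolated; censoring flags follow the concentration
  axis, so they are correct for competitive (decreasing) curves too.
* Persisted tables render doubles with 17 significant digits so that
  binarization recomputed from a persisted cutoff table is bit-identical
  to the original calls.
* All randomness flows from a single integer seed; runs emit a manifest
  (config, seed, group sizes, file digests) and `replay_manifest()`
  reproduces every output byte-for-byte.

## Known limitations

In-sample panel metrics are optimistic (quantified above); the generator
omits cross-marker dependence in controls, so real-data panel unions may
show *better* specificity than the independent-markers worst case; the
span criterion's quantile set is a fixed convention; and the package
deliberately does not attempt antigen annotation, network analysis, or
reproduction of published marker lists.
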