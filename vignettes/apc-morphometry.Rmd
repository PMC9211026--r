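---
title: "Annualized change, multiplicity and synthetic cohorts: the methods behind apcmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annualized change, multiplicity and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcmorph)
```

`apcmorph` is the statistical half of a longitudinal morphometry
pipeline: it starts where image processing ends (a long table of
per-subject, per-visit, per-region feature values) and ends with
multiplicity-corrected group differences and their correlation with
cognitive decline. This vignette explains the model and every design
choice a maintainer might want to revisit.

## The multiplicative change model

Morphometric features — volumes, areas, thicknesses — are strictly
positive. If a feature's relative change per unit time is constant, it
evolves as $x(t) = x_0 (1+q)^t$ with rate $q > -1$ per time unit. Two
observations $x_1, x_2$ at days $t_1 < t_2$ identify the daily rate
$q = (x_2/x_1)^{1/(t_2-t_1)} - 1$, and re-expressing it over a nominal
interval of $n$ days gives the annual percent change

$$\mathrm{APC} = \left(\left(\tfrac{x_2}{x_1}\right)^{n/(t_2-t_1)} - 1\right)\cdot 100.$$

Why this and not a per-day linear scaling $(x_2-x_1)/(x_1\,\Delta t)$?
Because follow-up visits never land exactly on schedule. Under the
multiplicative model the APC is *invariant* to the realized interval —
the same true rate observed over 250 or 480 days yields the same APC —
while the linear scaling is not (it over- or under-corrects whenever
$\Delta t \neq n$ and $q \neq 0$). Worse, the linear model
$x(t) = x_1 + P x_1 t$ crosses zero at a finite horizon whenever
$x_2 < x_1$, which is impossible for a volume; `linear_projection()`
exists only to demonstrate this, and `project()` (the exponential
model) provably cannot. Both behaviours are exercised in the test
suite and the acceptance script.

Numerical conventions: time is whole days from scan dates; $n = 365$
exactly (never 365.25) — a study with a 180-day design sets
`n_days = 180` instead. Scalar operations error on non-positive
inputs; the table-level `apc_table()` instead drops records containing
non-positive values and logs a count, because one degenerate region
extraction should not abort a whole study. Intervals deviating from
$n$ by more than half of $n$ are flagged with a warning (the
constant-rate assumption degrades as the gap grows) but are not
excluded automatically.

## Homogeneity quality assurance

Second-stage QA asks: does this subject's whole feature profile look
like its group's? The score is the Pearson correlation between the
subject's feature vector (every region × measure × visit value) and
the leave-one-out mean vector of the rest of the group. Subjects whose
score falls below *group mean − k · group SD* (default `k = 2`) are
excluded; the rule is lower-tail only (an unusually *high* homogeneity
is not a quality problem), computed in a single pass with mean and SD
taken over all group members including the candidates.

Design notes:

* Correlation against a leave-one-out template is the table-level
  analogue of the voxelwise sample-homogeneity checks used on
  modulated gray-matter segments; it needs no tuning, lies in
  $[-1, 1]$, and is invariant under any affine rescaling applied to
  all subjects alike. Within-subject standardization would change
  nothing (Pearson already centers and scales), so none is applied.
* The score is meaningful only because regions have distinct
  characteristic sizes — the shared anatomical profile is the signal.
  Feature tables where all features share one scale carry no profile
  and give near-zero scores for everyone.
* The 2-SD rule is deliberately permissive at small *n*: with four
  subjects scoring 1, 1, 1, 0, the threshold is −0.25 and nobody is
  excluded. That is the intended behaviour of an SD-based rule, not a
  defect.
* Exclusion is applied once; no iterative re-scoring.

## Group comparison

Per region × measure, the two groups' APC values are compared with a
two-sample t-test. The default is the pooled (Student) variant,
$df = n_a + n_b - 2$: for published comparison tables built on equal
group sizes, the pooled test is what reproduces the printed p-values
(a 25-versus-25 comparison has $df = 48$; Welch would give
region-dependent fractional df). Welch is available by flag for
unequal-variance settings. Tests are two-sided throughout, with
individual-level flags at $\alpha = 0.05$.

`ttest_from_summary()` operates directly on group means, SDs and
sizes, so printed summary tables can be audited without raw data;
`ttest_from_values()` is defined as the summary path applied to sample
statistics and is tested to agree with `stats::t.test()` to machine
precision. Zero-variance edge cases are defined, not errors: identical
summaries give $p = 1$, and zero SDs with unequal means give $p = 0$
with a warning.

`distribution_overlap()` quantifies group separability from
region-level mean APCs: both samples are binned on a shared fixed
grid (default width 0.5 APC percentage points — fixed, so the
coefficient is comparable across cohorts), normalized to densities,
and the overlap coefficient is $\sum_b \min(f_A, f_B)\cdot w \in [0, 1]$.

## Multiple testing

Three corrections are computed side by side within each family:

* **Bonferroni** ($p_{\mathrm{bonf}} = \min(1, m\,p)$): the FWER
  reference, hopeless for hundreds of regions.
* **Benjamini–Hochberg**: step-up adjusted p-values — sort, compute
  $p_{(i)} m / i$, cumulative-minimum from the top, cap at 1. The
  implementation is tested against a brute-force transcription of the
  definition on all permutations of six p-values and against
  `stats::p.adjust`.
* **Storey–Tibshirani q-values**: $q = \hat\pi_0 \times$ BH-adjusted
  p. $\hat\pi_0$ — the estimated fraction of true nulls — comes from
  the tail of the p-value distribution:
  $\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ on the grid
  $\lambda = 0.05, 0.10, \dots, 0.90$, smoothed by a cubic smoothing
  spline with 3 effective degrees of freedom and evaluated at
  $\lambda = 0.90$. These are the standard tuning choices for this
  estimator, adopted here because the method itself does not
  prescribe alternatives.

$\hat\pi_0$ is clamped into $(1/m, 1]$. The clamp matters: an
unclamped tail estimate can exceed 1 on null-heavy data, and
multiplying BH-adjusted p-values by a $\pi_0 > 1$ would make q-values
*larger* than their BH counterparts — a correction more conservative
than the bound it refines, which this package treats as meaningless
and never emits. Consequently `q <= p_adj_bh` always holds here, and
Storey rejections always contain BH rejections at the same level;
published tables in which q-values exceed BH-adjusted p-values by a
constant factor above 1 cannot be reproduced by a clamped estimator,
and no attempt is made to do so.

With fewer than 20 p-values, or all p-values identical, the estimator
falls back to $\pi_0 = 1$ (BH-equivalent) with a warning.

**Applicability diagnostics.** The q-value machinery only adds power
when (1) the family is large (threshold: $m \ge 100$), (2) p-values
are approximately uniform near 1, and (3) the density peaks near 0.
`storey_conditions()` makes these executable: the tail check fits a
line to the 10-bin histogram of $p \in [0.5, 1]$ and requires the
slope not be significantly positive (one-sided, 0.05); the peak check
requires the count in $[0, 0.05]$ to exceed the uniform expectation
$m/20$ *significantly* (one-sided binomial test at 0.05) — a bare
excess over the expectation would flip a fair coin on purely null
data. When the verdict is negative the family is marked
"BH recommended"; q-values are still reported.

**Family scoping** is configurable because adjusted values are only
comparable within their correction family: the default is one family
per stream × measure; a `reproduce` mode corrects the whole
volumetric stream as one family and all surface measures as one joint
family (the scoping under which identical raw p-values across surface
measures receive identical adjusted values); `global` and an explicit
`family` column are also supported. Whether a surface family should
include all five measures or only volume/area/thickness is not
decidable in general — it changes $m$ and thus every adjusted value —
so the package exposes it rather than hard-coding it.

## Cognition

Cognitive change is the raw difference (year 1 − screening) per
instrument — not a percent change, because CDR, FAQ and NPI are
legitimately zero at baseline. Subjects missing a visit are dropped
listwise per instrument. Association with regional change is the
Spearman rank correlation (Pearson on average ranks; ties get mean
ranks), computed over the pooled case + control set by default:
pooling spans the full severity range, which is what gives the
correlation its resolution, and the per-group restriction is one
argument away. Correlations with fewer than 3 overlapping subjects
are omitted with a warning, and no p-values are attached — with
hundreds of regions the comparison table, not the correlation table,
is where inference belongs.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the pipeline assumes —
it is the package's test bed, not a simulator of images:

* **Panel:** 88 volumetric features (19 subcortical regions, 64
  subfield-style subdivisions, 5 brainstem parts) plus 360 cortical
  parcels × 5 surface measures (volume, area, thickness, gyrification,
  depth). Region names not taken from a published atlas table are
  synthetic placeholders (`L_ctx_###`, `subfield_##`).
* **Rates:** an affected medial-temporal / temporo-parietal set
  declines several percent per year faster in the case group
  (hippocampus-like: −4.4 vs −0.3 %/yr; the strongest effect −8.8 vs
  +0.4 %/yr); every other feature is null — identical rates in both
  groups, spread smoothly between −2 and +0.5 %/yr (gyrification and
  depth near zero) so group-mean histograms have realistic width
  without spurious differences.
* **Baselines:** log-normal per feature (strictly positive,
  right-skewed), with measure-level scales (volumes ~3000 mm³,
  thickness ~2.5 mm, …) and a fixed per-region offset spanning about
  a factor of *e* either way — the shared size profile that
  homogeneity QA correlates against. `sdlog = 0.2` gives ~20%
  between-subject coefficient of variation.
* **Intervals:** 365 days plus a uniform integer jitter in ±45 days.
* **Noise:** multiplicative log-normal on the follow-up value
  (`noise_sigma = 0.03`, giving APC standard deviations of about 3
  percentage points — the order seen in regional tables); an option
  applies independent noise to the baseline too.
* **Progression heterogeneity:** each subject carries a Gaussian rate
  shift (`subject_rate_sd = 0.02`/yr) added to every feature's rate.
  Without it, all subjects in a group would share one true rate and
  the cognitive model below would be degenerate within groups; with
  it, subjects who atrophy faster also decline faster cognitively,
  which induces rank correlations of the observed order (|rho| ~
  0.1–0.4, positive with MMSE, negative with CDR/FAQ/NPI for affected
  regions). The value 0.02/yr was fixed once, as the point where the
  induced correlation magnitudes match regional morphometry studies.
* **Cognition:** baseline scores are drawn per group from
  demographic-table-level means/SDs; change is
  `intercept + coupling × (subject mean true rate) + noise`, clipped
  to instrument ranges (MMSE 0–30, CDR ≥ 0, FAQ 0–30, NPI ≥ 0). This
  is a phenomenological coupling, not a mechanistic model; clipping
  means floor-bound instruments (controls at CDR 0, MMSE near 30)
  carry attenuated signal, as in real cohorts.
* **Determinism:** one RNG stream, seeded from the configuration;
  identical configuration + seed reproduce every table byte for byte.

What the generator deliberately does **not** model: images, surfaces
or atlas geometry; spatial correlation between regions (features are
conditionally independent given the subject's rate shift — so
FDR-control experiments here speak to independent-ish tests, not to
spatially correlated maps); site or scanner effects; non-monotone
trajectories (exactly two visits). Passing tests on this generator
therefore show the statistics are correct under the stated model, not
that the model captures everything real data do.

`generate_pvalue_mixture()` is the lighter harness for the
multiplicity module alone: `round(pi0 * m)` uniform nulls plus
alternatives from a one-sided z-shift (`p = 1 - pnorm(z)`,
`z ~ N(effect, 1)`).

## Problem sizes and runtime choices

The test-suite simulations are sized to be decisive yet quick: type-I
calibration uses one all-null cohort of 1000 regions × 25 subjects per
group (3-binomial-SE band); FDR control uses 500 replicates of
m = 500 mixtures per null fraction (Monte-Carlo SE bands); consistency
of the group-mean APC uses n = 200 per group; BH is verified on all
720 permutations of six p-values. The full suite runs in well under a
minute on one core, and `scripts/acceptance.R` recomputes the same
quantities end to end in a few seconds.

## Known limitations

* Exactly two visits per subject; richer trajectories need a
  mixed-model treatment outside this package's scope.
* No covariate adjustment (age, sex, total intracranial volume) in
  the group comparison.
* The homogeneity score weighs large-valued features more (raw-scale
  correlation); that mirrors image-space practice but means volumes
  dominate thicknesses when both are in one table.
* $\hat\pi_0$ assumes roughly independent tests; strong inter-region
  correlation widens its sampling variability beyond what the
  diagnostics report.
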