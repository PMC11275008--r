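---
title: "Models and methods behind the OncoCompare pipeline"
author: "OncoCompare maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the OncoCompare pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OncoCompare)
```

OncoCompare packages the statistical chain used to characterize a
cytotoxic natural compound: docking-score thermodynamics, COMPARE-style
mode-of-action inference over a 60-cell-line panel, proteomic response
correlates with Ward clustering and a χ² association test, mass-action
K~D~ fitting, ΔΔCt expression quantification, and FDR-controlled
Kaplan–Meier screening.  This vignette records the models, the
parameter choices, the numerical conventions, and what the synthetic
generators do and do not emulate.

## Docking-score thermodynamics

AutoDock-style docking reports a best binding free energy ΔG (kcal/mol)
and a predicted inhibition constant.  The two are linked by the
thermodynamic convention

$$K_i = \exp\left(\frac{\Delta G}{RT}\right),
  \qquad R = 1.98719\times10^{-3}\ \mathrm{kcal\,mol^{-1}\,K^{-1}},$$

with T defaulting to 298.15 K but exposed as a parameter.  This is the
only convention that reproduces the packaged score tables: on the
28-compound NF-κB table the reconstruction agrees with the printed
inhibition constants within 2 % relative for 27 of 28 rows, the one
exception being a compound whose printed mean aggregates docking
replicates with a large spread.  Because the printed energies are
rounded to two decimals, exact digit-level agreement is only defined up
to the propagated rounding band ΔK/K = exp(0.005/RT) − 1 ≈ 0.85 %; the
acceptance suite tests containment in that band rather than digit
equality.

QC correlations (`correlateLbePki()`) are computed on the per-compound
*means* with Pearson's r and a two-sided t-based p-value: score tables
print one value per compound, replicate-level data are not available,
and two-sided is the conservative default when sidedness is unstated.
Missing values are removed pairwise throughout the package because
panel profiles routinely have untested lines.

## COMPARE and oncobiograms

`compareRank()` correlates a compound's log~10~IC~50~ profile against
every agent of an annotated library over their shared cell lines
(minimum overlap 3, configurable).  `moaEnrichment()` counts an agent
as mechanistic evidence when r ≥ 0.30 and p ≤ 0.05 — the one
significance convention the screening literature of this pipeline uses
for correlation tables — and ranks classes by that count, ties broken
alphabetically for determinism.  Only positive correlations count as
class hits: COMPARE infers shared mechanism from profile *similarity*;
negative correlations remain visible in the ranking but are evidence of
collateral sensitivity, not of a shared mode of action.

## Proteome correlates, Ward clustering, χ²

`compareProteins()` correlates each feature of an abundance matrix
(plain matrix or `SummarizedExperiment`) with the profile in one
vectorized pass; `selectTop()` keeps the 20 most directly and 20 most
inversely correlated features (sizes configurable, ties broken by
feature id so the selection is order-invariant).

`wardCluster()` implements Ward's minimum-variance criterion through
the Lance–Williams recurrence (`hclust` on squared Euclidean
distances); reported merge heights are the within-cluster
sum-of-squares increments, which Ward guarantees to be non-decreasing,
and the unit tests verify them against an exhaustive
variance-recomputation oracle to 10⁻⁹.  Distances are Euclidean on
per-feature z-scores by default so that features with different
dynamic ranges contribute comparably; `zscore = FALSE` preserves
raw-value clustering.  Constant features are given unit scale rather
than dropped, so they contribute zero distance.

The heat-map coding (`quartileCode()`) has five categories on
continuous data, which forces an explicit median category: values
exactly equal to the coding unit's median are `MEDIAN`; otherwise bins
are lower-inclusive below the median (`[min, q25)`, `[q25, median)`)
and upper-inclusive above it (`(median, q75]`, `(q75, max]`).  This is
the only reading under which a five-category legend partitions
continuous values, and it makes the four quartile bins balanced (counts
differing by at most 1) on distinct-valued vectors of length 4k+1.

Sensitivity calls are a strict median split of log~10~IC~50~: below the
median sensitive, above resistant, exactly at the median `tie` —
equality is left undefined by a strict-inequality rule, so tie lines
are reported and excluded from the χ² table.  `clusterResponseChi2()`
is Pearson's χ² without continuity correction on the K×2 table of
cell-line cluster versus call, df = K−1; Yates correction is exposed as
a flag.  The defaults cluster the 40 selected proteins into 3 groups
and the cell lines into 2; both K values are arguments, and so is the
axis, because display conventions differ on which dimension carries
numeric versus letter labels.

**Calibration null.**  The type-I error of the cluster–response test is
calibrated with response calls drawn independently of the proteome.
One subtlety matters: when two profiles are simulated on the same
panel *with* the default tissue shift, they correlate weakly through
that shared shift even if their compound-specific components are
independent, and chance-selected features then transmit a small
dependence from clusters to calls, inflating the rejection rate above
its nominal level.  The calibration therefore disables the tissue shift in the
profile that generates the calls, making the null exact; under it the
pipeline rejects at ≈ 5 % (2000 replicates in the acceptance suite).
The inflated variant is not a bug but a faithful property of
correlation-selected signatures on structured panels, and it is the
reason selection and response calls should never be derived from the
same profile when calibrating.

## Resistance-marker screening

`resistanceTable()` reuses the correlation machinery against marker
measurements (transporter expression, copy numbers, functional assays)
and flags associations with *strict* inequalities, p < 0.05 **and**
|r| > 0.30 — a marker at exactly r = 0.30 is not flagged.  Both signs
flag, because a negative correlation (higher marker, lower IC~50~) is
collateral sensitivity and equally reportable.  At n = 60 the magnitude
condition dominates: under independence P(|r| > 0.30) ≈ 2 %, so the
flagged fraction of null markers sits well below the nominal α.

## Binding isotherm

The titration model is the exact 1:1 mass-action solution with ligand
depletion,

$$FB(L) = \frac{(L+T+K_D) - \sqrt{(L+T+K_D)^2 - 4LT}}{2T},$$

evaluated in the catastrophe-free form 2L/(S + √(S²−4LT)).  The
quadratic form is the default because in the emulated experiment the
labelled target (200 nM) is not negligible against the fitted K~D~
(≈ 1 µM); the hyperbolic approximation L/(L+K~D~) is available as
`model = "hyperbolic"`.

`fitKd()` minimizes unweighted squared signal residuals over
(log K~D~, two signal plateaus).  Fitting on the log scale enforces
positivity, makes the fit scale-equivariant in concentration units, and
yields a scale-free curvature from which the standard error is obtained
by the delta method.  Starting values are robust: plateaus from the
low- and high-concentration tertile medians, K~D~ from the mid-signal
crossing.  When the optimizer's gradient is singular (nearly flat
series) the fit falls back to a profiled grid search on log K~D~ with
the plateaus solved as a linear subproblem.  A fit is flagged
`poorlyConstrained` when every point sits below 10 % or above 90 %
fraction bound at the fitted K~D~, or when the standard error is as
large as the estimate.

The generator (`simTitration()`) defaults to a 14-point 1:1 serial
dilution from 300 µM (reaching ≈ 37 nM), target 200 nM, true K~D~
943 nM, and 2 % multiplicative Gaussian noise — noise proportional to
signal, as for normalized fluorescence.  The plateau defaults (1.0
unbound, 0.5 bound) set the amplitude-to-noise ratio so that the
Monte-Carlo replicate spread of the fitted K~D~ is on the order of
±100 nM, the uncertainty scale such an experiment reports; amplitude
and noise are both exposed.

## Expression quantification

`ddctFold()` implements the Livak convention: ΔCt = Ct(target) −
Ct(reference) per group, ΔΔCt = ΔCt(treated) − ΔCt(control), fold =
2^(−ΔΔCt).  The sign convention matters — only −ΔΔCt makes
downregulation come out as a negative log2 fold — and is switchable
(`convention = "literal"`) for data recorded the other way.  No
amplification-efficiency correction is applied.

`ic50FromCurve()` fits a monotone-decreasing four-parameter logistic
with the top constrained to ≤ 110 % and the bottom to ≥ −10 % of
control (viability is a percent scale; small overshoots are measurement
noise, not biology).  When viability never reaches 50 % of control the
IC~50~ is reported as a censored value "> max tested" rather than an
extrapolation, and `degreeOfResistance()` propagates that censoring
through the resistant/parental ratio ("> 7.3-fold" style) instead of
ever emitting a bare number.

## Survival screening

`kmEstimate()`, `logrankTest()` and the per-arm location summaries wrap
the `survival` package: product-limit estimation, Mantel–Haenszel
log-rank with pooled ties and the hypergeometric variance, two-sided
against χ²₁.  `dichotomize()` splits expression at the median by
default (the cutoff is a parameter; quantile splits are supported, and
exact-cutoff values go to the high group and are flagged).
`survivalScreen()` runs dichotomize → log-rank per cohort, determines
the direction from per-arm median survival (restricted mean over
observed follow-up when a median is never reached), and applies
Benjamini–Hochberg across cohorts with pass ⇔ q ≤ 0.05 — the
"FDR ≤ 5 %" retention rule of multi-entity survival mining.

## Synthetic generators

Every analysis input has a seeded generator with recorded ground truth:

- `simPanel()` — 60 lines over the nine NCI-60 tissues (6 leukemia,
  9 melanoma, 6 brain, 7 colon, 7 ovary, 6 breast, 8 kidney, 9 lung,
  2 prostate).
- `simActivity()` — single-factor mode-of-action structure: one latent
  response factor per class, agent profiles mixing factor and noise at
  within-class correlation ρ = 0.8 (91 agents, 10 mechanism classes,
  10 microtubule inhibitors), the query compound tied to one class;
  plus a −0.5 log₁₀ shift for leukemia lines, emulating their uniformly
  higher sensitivity.
- `simProteome()` — 500 features by default (a reduced stand-in for a
  full cell-panel proteome, keeping the test suite fast), 20 + 20
  planted correlates at population r = ±0.6, per-feature arbitrary
  location/scale.
- `simSurvivalCohort()` — exponential event times, arm hazard ratio,
  expression drawn so a median split recovers the arms exactly,
  per-subject random censoring at the stated fraction.
- `simCtTable()` — the treated target Ct offset by minus the true log2
  fold with replicate noise.

Single-factor constructions were chosen over full covariance matrices
deliberately: they realize exactly the planted correlations, are cheap,
and are analytically checkable.  The generators do **not** mimic real
marginal IC~50~ distributions, real proteome covariance, tissue-specific
survival baselines, or plate effects; recovery results on them
demonstrate that the estimators are correct and calibrated under the
assumed structure, not that real screens carry that much signal.

## Problem sizes and tolerances in the test suite

The suites use 60-line panels, 500-feature proteomes, 14-point
titrations and cohorts of 100–200 subjects per arm; Monte-Carlo checks
use 100 seeds for recovery rates, 200 for K~D~ spread, 500 for
FDR/ΔΔCt summaries and 2000 for type-I calibration — sizes at which the
binomial error of an estimated rate (≈ 0.5 % at 2000 replicates) is
well inside the asserted bands.  Oracle comparisons are exact to
10⁻¹² (Pearson, BH) or 10⁻⁹ (Ward heights); the full suite runs in
about two minutes.

## Known limitations

- Pearson-only correlation: the screening convention this pipeline
  reproduces is Pearson's r; rank-based alternatives are not offered.
- The χ² association test relies on the large-sample approximation; on
  60 cell lines with very unbalanced clusters its nominal level drifts
  (the Yates flag is available but conservative).
- `fitKd()` reports curvature-based standard errors, not profile
  likelihood or bootstrap intervals.
- Censored IC~50~ values participate in ratios only as "greater than"
  bounds; no maximum-likelihood treatment of censored dose–response
  fitting is attempted.
- The survival module does no Cox modelling; hazard ratios enter only
  through the generator, and the screen reports direction by median
  survival.
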