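---
title: "Methods: kinase activity deconvolution, Bliss synergy and xenograft effect sizes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinase activity deconvolution, Bliss synergy and xenograft effect sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kamdecon)
```

kamdecon implements the computational stack used to study adaptive resistance
to targeted therapy in functional-kinomics screens: phospho-catalytic plate
assays read out as ATP consumption, Bliss-independence synergy scoring of drug
combinations, zero-normalized effect-size models for multi-arm xenograft
studies, and 2^(−ΔΔCt) expression scoring. Every analysis stage is paired with
a seeded synthetic-data generator with known ground truth, so the whole
pipeline is testable without any external data.

## The plate assay model

Each 384-well plate measures one sample/treatment/replicate condition. A well
contains kinase assay buffer, 250 nM ATP, one 11-mer peptide sensor (or no
peptide, for the background controls) and cell extract; after incubation a
luminescent reagent reports the ATP *remaining*, so kinase activity against a
peptide appears as ATP *consumption*. The default layout carries

* 228 biological peptide sensors, of which 16 are Y/S/T-free peptides (no
  phosphorylatable residue; negative-control substrates) and 63 are reference
  peptides, both carried as tagged subsets *of* the 228 — this makes the
  internal-normalization well count 228 + 14 = 242, consistent with the assay's
  published bookkeeping;
* 14 peptide-free control wells (extract plus ATP, no peptide);
* blank (0 nM ATP) and full-ATP calibration wells.

The luminescence readout is taken to be affine in remaining ATP. No published
slope exists for the instrument, so the package uses the minimal assumption
consistent with a signal that "directly correlates" with ATP: a two-point
linear calibration against the plate's own blank and full-ATP wells (an
explicit slope/intercept can be supplied instead). Consumption is clipped to
[0, 250] nM; negative values are measurement noise around an empty signal and
clipping (rather than erroring) preserves downstream mean-centering. Clip
counts are recorded.

### Normalization and peptide activity

The activity of a peptide is its ATP consumption minus a per-plate
normalization reference. Four schemes are provided: the default
`internal_mean` (mean over the 242 sample-containing wells), `peptide_free`
(14 wells), `ystf_free` (16) and `reference_peptides` (63). Activities are
computed **per replicate and then averaged**. The averaging order is
mathematically irrelevant for the means (subtraction is affine) — a property
the tests assert — but computing per-replicate activities first preserves the
replicate variance needed by the differential t-tests.

### Deconvolution and differential statistics

A kinase's activity is the arithmetic mean of the activities of the biological
peptides it maps to in the peptide–kinase incidence map; kinase families are
just map entries with larger incidence lists, with no special-casing. Only
kinases detected with ≥ 3 distinct peptides are reported; the rest are listed
as omitted. The standard error over the peptide subset accompanies each value.

Treated-versus-control contrasts use two-sample, equal-variance, two-tailed
t-tests uniformly across the package (peptides, kinases, tumor time points,
expression). Kinase-level p-values are computed on per-replicate kinase means
by default: each replicate's peptide profile is deconvoluted first, giving one
kinase value per replicate, and the test runs across replicates. The
alternative — pooling all (peptide × replicate) observations — is available via
`pvalue_on = "pooled_peptides"`; it inflates the nominal sample size with
correlated observations, which is why it is not the default. Degenerate data
follow fixed conventions: identical constant groups give p = 1, constant but
different groups give p = 0 (flagged), fewer than two replicates give NA.

Volcano tables sort by p ascending with deterministic tie-breaks (|Δ|
descending, then unit id). Hierarchical clustering exposes exactly the
distance/linkage vocabulary conventional for these signatures — Euclidean or
(absolute) correlation, centered or uncentered, with Ward (Euclidean only),
complete or average linkage — through `stats::hclust`, which resolves ties by
input order, making leaf orders reproducible.

## Bliss combination index

"Effect" E is the *surviving fraction* relative to untreated: the Bliss
product null E_A · E_B is only multiplicative on survival, and this reading
makes the sign convention come out right (CI > 0 synergy). For a pair,

CI = −log2( E_AB / (E_A · E_B) ),

and for a triple the combined survival E_ABC (drug C fixed at its GI50) is
scored **against the two-drug null**, so a Bliss-independent third drug that
halves survival contributes exactly +1 CI unit. Surviving fractions are
floored at 10⁻³ before the log (configurable) so fully killed wells yield a
large finite CI instead of ∞; negative fractions are a domain error.

GI50 is estimated by log-concentration linear interpolation between the
bracketing doses of a 2-fold dilution ladder (a 4-parameter logistic fit is
available). Grid CI scoring uses the 3 × 3 grid at {0.5×, 1×, 2×} GI50 of each
drug (9 points); measured doses within a factor 1.25 of a nominal grid dose
are accepted, because 2-fold ladders never land exactly on multiples of a
fitted GI50. The extended window takes every measured combination point whose
single-agent survivals both lie in [0.25, 0.75] (i.e. between GI25 and GI75);
with slope-1 Hill curves this yields the same 9 cells, and 12–20 points for
steeper or denser designs. The summary CI is the unweighted arithmetic mean of
per-point CIs, and |CI| ≤ 0.1 is classified additive — a band below plausible
assay noise, configurable. Fold change in drug sensitivity is the log2 GI50
ratio (alone / with modifier) by default; the viability-ratio-at-GI50 variant
is behind a flag since the two differ only for non-parallel curves.

## Xenograft growth effect sizes

Volumes are expressed relative to each mouse's day-1 baseline (100%), then
zero-normalized: for each model and time point the mean relative volume of the
vehicle arm is subtracted, so vehicle is identically centered at 0 and
between-model growth differences drop out. The effect of an arm versus a
baseline arm is then estimated with a Gaussian identity-link linear model of
the adjusted response on a treatment indicator plus a day term (plus fixed
model-identifier terms when models are pooled; no random effects, matching
the fixed-effect pooling convention). The reported effect size is the
*standardized* coefficient of the treatment indicator — response and all
predictors scaled by their standard deviations — with the response negated so
growth inhibition gives a positive effect size ("bigger bar = better drug").
The Gaussian/identity choice follows from the normalization: once the vehicle
trend is removed the response is a roughly symmetric percentage-point
difference, and a standardized linear coefficient is the natural reading of a
"standard coefficient" effect size. The day main effect is included by
default; `include_day = FALSE` treats time points as exchangeable.

Benjamini–Hochberg FDR correction is applied over the family of contrasts in
one analysis run. Per-time-point two-sided t-tests mirror the growth-curve
p-value tracks, with cells marked not-available when an arm has fewer than two
mice remaining — dropout is real in these designs (mice are culled at the
2,000 mm³ welfare cap) and is propagated, never imputed. Waterfall summaries
compare day 21 to day 1 per tumor, cap the displayed relative change at 200%
(twofold the starting volume), and flag regression versus day 1 and versus
mid-treatment (day 10) separately, with per-arm regression percentages.

## Relative expression

ΔCt = mean target Ct − mean housekeeping Ct, where the two reference genes
(ACTB, UBC by default) are combined by the arithmetic mean of their Cts —
equivalent to the geometric mean of their expression quantities, the standard
dual-reference construction. ΔΔCt subtracts the calibrator arm's ΔCt and
rel_level = 2^(−ΔΔCt). Targets with mean Ct above 35 cycles are flagged
unavailable (NA) and propagate. Fold-versus-arm-mean divides each arm's level
by the mean over the three treatment arms, so no single arm is privileged as
calibrator in cross-arm displays; the proportion-lower summary counts strict
inequalities (ties are "not lower") over available (cell line × comparator)
measurements, per gene by default with a pooled option.

## The synthetic generators

Each generator is a deterministic function of its spec and seed and attaches
its ground truth to the output:

* **Plates** — consumption = baseline (20 nM) + the sum of mapped kinase
  activities + Gaussian well noise (1 nM default), clipped to [0, 250];
  Y/S/T-free peptides and peptide-free controls receive baseline only; RLU is
  produced by inverting the affine calibration so conversion is exact. The
  spec rejects parameter combinations whose 3σ envelope leaves the assay
  range.
* **Dose–response surfaces** — slope-1 Hill singles on 2-fold ladders spanning
  0.125×–8× GI50; combination wells deviate from Bliss independence by a
  constant: E = E_A · E_B · 2^(−s), so the ground-truth CI *is* s.
  Multiplicative lognormal viability noise with 5% CV and 3 replicates by
  default, matching routine viability-assay precision.
* **Tumor studies** — per-mouse exponential growth V(t) = V₀·e^((g−τ)(t−1))
  with lognormal measurement noise (σ = 0.1) after the enrollment measurement;
  enrollment at 100–150 mm³, twice-weekly measurement days 1–21, 8 mice per
  arm, dropout from the first breach of the 2,000 mm³ cap. The default
  vehicle growth rate (0.11/day, ≈ 9-day doubling) is typical of untreated
  colorectal xenografts.
* **Ct tables** — target Ct = housekeeping mean + baseline ΔCt − log2(fold) +
  Gaussian cycle noise (0.15 cycles), quadruplicate replicates, so the ΔΔCt
  pipeline recovers the fold matrix exactly in the noiseless case.

What the generators deliberately do **not** emulate: plate-position and batch
effects, luminescence kinetics and quenching, non-Hill (biphasic) response
curves, tumor growth saturation (Gompertz), inter-mouse heterogeneity in
growth rate, and primer-efficiency deviations in qPCR. Passing
parameter-recovery tests therefore demonstrate correctness of the estimators
under their stated models, not robustness to every artifact of real assays.

## Problem sizes and numerical choices

The test and acceptance suites run at desk scale: 200 seeded dose-response
simulations for CI recovery (tolerance ±0.15 at 5% CV), 100 plate simulations
(10 replicates per arm) for top-kinase recovery of a 5 nM shift, 100 xenograft
simulations for GLM sign and ordering recovery, and ≥100 random instances per
brute-force oracle comparison (deconvolution, grid CI averaging, BH
correction, proportion-lower, waterfall counts). Singular designs are marked
not-testable rather than errored; clustering requires finite matrices; the
Hill fit uses Nelder–Mead least squares from an interpolation-based start.

## Known limitations

* The RLU→nM calibration is assumed linear and per-plate; drift within a
  plate is not modeled.
* Combination surfaces are matched to grid doses by nearest measured dose
  (factor ≤ 1.25); strongly off-grid designs should use the GI25–GI75 window.
* The growth model pools models with fixed effects; random-effect or
  AUC-based analyses are out of scope.
* Expression scoring assumes perfect primer efficiency (exact doubling per
  cycle).
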