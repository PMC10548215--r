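---
title: "From canopy reflectance to leaf physiology: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From canopy reflectance to leaf physiology: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the statistical machinery in `canopyspec`, the
assumptions behind it, the parameters that matter, what the synthetic
experiment generator does and does not emulate, and the design choices made
where the problem was genuinely open. It states no numerical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

A hyperspectral imaging booth records raw digital numbers per wavelength for
the plant, a white reference panel (lights on), and a dark reference
(shutter closed). Relative reflectance in percent is the normalized
difference

$$R(\lambda) = 100\,\frac{\mathrm{Plant}(\lambda) - \mathrm{Dark}(\lambda)}
{\mathrm{White}(\lambda) - \mathrm{Dark}(\lambda)}.$$

`calibrate_reflectance()` applies this elementwise and refuses any
wavelength where White ≤ Dark (naming it). Noise can push calibrated values
slightly below 0% or above 100%; these are deliberately **not clipped** —
clipping would bias the weekly and accession means that all downstream
stages consume. Instead `qc_reflectance()` flags spectra with more than 1%
of bands outside [−5, 105]%.

Plants are imaged about three times per week; events within a week are
averaged per plant (`weekly_average()`), and replicate plants of an
accession are averaged within treatment (`accession_mean()`). If a
replicate's spectrum is missing, the remaining replicates represent the
accession mean rather than dropping the accession.

## Wavelength selection

Two selectors serve two tasks:

* **Classification (`select_wsvm()`).** PCA on the *covariance* matrix of
  weekly accession-mean spectra (reflectances share units, so no
  rescaling). The minimal leading set of components whose cumulative
  variance fraction strictly exceeds 0.90 is retained, and the top ten
  wavelengths by |loading| of each retained component are pooled. Absolute
  loadings are used — the sign of a principal axis is arbitrary, and the
  selection is invariant to sign flips.
* **Regression (`rrelieff_rank()`).** The RReliefF estimator for continuous
  responses, with exponential rank-based neighbour weights
  $w_r \propto \exp(-(r/\sigma)^2)$ ("expRank"). For each sampled instance,
  its $k$ nearest neighbours (Manhattan distance on min–max-scaled
  attributes) update three accumulators — probability mass of a changed
  response, a changed attribute, and both — and the final attribute weight
  is $W_a = N_{dC\wedge dA}/N_{dC} - (N_{dA} - N_{dC\wedge dA})/(m -
  N_{dC})$. Weights lie in $[-1, 1]$ and a constant attribute scores
  exactly 0. Defaults follow the reference estimator: $k = 70$ (capped at
  $n-1$), $\sigma = 20$, and $m = 100\,n_{cal}$ iterations. Because
  sampling is with replacement from a finite set, the implementation
  accumulates each distinct instance's contribution once, weighted by its
  draw count — algebraically identical to the per-iteration loop (the test
  suite verifies equality against a literal transcription at $10^{-12}$)
  and fast enough that $m = 100n$ costs little.

Top-$n$ selection (`select_wplsr()`) breaks score ties by ascending
wavelength, so results are deterministic.

## Classification protocol

An SVM (RBF or linear kernel) is tuned by an exponential rough grid — cost
$2^{-5}..2^{15}$, gamma $2^{-15}..2^{23}$, exponent step 2 — under 23-fold
cross-validation, followed by a fine grid at ±$2^{0.5}$ around the rough
optimum with exponent step 0.1; if the rough optimum sits on a lattice
boundary, the fine window is ±2 in the exponent, clipped to the rough
range. Fine parameters are adopted **only** on a strict CV-accuracy
improvement. Folds are stratified by treatment by default (an
accession-grouped mode is available, since 23 folds plausibly meant one
fold per accession; the text does not say). Features are standardised on
the training week and the *same* transform is applied to the evaluation
week — this matters for cross-week evaluation, where the training week's
selected wavelengths are extracted from the evaluation week's spectra.
Diagonal entries of the train-week × eval-week accuracy matrix reuse their
training data and are flagged optimistic.

## Trait prediction protocol

For a trait like leaf nitrogen:

1. complete cases only; 80/20 split stratified by treatment, sampling
   `floor(0.8 · stratum)` per stratum (this rounding is pinned by the
   arithmetic 78 → 62 calibration samples);
2. RReliefF scores computed **on calibration rows only** — the validation
   set never influences selection (a permutation test in the suite checks
   that permuting validation responses changes nothing upstream);
3. top 300/400 wavelengths enter a univariate orthogonal-scores (NIPALS)
   PLSR: centred predictors and response, no scaling (reflectances share
   units), per component $w = X^\top y/\|X^\top y\|$, $t = Xw$,
   $p = X^\top t/t^\top t$, $q = y^\top t/t^\top t$, deflating both $X$
   and $y$;
4. the component count minimises leave-one-out RMSEP over $0..A$,
   $A = \min(20, n_{cal}-2, p)$; ties go to the smaller count; an optimum
   at 0 components (the calibration-mean predictor) is a first-class
   **NotFittable** outcome, reported with its diagnosis, never silently
   skipped;
5. jackknife prediction intervals: refit leaving each calibration sample
   out, variance $(n-1)/n\,\sum_i(\hat y_{(i)} - \bar{\hat y})^2$, normal
   95% interval around the full-model prediction. The normal form was
   chosen over percentile intervals because the jackknife SE is the
   variance machinery the reference PLS implementation exposes; coverage
   is validated by simulation in the test suite rather than assumed.

Metrics: $\mathrm{RMSEP} = \sqrt{\sum(y-\hat y)^2/n}$,
$R^2 = 1 - \sum(y-\hat y)^2/\sum(y-\bar y)^2$, and
$\%\mathrm{RMSEP} = 100\,\mathrm{RMSEP}/\mathrm{range}(y)$. Calibration
metrics use the LOO predictions at the chosen count; validation metrics use
the held-out fifth.

## The synthetic experiment generator

The generator (`synthetic_config()`, `generate_experiment()`) emulates the
study design so that every stage is testable without the archived imaging
data: 23 accessions (15 *indica*, 8 *tropical japonica*), two nitrogen
levels, 22 accessions × 2 replicates × 2 treatments plus one accession ×
3 replicates × 2 treatments = 94 pots, weekly timepoints {6, 9, 10, 13},
three imaging events per plant-week, and a VNIR grid at 2 nm plus a SWIR
grid at 5 nm (601 bands; the junction keeps the VNIR sample at 1000 nm and
starts SWIR one step above). The spectral resolutions are a stand-in — band
counts of the actual cameras are not public — chosen to land in the
300–700-wavelength selection regime the analyses operate in.

Three latent variables drive each plant: *chlorophyll* (visible absorption,
Red-Edge position, leaf N), *water* (1450/1940 nm troughs), *structure*
(NIR plateau, biomass). The spectrum is a sum of Gaussian absorption
features on a smooth baseline with a logistic Red-Edge ramp — it reproduces
the qualitative shape of measured rice canopy spectra without licensing a
radiative-transfer model (PROSPECT-class realism is an explicit non-goal).
The nitrogen treatment shifts the chlorophyll latent (N1 − N2 = 1.0 on the
latent scale), moving the Red-Edge inflection by ~6 nm per latent unit, so
the treatment signal concentrates near 715 nm by construction. Leaf
nitrogen is affine in chlorophyll, $N = 1.4 + 0.9\,\mathrm{chl} + \epsilon$
($\sigma_\epsilon = 0.18$, floored at 0.8% — lower leaf N is not viable
tissue), which puts N in the realistic 1.4–4.4% range and, with carbon
near-constant at 40%, makes corr(N, C:N) ≈ −0.96. Transpiration is exactly
proportional to stomatal conductance (their logs correlate 1.0, as in the
ground-reference data, where E derives from the same gas-exchange record).
Quantum yields are higher under high nitrogen; biomass couples weakly to
the water latent.

Noise has three components, each with a physical reading:

* per-event i.i.d. band noise (0.5%), attenuated by weekly averaging;
* smooth per-plant-week "architecture" bumps (0.4%) — broad Gaussian
  deviations shared by a week's events, emulating pose and canopy-geometry
  differences;
* band-level deviations that persist across a plant-week's events (0.9%),
  emulating segmentation and view-geometry artifacts, scaled by an
  instrument profile: the SWIR detector is noisier than the VNIR one, and
  noise rises steeply in the strong water-absorption bands (~1450,
  ~1940 nm) and toward the range edges, where little reflected light
  reaches the sensor.

The third component is what makes many-wavelength models fragile at small
calibration sizes: smooth nuisance can be *cancelled* by adding wavelengths
(neighbouring bands observe the same bump), whereas high-dimensional
band-level noise can only be *fitted*, and fitting it at $n_{cal} = 38$
with 700 features costs validation accuracy. Week effects: latents drift
mildly with week, and by default week 13 carries a water-stress ×
treatment interaction (high-N plants lose chlorophyll expression and
water), which erodes the treatment signal in the final week — the
cross-week classification degradation is a property of the generator, not
of a particular draw.

`noise_ceiling_r2()` gives the analytic upper bound on validation $R^2$ for
nitrogen: a perfect recovery of the chlorophyll latent explains
$b^2\mathrm{Var}(\mathrm{chl})/(b^2\mathrm{Var}(\mathrm{chl}) +
\sigma_\epsilon^2)$ of the nitrogen variance (≈ 0.91 under defaults). The
test suite checks that the full pipeline's median validation $R^2$ over
20 seeds comes within 0.1 of this bound.

What the generator does **not** emulate: radiative transfer, pixel-level
imagery and segmentation, temporal dynamics finer than weekly, genuine
biochemical couplings for traits other than those listed (leaf carbon is
pure noise around 40%, so carbon models are expected to be not-fittable).
Passing tests therefore demonstrate that the *pipeline* behaves correctly
under the study's statistical structure — not that any particular real
dataset will reach the same accuracies.

One behaviour worth knowing: with a pure-noise response, the argmin-LOO
rule (with RReliefF preselection computed on the same calibration rows)
still admits a weak spurious 1-component model in roughly half of
replicates under default conditions; the rest are correctly NotFittable.
This is a property of minimising LOO RMSEP over 20 candidate counts, not a
bug; a parsimony margin (e.g. a one-SE rule) would suppress it but would
depart from the selection rule the protocol specifies.

## Numerical and degenerate-input choices

* Component search caps at $\min(20, n_{cal}-2, p)$; LOO needs two spare
  rows.
* If deflation exhausts the response (weight norm below
  $\sqrt{\epsilon_{mach}}$), the fit truncates at the last usable component
  rather than producing numerically meaningless directions.
* Ties in RReliefF neighbour distances break by instance index; ties in
  selection scores break by ascending wavelength; `hclust` merge ties
  follow agenda order — all deterministic given input order.
* "Normalized" traits (FB, pQY, mQY) use min–max scaling to [0, 1]; the
  convention was not fixed by the protocol, and min–max keeps quantum
  yields interpretable as fractions of their observed range.
* Clustering standardises traits before Euclidean distances; with mixed
  units (µmol m⁻² s⁻¹ to unitless ratios), raw distances would be
  meaningless. The correlation/PCA trait set uses log(E), log(gsw) in place
  of the raw skewed traits, applied before those analyses.
* Correlation significance is the unadjusted two-sided t test at α = 0.01;
  no multiplicity correction is applied, matching the protocol.
* One global seed is split into per-stage streams by stable string keys
  (`stage_seed()`), so toggling one stage never changes another's draws.

## Problem sizes used in the checks

The test suite runs the full design (94 pots, 601 bands) for single-run
checks; seed-replicated properties use 8–20 seeds; the hyperparameter-grid
check runs the two decisive cells (48 × 700 vs 88 × 300 wavelengths) at 10
iterations, which is where the overfitting contrast lives — the full 10 × 5
lattice at the same iteration count is available through
`analysis/06_hypergrid.R`, and at 100 iterations via its `iterations`
argument.
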