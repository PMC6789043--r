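---
title: "Methods: models, parameters and design choices in cardiophen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in cardiophen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiophen)
```

`cardiophen` quantifies the functional phenotype of stem cell-derived
cardiomyocytes across seven measurement modalities. This vignette is the
package's account of the underlying models, the parameters that matter, the
numerical choices, and the places where the methodology was genuinely open
and a decision had to be made. Its companion is the synthetic-data
generator: every analysis stage ships with a generator that plants known
ground truth, and the test suite validates each stage by parameter
recovery, not by comparison to archived outputs.

## The synthetic transient model

Calcium transients and micropost twitches share one waveform: a flat
baseline, a linear rise to peak over `t_peak`, and an exponential
relaxation with constant τ that is *truncated* — shifted and rescaled as
`(e^(-s/τ) − e^(-T/τ)) / (1 − e^(-T/τ))` over the relaxation window of
length `T` — so each beat returns exactly to baseline before the next
upstroke. Two properties motivate the truncation:

* at physiological pacing (0.5–1 Hz) a pure exponential with τ ≈ 0.6–0.8 s
  retains ~5% of its amplitude at the next upstroke, which would bias the
  measured baseline and fold change by several percent;
* the truncated decay is still of the form `A·e^(-s/τ) + C`, so the
  offset-free exponential fit used by `fit_tau()` recovers exactly the
  planted τ. Recovery is a genuine test of the fit, not an artifact of the
  generator and analyzer sharing code.

The imaging generator plants the fold change on the *background-corrected*
scale: in-cell intensity is `background + F0 + F0·(fold − 1)·w(t)`, so that
after the analyzer's background subtraction the trace has baseline `F0` and
peak `fold·F0`. Default geometry is a 48×48 px field with a centered disc
cell, 50 fps (comfortably above the 20 fps floor below which T50R becomes
unresolvable), 0.5 Hz pacing, 5 beats, and waveform anchors snapped to the
frame grid so the analytic peak is sampled exactly. The generator does not
attempt indicator photophysics (bleaching, saturation), motion artifacts,
or structured background; noise is additive white Gaussian only. Passing
recovery tests therefore demonstrates correctness of the metric
definitions and numerics, not robustness to every artifact of real
microscopy.

## Calcium metrics

`extract_trace()` segments once on the temporal-maximum projection: global
Otsu threshold, largest connected component, morphological closing (5 px
disc). Background is the per-frame median of pixels outside the mask
dilated by 5 px, following the convention that the background estimate must
exclude a guard zone around the cell. Degenerate inputs error ("no
foreground detected"); a mask touching all four borders warns of
truncation.

Per-beat metrics follow fixed conventions where the field has no single
standard:

* **Upstroke onset** is the last sample below `F0 + 5%·(F − F0)` before the
  peak. On an idealized linear rise this sits 5% of the rise time after the
  geometric corner — a small, known definitional offset, accepted because
  the 5% guard is what makes onset detection robust to baseline noise. The
  provisional baseline (segment minimum) and onset are iterated once so
  that `F0` is the mean of the 100 ms window preceding the final onset,
  tie-broken toward earlier samples.
* **Fold change** is reported as `F/F0`; the relative change `(F − F0)/F0`
  is carried alongside as `dF_over_F0`. The published mutant/control group
  means (≈2.0 vs ≈1.5) read naturally as peak-to-baseline ratios.
* **Recovery times** are interpolated sub-sample at the 50%/90% crossings;
  a transient that never crosses 90% has `T90R = NA` and warns.

`fit_tau()` fits `A·e^(-t/τ) + C` by Levenberg–Marquardt
(`minpack.lm::nlsLM`) restricted to samples between the 10% and 90%
relaxation crossings, initialized at `τ₀ = T50/ln 2`, `A₀ = F − F0`,
`C₀ = F0`. Fewer than 3 in-window samples, a non-decaying segment, or a
non-positive fitted τ are errors, not silent results. The test suite
cross-checks the fit against a dense grid search over τ with `(A, C)`
solved exactly by linear least squares at each candidate.

## Action potentials and optical waves

APD is measured from the maximum-dV/dt upstroke (not stimulus onset — the
standard convention) to the interpolated crossing of
`peak − x%·(peak − resting)`; the repolarization reference is the resting
potential, not 0 mV. Resting potential uses the diastolic samples of a
gap-free recording when available (the 20% most negative samples),
otherwise the pre-stimulus mean. Optical wave widths WD50/WD90 are widths
*at* the 50% and 90% repolarization levels, from the interpolated upstroke
crossing to the repolarization crossing, averaged across waves.

The stylized AP generator uses a piecewise-linear repolarization with
anchors placed exactly at the APD50/APD90 crossings, and a single-sample
upstroke so the maximum-dV/dt criterion is unambiguous. The published group
means constrain only APD90; APD50 defaults to 0.8·APD90, a plateau shape
typical of ventricular-like hPSC-CMs. No wave-duration group means are
printed, so the optical-wave generator takes WD50/WD90 as explicit
parameters (defaults 0.40/0.70 s).

## Beat-rate variability and the Poincaré ellipse

The single biggest interpretive choice in the package: published analyses
report "fitted ellipses (95% confidence interval)" on the lag-1 interval
scatter without a formula. `cardiophen` defines the ellipse as the
covariance chi-square ellipse: center at the componentwise mean of
`(BI_n, BI_{n+1})`, axes along the eigenvectors of the sample covariance,
half-lengths `sqrt(qchisq(0.95, 2)·λ)`. The axis ratio
`sqrt(λ_major/λ_minor)` is then a monotone function of the lag-1
correlation ρ; for a stationary Gaussian AR(1) model the population ratio
is `sqrt((1 + ρ)/(1 − ρ))`, an identity the test suite verifies by Monte
Carlo. The generator and analyzer share this definition, which makes
recovery self-consistent — the rotation-search oracle in the tests guards
the eigen-decomposition itself.

Beat events are modeled as stationary Gaussian AR(1) intervals (mean 1.2 s,
SD 0.12 s by default): the only property the Poincaré analysis consumes is
the joint distribution of successive pairs, so a richer point-process model
would add parameters without adding testable structure. At series length
n = 500 the sample axis ratio estimates a population ratio of ~4.4 with a
sampling SD near 10% of its value (and the usual small-sample downward bias
of the AR(1) correlation estimate), which is why the recovery tolerance for
seeded preset series is ±10% where the deterministic stages use 1%.

ΔBI uses absolute first differences; the arrhythmic fraction counts
`ΔBI > 250 ms` with strict inequality. Beat detection uses half-amplitude
prominence over the 10th-percentile baseline with a 0.25 s refractory
period. All-equal intervals make the pair covariance singular; the ellipse
is then flagged undefined rather than fit.

## Micropost mechanics

Deflections are Euclidean distances from rest; when rest positions are not
supplied they are taken from the frame at the 10th percentile of
provisional total deflection (a diastolic frame). Twitch force is the peak
of `Σᵢ k_post·Δᵢ` minus its diastolic baseline (10th percentile); the
absolute peak is reported alongside, since published values do not state
which convention was used (for the generator's waveforms the two coincide —
the twitch returns exactly to rest).

**Power is not defined in the source platform's report.** The package
defines instantaneous mechanical power as total force × total deflection
velocity, reported at its contraction-phase peak, in fW (nN·μm/s ≡ fW) —
the dimensionally consistent choice used in the traction-force literature.
For the package's twitch shape this peak equals `F²/(k·t_peak)`, so when a
preset prints both a twitch force and a power, the generator derives its
rise time from them (e.g. 24 nN and 22 fW give `t_peak ≈ 0.46 s`), making
the simulated recording consistent with both printed group means at once.

## Extracellular flux

Segment summaries default to the mean of all timepoints within an
injection segment; the vendor convention "last rate before the next
injection" is available via `summary = "last"`. On the generator's plateau
time courses the two agree; on noisy data the mean is more stable, which is
why it is the default. The decomposition follows the standard mitostress
definitions, and `ATP + leak + non-mito = basal` holds as an exact
arithmetic identity on every input — the tests assert it at machine
precision under noise.

Published values constrain the three *differences* (maximal OCR, ATP
production, proton leak) but never the non-mitochondrial floor; the
generator uses 10 pmoles/min/cell as a synthetic floor, and no reported
metric depends on it. Noise on a per-segment mean of m points propagates to
difference metrics as σ·√(2/m), a law the suite checks by Monte Carlo.

## Transcriptomic scoring

The net-benefit score needs only the ±1.5-fold DE sets, which are defined
directly on fold changes; the package therefore computes DE as mean
normalized expression with a pseudocount of 1, rather than a full
count-model fit, and "< −1.5-fold" is read on the ratio scale as
`fold < 1/1.5`. Thresholds are strict: a fold of exactly 1.5 is in neither
set. Enrichment is the upper-tail hypergeometric probability
`P(X ≥ overlap)` with no multiple-testing correction — the score
construction uses the two p-values as a ratio, so a monotone correction
would cancel anyway. The score is `log10(p_down) − log10(p_up)`,
antisymmetric under exchanging the up and down sets.

Single-cell QC reads the published thresholds as strict removal rules
("more than 40%", "less than 200", "less than 2000"), so boundary cells —
exactly 40% mitochondrial, exactly 200 genes, exactly 2000 UMIs — are
kept. Cluster heat-map values are per-gene z-scores across all cells,
averaged within cluster; zero-variance genes are flagged as undefined
rows rather than propagating NaN.

## Lipidomics

The species grammar covers the cardiolipin dialect
(`CL(a:b/c:d/e:f/g:h)`, the bracket shorthand, `tetra[a:b]-CL`), MLCL, TG,
AC and FFA, with an optional `-OH` hydroxylation mark on any chain, and
enforces chain-count invariants (CL 4, MLCL 3, TG 3, AC/FFA 1) with typed
parse errors carrying the failing position. "Long-chain" means an acyl
chain of ≥ 14 carbons and "medium-chain" 6–12, matching the species
grouped under those headings in the source tables; both bounds are
arguments, not constants. Chain predicates use any-chain semantics
(a cardiolipin "contains 14:0" if at least one of its four chains is
14:0).

mTIC normalization scales each sample so its summed signal over identified
species equals the cross-sample mean of those sums, unknowns riding along
with the same factor. Note the anchor: rescaling one sample's raw values
changes the cross-sample mean, so normalized *values* are invariant only up
to that global anchor; all within- and between-sample ratios — and hence
the reference-anchored fold-change matrix — are exactly invariant, and
normalization is idempotent. Fold changes on real mass-spectrometry data
are not reproduction targets; the operation is validated on synthetic
tables with planted effects.

## Morphometrics

Circularity is `4πA/P²` with the perimeter from 8-connected
Moore-neighbor boundary tracing and Vossepoel–Smeulders corner-corrected
step lengths (0.980 per axis step, 1.406 per diagonal, −0.091 per
direction change). Naive boundary-pixel counting underestimates the
perimeter of smooth shapes and pushes disc circularity above 1; the
corrected estimator is near-unbiased for smooth convex contours (a
rasterized r = 50 px disc measures ≥ 0.95) at the cost of a small positive
bias for sharp-cornered polygons (a 100×100 px square measures ≈ 0.84
against the ideal π/4 ≈ 0.785). Values are clipped at 1 after correction.
Manders coefficients default to `> 0` positivity so that identical
channels give M1 = M2 = 1 exactly; per-channel Otsu thresholds are an
option. The nucleation comparison is the standard Pearson chi-square on
the 2×4 table (1, 2, 3, ≥4 nuclei), df = 3, with an explicit choice
between erroring and collapsing when a pooled category is empty.

## Problem sizes and reproducibility

All generators are seeded and bit-reproducible given identical arguments;
noise models carry their own seed so a noisy stack can be regenerated
exactly. The test suite and the acceptance script run at deliberately
modest sizes — 5-beat 48×48 px stacks at 50 fps, 10 kHz AP traces,
500-interval beat series (10⁴ for i.i.d. symmetry checks), 6-well plate
assays, a few hundred Monte-Carlo replicates — chosen so the full recovery
suite completes in minutes on a single core while keeping every statistical
tolerance comfortably powered.

## Known limitations

* The generators are validation instruments, not simulators of raw data in
  all its messiness: no photobleaching, motion, focus drift, segmentation
  confounders, batch effects, or heavy-tailed noise.
* `extract_trace()` assumes one connected bright cell on a darker
  background; fields with several cells need upstream cropping.
* The DE layer is a fold-change filter by design; it is not a substitute
  for count-based differential testing when replicate structure matters.
* Micropost analysis starts from post-top centroid time series;
  image-based post tracking is upstream of the package.
* The Poincaré ellipse definition, the power definition, and the AC
  chain-length bounds are documented conventions; alternatives exist in
  the literature, and results should cite the convention used.
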