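# cardiophen

Functional phenotyping of human pluripotent stem cell-derived
cardiomyocytes (hPSC-CMs) in R.

Disease modeling with hPSC-CMs — for example mitochondrial trifunctional
protein (MTP/HADHA) deficiency, where fatty-acid-challenged mutant
cardiomyocytes develop calcium-handling defects, prolonged repolarization,
erratic beating and mitochondrial dysfunction — leans on a battery of
bespoke quantitative readouts that are usually scattered across one-off
MATLAB and ImageJ scripts. `cardiophen` collects those analyses as tested,
reusable R functions, together with a seeded synthetic-data generator whose
presets encode published group means, so that every stage can be validated
by parameter recovery without any external data.

## What it computes

**Calcium transients** (`extract_trace`, `transient_metrics`, `fit_tau`).
The cell boundary is segmented on the temporal-maximum projection (Otsu,
largest component, morphological closing) and the per-frame in-mask mean is
background-corrected. Each transient yields peak fluorescence F, baseline
F0, fold change F/F0, time to peak T_peak, times from peak to 50%/90%
recovery (T50R, T90R), the rates R_peak = (F−F0)/T_peak,
R50R = 0.5(F−F0)/T50R, R90R = 0.9(F−F0)/T90R, and the relaxation constant τ
from a least-squares fit of A·e^(−t/τ) + C restricted to the 10–90%
relaxation window.

**Electrophysiology** (`ap_metrics`, `optical_wave_metrics`). APD50/APD90
from the maximum-dV/dt upstroke to the interpolated crossing of
peak − x%·(peak − resting); optical voltage-dye wave widths WD50/WD90 at
the 50%/90% repolarization levels, amplitude and maximum depolarization
rate.

**Beat-rate variability** (`detect_beats`, `variability_stats`). Beat
intervals BI_n, absolute interval changes ΔBI, the fraction of ΔBI > 250 ms,
and the 95%-confidence covariance ellipse of the Poincaré scatter
(BI_n, BI_{n+1}) — axes along the covariance eigenvectors, half-lengths
√(χ²₀.₉₅,₂ · λ); the major/minor axis ratio indexes beat-to-beat
instability.

**Micropost traction** (`compute_deflections`, `twitch_metrics`). Post
deflections Δ_i convert to total twitch force F_twitch = Σᵢ k_post·Δ_i
(k_post = 56.5 nN/μm, 6 μm spacing by default), twitch velocity, and
contraction-phase peak mechanical power in fW (nN·μm/s).

**Mitochondrial flux** (`normalize_ocr`, `mitostress_metrics`,
`palmitate_utilization`). Per-cell OCR; maximal OCR = FCCP − oligomycin,
ATP production = basal − oligomycin, proton leak = oligomycin −
antimycin/rotenone, non-mitochondrial = antimycin/rotenone level
(ATP + leak + non-mito = basal exactly); palmitate utilization = mean OCR
after the second palmitate addition minus the last rate before it.

**Transcriptomic scoring** (`de_sets`, `hypergeom_enrichment`,
`net_benefit_matrix`, `qc_filter_cells`, `cluster_zscores`). ±1.5-fold DE
sets, upper-tail hypergeometric pathway enrichment, the pathway × condition
net-benefit score −log₁₀(p_up/p_down), single-cell QC (remove cells with
>40% mitochondrial reads, <200 genes, or <2000 UMIs), and marker × cluster
z-score matrices.

**Lipidomics** (`parse_lipid_name`, `mtic_normalize`, `class_summaries`,
`fold_change_matrix`). A parser for the cardiolipin/acyl-carnitine species
dialect (`tetra[18:2]-CL`, `[18:1][18:1][18:2][18:2]`, `AC(16:0-OH)`, ...),
mTIC normalization, class sums under chain predicates (long-chain ≥ C14,
hydroxylated, contains-14:0, ≥ C20), and reference-anchored fold changes.

**Morphometrics** (`shape_metrics`, `colocalization`, `nucleation_test`).
Cell/mitochondrial area and circularity 4πA/P² with a corner-corrected
traced perimeter, Pearson + Manders colocalization, and the 2×4
nucleation-category chi-square test (df = 3).

## Worked example

Simulate a fatty-acid-challenged mutant-line calcium stack (preset group
mean: fold 1.55, τ 0.76 s) with photon noise, and recover its kinetics:

```r
library(cardiophen)

sim   <- gen_imaging("Mut_12D_GlcFA",
                     noise = noise_model("gaussian", sd = 0.4, seed = 7))
trace <- extract_trace(sim$stack)
m     <- transient_metrics(trace, pacing_hz = 0.5)
m
#> <transient_metrics> 5 beats
#> ...
#> average: fold 1.550, T_peak 0.160 s, T50R 0.428 s, T90R 1.134 s

fit_tau(relaxation_window(trace, m, beat = 1), f0 = m$F0[1])
#> <tau_fit> tau = 0.7601 s (A = 63.9, C = 91.1, n = 53, rss = 0.025)
```

The fold change (1.550) and relaxation constant (0.760 s) recover the
preset's encoded group means to within noise. The same pattern runs for
the other modalities, e.g. beat-rate variability and the mitostress
decomposition:

```r
be <- gen_electro("Mut_Glc", "beat_events", n = 500, seed = 42)
variability_stats(be$series)
#> <rhythm_stats> mean BI 1.187 s, mean dBI 0.041 s, 0.0% dBI > 250 ms
#> <poincare_ellipse> 95% CI, center (1.187, 1.187) s, axes 0.361/0.091 s, ratio 3.983

mitostress_metrics(normalize_ocr(gen_ocr("WT_12D_GlcFA")$assay))
#> <mito_metrics> 6 wells (pmoles/min/cell), segment summary 'mean'
#>          basal        max_ocr atp_production    proton_leak       non_mito
#>         106.64         359.00          93.00           3.64          10.00
```

The Poincaré axis ratio (3.98 for this seed) estimates the preset's
population ratio of 4.36 from 500 intervals; the mitostress metrics return
the encoded group means exactly on noiseless input.

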