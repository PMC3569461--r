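# atriasim

Desk-scale simulation of human atrial electrophysiology and electrograms.

Atrial fibrillation is sustained by reentrant waves whose electrogram
signatures — dominant frequency (DF), organization index (OI), and
single/double/fractionated (CFAE) morphology — are used clinically to find
ablation targets, yet the link between a propagation pattern and the
electrogram it writes is hard to study in patients. `atriasim` provides the
full chain needed to study that link on synthetic tissue: a human atrial
ionic cell model with regional heterogeneity and chronic-AF electrical
remodeling, an anisotropic monodomain solver on cable/sheet/ring geometries,
a pseudo-unipolar electrogram forward model, and the standard electrogram
analysis pipeline.

## The model

Cellular kinetics follow the Nygren human atrial action-potential model
(29 state variables; Rush–Larsen gating integration at dt = 0.02 ms).
Five regional variants — crista terminalis (CT), pectinate muscles (PM),
appendages (APG), atrioventricular rings (AVR) and atrial working myocardium
(AWM) — differ only in the maximal conductances of I_t, I_CaL, I_Kr and
I_K1. Chronic-AF remodeling reduces g_t by 85% and g_CaL by 74%, raises
g_K1 to 2.5×, slows fast I_CaL inactivation by 62%, and shifts the I_t
activation and I_Na inactivation curves by +16 and +1.6 mV.

Tissue propagation solves the monodomain equation

    S_v C_m ∂V/∂t = ∇·(D ∇V) − S_v I_ion + I_stim,

with D(x) = σ_l f fᵀ + σ_t (I − f fᵀ) built from per-region conductivities
(CT 0.7, BB/PM/FO 0.5, PV 0.15, isthmus 0.1, SAN 0.05, AWM 0.2 S/m) and
anisotropy ratios (1:9 CT, isotropic SAN/isthmus, 1:2 elsewhere), using
Strang operator splitting on a structured grid (300–700 µm spacing). The
surface-to-volume ratio is calibrated once so the control AWM cable
conducts at 69 cm/s; every other regional velocity is then a prediction.

Electrograms are computed 0.2 mm above the tissue with the large-volume-
conductor approximation, Φe ∝ Σ −∇V·∇(1/r) dV, then processed with the
standard chain: 40–250 Hz band-pass, rectification, 20 Hz low-pass, FFT at
≤ 0.12 Hz resolution; DF is the highest spectral peak in 2–20 Hz and OI the
fraction of band power under the DF peak and its three harmonics (0.75 Hz
windows).

## Worked example

```r
library(atriasim)

## a flutter analogue: one wave circulating a ring sized to CV x 200 ms
rf <- runRingFlutter("remodeled", cycleMs = 200)
rf$table[1, c("df", "oi", "morphology", "meanCL")]
#>         df        oi morphology   meanCL
#> x 5.004883 0.9446854     single 198.8636
```

Every electrode around the ring reports the same dominant frequency
(5.0 Hz — the 200 ms circulation cycle), an organization index near unity,
and single potentials: the electrogram signature of a stable macroreentry.
Contrast with a fractionated synthetic trace:

```r
eg <- synthesizeEGM(cl = 200, duration = 8000, morphology = "cfae")
classifyMorphology(eg)@morphology
#> [1] "cfae"
```

Cell-level and tissue-level quantities come from the same objects:

```r
tr <- paceCell(makeCellParams("AWM", "remodeled"), bcl = 1000, nBeats = 10)
measureAPD90(tr)          # last-beat APD90, ms
#> [1] 68.6

round(runCVTable("control")$cv, 1)  # CT, BB, PV, isthmus, SAN, AWM cm/s
#> [1] 140.5 117.2  57.3  43.5  25.8  68.9
```

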