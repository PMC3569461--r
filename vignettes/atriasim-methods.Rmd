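---
title: "atriasim: models, numerics and design decisions"
author: "atriasim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{atriasim: models, numerics and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it simulates, which
knobs matter, which numerical choices were made where the design was
genuinely open, and what the passing test suite does and does not
demonstrate about real atrial tissue.

## The cellular model

Membrane kinetics are the Nygren human atrial action-potential model: a
29-variable ODE system (membrane potential, 12 gating variables, 7 ionic
concentrations across cytosol/cleft/sarcoplasmic reticulum compartments,
Ca²⁺ buffers and ryanodine-receptor states) at 33 °C with a 50 pF membrane
capacitance. The equations are implemented in C++ (`src/nygren.h`) exactly
as published; regional heterogeneity and disease enter *only* through a
seven-entry parameter vector:

| parameter | meaning | control (AWM) | remodeled |
|---|---|---|---|
| `gt` | max. transient-outward conductance, nS | 7.5 | 1.1 |
| `gCaL` | max. L-type Ca conductance, nS | 6.7 | 1.7 |
| `gKr` | max. rapid delayed-rectifier conductance, nS | 0.5 | 0.5 |
| `gK1` | max. inward-rectifier conductance, nS | 4.2 | 10.5 |
| `tauFCaLScale` | multiplier on fast I_CaL inactivation τ | 1 | 1.62 |
| `itActShift` | I_t activation shift, mV | 0 | +16 |
| `iNaInactShift` | I_Na inactivation shift, mV | 0 | +1.6 |

The five regional variants (CT, PM, APG, AVR, AWM) are pure conductance
overrides (`makeCellParams`); the chronic-AF "remodeled" condition applies
the tabulated conductances plus the three kinetic modifications. Both
shifts are applied to the steady-state curves only, in the depolarizing
direction; time constants are untouched. This is the conventional reading
of "curve shifted by +x mV", and it is exposed as a parameter so the
alternative (shifting the time constants too) can be explored.

Single-cell stimulation uses 6 ms rectangular pulses at twice the
diastolic threshold, which is found per variant by bisection to 1%
(`diastolicThreshold`). A fixed tissue-derived current amplitude does not
translate to an isolated cell; capture at a controlled margin is what
matters for APD measurements.

APD90 is measured from the instant of maximum upstroke velocity to
recovery to (diastolic + 10% of amplitude), with the diastolic reference
taken immediately before the stimulus of that beat — unambiguous even with
incomplete repolarization at short coupling intervals. The restitution
protocol is the conventional S1–S2: ten conditioning beats at a 1000 ms
basic cycle length, then a single premature stimulus at each coupling
interval measured from the last S1 upstroke, one S2 per run; non-captured
intervals are flagged rather than dropped.

### Fidelity and a known limitation

The implementation reproduces the qualitative regional physiology —
CT longest and AVR shortest APD in both conditions, remodeling shortening
every region's APD and compressing the regional dispersion, a flatter and
lower restitution curve under remodeling — and the remodeled APD90s land
within ~15% of the reference regional values targeted by the acceptance
suite. The *control* APD90s, however, come out systematically shorter
(e.g. the AWM variant gives ≈151 ms rather than the ≈282 ms reference).
Every constant of the published equation set has been re-verified (the
model also reproduces the published resting potential of −74.25 mV exactly
and stably under its original parameters), and no single-parameter change
reconciles all ten regional values at once; the reference implementation
evidently carried additional unstated adjustments. We deliberately ship
the published equation set rather than re-tuning conductances to fit the
reference durations: the acceptance suite reports the discrepancy
honestly instead of hiding it inside modified kinetics.

A related consequence: the published resting state is a fixed point only
of the original conductance set. The regional variants (higher g_K1)
settle a few mV more negative over tens of seconds; quiescence tests
therefore use per-variant settled states, and tissue runs start from the
published state, whose residual drift (<10 mV over a minute, far slower
than any protocol) is irrelevant on simulation time scales.

## Tissue: the monodomain solver

Propagation solves S_v C_m ∂V/∂t = ∇·(D∇V) − S_v I_ion + I_stim on
structured cable, sheet and ring grids with node spacing restricted to the
300–700 µm range in which this discretization is validated (530 µm
default). D(x) = σ_l f fᵀ + σ_t (I − f fᵀ) with per-region conductivities
and anisotropy ratios (1:9 CT; isotropic SAN and isthmus; 1:2 elsewhere).
Regions without their own ionic variant (BB, FO rim, PV, isthmus, SAN)
carry AWM cells by default — they are distinguished by coupling, not
kinetics — and the mapping is overridable per model. APG and AVR, which
have ionic variants but no tabulated conductivity, couple like working
myocardium.

Discretization: conservative finite differences — face-averaged
conductivity fluxes for the diagonal tensor terms with zero-flux boundary
faces (periodic on rings), and centred cross-derivative terms with
mirrored indices for rotated fibers. Rows of the assembled operator sum to
zero exactly, so uniform fields carry no diffusion current, and the
operator is invariant to fiber sign flips. Time integration is Strang
splitting at a fixed dt = 0.02 ms in the order reaction(dt/2) →
diffusion(dt) → reaction(dt/2); the diffusion step is explicit, guarded by
a Gershgorin CFL check. Gates use Rush–Larsen exponential updates from
precomputed voltage tables (0.05 mV resolution, linear interpolation);
reversal potentials and concentration powers are refreshed every 0.25 ms
rather than every step, which changes APD90 by <0.5% and halves run time.
Halving dt changes measured conduction velocity by <2%.

**Sv calibration.** Neither the surface-to-volume ratio nor the membrane
capacitance per area is independently constrained here; we fix
C_m = 1 µF/cm² and bisect S_v *once* so that a control AWM cable at its
tabulated 0.2 S/m conducts at 69 cm/s (`calibrateSv`). S_v is then frozen
for all regions and conditions, so the remaining eleven entries of the
velocity table are genuine predictions; they land within ~6% (control) and
~16% (remodeled) of the reference values, preserving the full regional
ordering. The calibrated value (~4.8 × 10⁴ m⁻¹) is an *effective*
parameter: at 530 µm the depolarization front is marginally resolved, so
part of the physical surface-to-volume ratio is absorbed into
compensating the discretization's velocity suppression, exactly as in any
fixed-grid monodomain calibration.

**Conduction velocity** is measured by regressing activation time (time of
maximum dV/dt per node) on distance between the 25% and 75% marks of the
path, excluding stimulus and boundary artifacts; non-monotone activation
along the path (collision, fragmentation) is an error rather than a number.

**Tissue stimulation.** The patch convention (30 µA over ~10 mm²)
translates to ≈140 pA per 50 pF cell at the calibrated S_v — subthreshold
for the small node sets of desk-scale protocols. When that happens the
amplitude falls back to a multiple of the tissue diastolic threshold
(measured by bisection on a reference cable and cached): 2× for cable ends
and extended stimulus lines/areas, 3× for compact patches inside sheets
and rings, which are loaded from all sides. The multiple is deliberately
capped near 3×: far above threshold, a sustained 6 ms pulse drives the
cell model outside its validity range (the inward rectifier's
rectification means nothing opposes the stimulus at strongly depolarized
potentials, and the stimulated cell's Ca²⁺ subsystem destabilizes).

## Electrograms

Pseudo-unipolar potentials 0.2 mm above the tissue use the
large-volume-conductor approximation, Φe = K Σ [−∇V·∇(1/r)] dV, summed
over nodes with central-difference gradients, with K = 1 (every analysis
downstream — DF, OI, morphology — is amplitude-scale-free) and volume
element dx²·h with monolayer thickness h = dx. No truncation radius is
applied by default. Sampling is 1 ms, matching the solver's recording
cadence. The geometry reproduces the expected polarities: an approaching
and passing plane wave writes an RS (positive-then-negative) complex,
collisions write positive-dominant potentials, and a wavefront born under
the electrode that only recedes writes a QS-like negative-dominant one.

## The analysis chain

Processing follows the standard intracardiac recipe: 4th-order Butterworth
40–250 Hz band-pass, rectification, 4th-order 20 Hz low-pass — both
filters applied forward–backward for zero phase so activation timing
survives for cycle-length extraction. Spectra are plain FFT periodograms
(rectangular window) zero-padded to a bin width ≤0.12 Hz (8 s records pad
from their natural 0.125 Hz to 0.061 Hz). DF is the highest peak within
2–20 Hz — the low edge excludes DC/baseline leakage, the high edge is the
post-low-pass support; ties break toward the lower frequency. OI is the
band power inside 0.75 Hz windows centred on DF and its three harmonics
(overlapping windows merged so power is never double-counted) divided by
total band power.

Morphology classification works on the raw trace per 90 ms activation
window (windows centred on envelope peaks; complexes closer than 50 ms
merge). Deflections are signed lobes exceeding 10% of the trace's maximum
absolute deflection. A window is CFAE if fast activity is continuous for
>50 ms without an isoelectric interval, double if it contains exactly two
negative deflections, CFAE if it contains more than two deflections, and
single otherwise. One design decision deserves emphasis: *continuity* is
judged on the slope magnitude |dΦ/dt| of the lightly smoothed trace (an
isoelectric interval is ≥10 ms with slope below 15% of its window
maximum). Amplitude-based criteria at the conventional 5% level fail on
forward-modeled electrograms because slow repolarization waves and filter
tails never return to 5% of the activation amplitude, flagging every
complex as continuous; the slope criterion removes slow content without
introducing band-pass ringing, and separates the generator's three
morphology families with a wide margin (longest runs ≤26 ms for singles
and doubles, ≥67 ms for fractionated complexes, against the 50 ms rule).
Both thresholds remain configurable.

## The synthetic electrogram generator

`synthesizeEGM` builds periodic trains of template complexes at a given
cycle length: a biphasic derivative-of-Gaussian RS complex ("single"), two
negative deflections 40 ms apart with the second at 70% amplitude
("double"), and five alternating low-amplitude deflections spanning ~60 ms
with no isoelectric gap ("cfae"), plus Gaussian activation-time jitter and
additive white noise under an explicit local seed. It emulates the
*timing and morphology statistics* of electrograms — which is exactly what
the spectral and classification code consumes — but none of the
biophysics: no far-field from distant tissue, no amplitude dependence on
wavefront curvature, no respiration/contact artifacts. Passing the
generator-recovery tests therefore validates the analysis chain's
bookkeeping, not its robustness to clinical recordings; the
simulation-driven scenario tests close part of that gap by feeding the
chain forward-modeled electrograms.

## Scenarios and problem sizes

The experiment drivers reproduce mechanism analogues on geometries small
enough for a desk machine, chosen as the smallest domains on which each
mechanism is expressible:

- **CV table** (`runCVTable`): 150-node cables (7.95 cm) per region and
  condition.
- **Ring flutter** (`runRingFlutter`): ring length = measured CV × 200 ms
  (~12.6 cm, ~238 nodes), started from a phase-distributed initial
  condition (one full pre-excited lap, states sampled from a paced cell at
  the target cycle length) and run 5 s so the spectral window is ≥4 s.
  This stands in for a macroreentry around an anatomical obstacle: every
  electrode sees 5.0 Hz, OI ≈ 0.95, single potentials, and <1 ms
  cycle-length dispersion.
- **Cross-field spiral**: 100 × 100 sheet (5.3 cm); S1 plane wave plus an
  S2 quadrant at a delay scanned in 10 ms steps (`scanS2Window`). In the
  remodeled condition (wavelength ≈ CV × APD ≈ 4–5 cm) delays of
  120–140 ms launch a spiral that outlives a 2 s run; in control the
  ~20 cm wavelength cannot re-enter anywhere on the sheet and activity
  self-terminates after the last stimulus.
- **Block line** (`runBlocklineTachycardia`): an 80 × 80 sheet with an
  embedded CT strip (fibers along the strip, 1:9 anisotropy) that leaves a
  free conduction gap at one end. Because the strip's fibers run along it,
  *transverse* velocities of strip and bulk are nearly equal (143/3 ≈
  69/√2 cm/s), so any block must be refractory, carried by the CT/AWM APD
  contrast — large in control (≈199 vs 151 ms) and nearly absent after
  remodeling (≈72 vs 69 ms) in this cell model. The driver therefore
  defaults to the control condition: after two fully recovered
  conditioning beats, a premature beat delivered just below the strip
  (coupling interval found by scanning, default 178 ms) blocks across the
  still-refractory strip, detours through the gap, and re-activates the
  far side and then the strip retrogradely. Electrodes straddling the
  blocked segment record the near-side activation and the 40–90 ms
  delayed retrograde one as double potentials (with fractionation at the
  pivot), while electrodes away from the line record single potentials.
  Since the split exceeds the default 90 ms activation window, this
  scenario's morphology analysis widens it (windowMs = 200,
  mergeMs = 100); sustained anchored reentry does not fit the control
  wavelength on a 4.2 cm sheet and the driver reports the episode's last
  activation instead.
- **Focal AF** (`runFocalAF`): continuous 130 ms focus in one corner of a
  remodeled sheet (150 × 150 default); near-focus electrodes follow the
  focus frequency with high OI, remote tissue shows conduction block,
  lower DF and lower OI. The full-size run takes minutes and is exercised
  at reduced size in the test suite.

All scenarios are deterministic given their configuration; the only
randomness anywhere in the package is the synthetic generator's explicit
seeding.

## Degenerate inputs and error behaviour

Time steps above 0.02 ms are rejected (reaction stiffness); explicit
diffusion instability is caught by a CFL bound before the run; diverging
states abort with the offending time and node rather than returning NaNs;
loss of stimulus capture is an explicit error, as are flat traces in the
spectral chain (<500 ms), fewer than two detected activations in
cycle-length extraction, and undefined DF in OI computation. Electrodes
cannot be placed in the tissue plane (r = 0).

## What the tests show, and don't

The suite validates: exact lookup semantics of the parameter
modules, the discrete operator against a brute-force dense oracle,
conservation (zero row sums), √σ velocity scaling on resolved grids,
time-step robustness, forward-model polarity physics, the spectral
pipeline against a direct DFT oracle and against constructed ground truth,
classifier recovery of generator labels (≥95% over 200 seeded fixtures),
and the scaled-down mechanism signatures above. It does not validate
anatomical realism (no 3D atria, no fiber atlas, no wall thickness), the
absolute control APD90s (see the cellular fidelity note), or behaviour on
clinical signals.
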