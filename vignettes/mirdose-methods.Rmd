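---
title: "Methods: organ- and voxel-level internal dosimetry with mirdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organ- and voxel-level internal dosimetry with mirdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdose)
```

## The problem

Molecular radiotherapy (for example Lu-177 peptide receptor radionuclide
therapy) delivers radiation internally: a radiopharmaceutical accumulates in
organs, decays there over days, and the absorbed dose to each organ is
estimated from a series of quantitative SPECT/CT images. Clinical platforms
implement this chain in mutually incompatible fragments — different
calibration conventions, different fit families, different dose engines —
which makes their results hard to compare and the chain hard to validate.
`mirdose` implements the whole chain as one open pipeline with every stage
testable against analytic ground truth:

1. **Calibration** — a calibration factor converts reconstructed counts to
   activity; its unit algebra is made explicit.
2. **Quantification** — per-organ activity at each time point from a count
   volume, a label map, and the calibration factor.
3. **Kinetics** — time–activity curves are fitted and integrated to the
   time-integrated activity (TIA, MBq h) and its coefficient
   (TIAC = TIA / A0, hours).
4. **Absorbed dose** — three engines: organ-level S values with patient mass
   adjustment, voxel-level local energy deposition (LED) with density
   correction, and dose-voxel-kernel (DVK) convolution, with dose–volume
   histograms.

The organ-level model is the standard MIRD schema: the mean absorbed dose to
a target region is
$D(r_T) = \sum_{r_S} \tilde A(r_S)\, S(r_T \leftarrow r_S)$,
where $\tilde A(r_S) = A_0 \cdot \mathrm{TIAC}(r_S)$ is the time-integrated
activity in the source region and $S$ is the tabulated dose per unit
time-integrated activity for a reference anatomy.

## Units and calibration algebra

All internal quantities use MBq, hours, grams, Gy and mm; acquisition
durations alone are in seconds. A calibration factor is only meaningful
together with the acquisition it was measured on. The supported unit kinds
are `cps_per_MBq` (duration-invariant sensitivity), `MBq_per_count`,
`Bq_per_count` and `Bq_per_intensity` ("intensity" is reconstructed voxel
counts under another name). The conversions are exact and invertible:

$$\mathrm{sensitivity\ [cps/MBq]} = \frac{1}{(\mathrm{MBq/count}) \times
T_\mathrm{acq}\,[\mathrm{s}]}$$

```{r calibration}
bottle <- CalibrationFactor(13.6e-6, "MBq_per_count", AcquisitionMeta(60, 120))
sensitivityCpsPerMBq(bottle)
patient <- rescaleForDuration(bottle, AcquisitionMeta(60, 45))
patient@magnitude                      # x (120/45), sensitivity unchanged
```

A count-based factor applied to a scan of different total duration must be
rescaled by the duration ratio; the implied sensitivity is invariant under
this rescaling, which the test suite checks as a property over random
durations.

## The synthetic phantom: what it emulates and what it does not

No patient images ship with the package, so validation uses a digital
abdominal phantom whose ground truth is available in closed form. Its
defaults are the study conditions the package targets:

| Parameter | Default | Why |
|---|---|---|
| Grid | 128 × 128 × 96 voxels, 4.42 mm isotropic | typical reconstructed SPECT matrix; desk-scale runtimes |
| Time points | 4, 24, 72, 192 h post injection | standard four-point Lu-177 protocol |
| Injected activity | 7200 MBq | one ~7.4 GBq therapy cycle |
| Acquisition | 60 projections × 45 s | patient protocol; calibration scans may differ (e.g. 60 × 120 s) |
| Sensitivity | 10 cps/MBq | order of measured Lu-177 system sensitivities (~9.7–10.2) |
| Organs | liver and spleen at 1.06 g/cm³, two kidneys at 1.05 g/cm³ | fixed densities, no CT conversion |
| Kinetics | mono-exponential; TIAC 3.0 h (liver), 1.5 h (spleen), 0.75 h per kidney | kidney pair ~1.5 h, the clinical order of magnitude for Lu-177-DOTATATE |
| Noise | Poisson per voxel | counting statistics |

Counts are generated directly in image space as
`activity × sensitivity × duration` per voxel: there is **no** projection,
reconstruction, scatter, attenuation, collimator response or partial-volume
blur. Passing tests therefore demonstrate that the analysis chain is
internally consistent and recovers known kinetics and doses from count data
with realistic counting noise — they say nothing about reconstruction
accuracy or segmentation quality on real images. Registration is exercised
with optional integer-voxel translations; rotation is not modelled.

```{r phantom}
spec <- PhantomSpec(dim = c(48, 48, 40), noise = "none")
truth <- phantomGroundTruth(spec)
truth@organs[, c("organ", "mass_g", "tiac_h")]
```

The ground-truth TIAC of a mono-exponential organ is the closed form
`fraction / rate`, which serves as the oracle for every downstream fit.

## Curve fitting and integration

Four families cover the integration behaviours found across clinical
platforms:

* **Mono-exponential** `A exp(-λt)`: least squares on the activity scale
  (Levenberg–Marquardt), started from a log-linear regression; TIA = A/λ.
* **Bi-exponential** `A1 exp(-λ1 t) + A2 exp(-λ2 t)`: initialised by
  splitting the samples into a tail half (slow component) and head
  residuals (fast component). Amplitudes are non-negative by default
  (activity cannot be negative); a wash-in option releases the fast
  amplitude. TIA = A1/λ1 + A2/λ2.
* **Power-exponential** `A t^b exp(-c t^d)` with `c, d > 0`, `b > -1`
  (integrability); TIA by adaptive quadrature on (0, ∞) at 1e-8 relative
  tolerance. Initialised from the mono-exponential fit (b = 0, d = 1), so
  the fit is deterministic and seed-free.
* **Trapezoid with tail**: head on `[0, t1]` either as a straight line from
  the origin (`zero_line`, head = t1·A1/2) or holding the first activity
  constant (`constant`, head = t1·A1); trapezoids between samples; after
  the last sample a mono-exponential tail `A_last / λ_tail`. The default
  tail rate is physical decay only (ln 2 / 159.53 h for Lu-177), the
  conservative clinical convention; effective-rate tails are configurable.

Goodness of fit is reported as the Spearman rank correlation between fitted
and observed activities (1 for any exact monotone fit), plus the residual
sum of squares. No visual assessment is involved.

```{r trapezoid}
tac <- TimeActivityCurve("kidneys", c(4, 24, 72, 192), c(90, 70, 40, 10),
                         A0 = 7200)
f <- integrateTrapezoidTail(tac, "zero_line")
c(TIA_MBqh = tia(f), TIAC_h = tiac(f))
```

**Automatic selection** (`autoSelect()`) fits every applicable family and
picks the lowest small-sample-corrected AICc, with two deliberate numerical
choices. First, AICc is undefined when a family's parameter count leaves no
residual degree of freedom (`n ≤ k + 1`); such candidates are excluded, so
on a four-point curve the four-parameter bi-exponential can only be chosen
when more time points are available. Second, residual sums of squares are
floored at a relative epsilon before entering the criterion, so that two
exact fits of noiseless data compare purely by parsimony (fewer parameters
win). When no exponential family converges, trapezoid-with-tail integration
is the fallback and is flagged as such.

## Dose engines

**S values.** `svalueDose()` implements the MIRD sum with patient mass
adjustment applied to the self-dose term:
`D = Σ A0 · TIAC(src) · S(tgt←src) · adj`, with
`adj = m_ref(tgt)/m_patient(tgt)` when `src == tgt` (non-penetrating
emissions scale inversely with target mass) and 1 otherwise. How tabulated
compilations scale the photon part of cross-organ terms is
compilation-dependent, so cross-term scaling is configurable
(`crossMassScaling = "inverse"`). No published S-value compilation is
bundled; tables load from CSV, and phantom studies can use a synthetic
matched local-deposition table (`matchedSValueTable()`) in which engines
agree by construction.

**Local energy deposition.** Every decay's non-penetrating energy is
absorbed where it is emitted:
`dose = TIA × 3.6e9 decays/(MBq h) × E_local / (density × voxel volume)`.
`E_local` (J per decay) is a configuration input from a decay-data
compilation, not a hard-coded constant; the shipped Lu-177 file carries
2.3697e-14 J (~147.9 keV mean electron energy per decay) and documents that
the user should review it against their preferred compilation.

**Dose-voxel-kernel convolution.** The TIA map is convolved with a
precomputed water kernel of identical voxel spacing (a spacing mismatch is
a hard error — no implicit resampling). Convolution is zero-padded and
linear (FFT-based), so there are no periodic wrap artifacts; energy is
conserved exactly over the padded field, which the tests check to 1e-6.
Density correction is first-order voxel-wise division by relative density;
heterogeneous transport is out of scope. The default kernel profile is an
isotropic exponential with an e-folding length of 0.6 mm, putting the mean
deposition radius (3 × scale = 1.8 mm) at about the maximum beta range of
Lu-177 in water — well below a 4.42 mm voxel, the regime in which
near-local deposition is the right physical picture. Truncated kernels are
renormalised to unit energy (the standard treatment); building a kernel
whose raw grid coverage falls below 99.5% of the analytic whole-space
integral is an error (increase the radius). A radius-0 kernel degenerates
to pure local deposition and reproduces the LED engine bit-for-bit in
water, which doubles as an engine cross-check.

DVHs are cumulative (fraction of VOI volume receiving at least each dose,
default 0.01 Gy bins); the mean dose is always computed from the dose map,
never from the histogram.

## Numerical and design choices

* **Registration** is translation-only exhaustive integer search (default
  radius 5 voxels) maximising normalised cross-correlation with zero fill;
  constant volumes return the zero shift with a warning. VOIs are defined
  once and propagated rigidly, holding volume (hence mass) constant across
  time points. The correlation score is exposed, but no clinical
  registration-quality threshold is defined.
* **Voxel conventions**: 0-based indices, voxel-centre world coordinates,
  spacing from the image header.
* **Masses** come from the label catalogue's fixed densities; no
  HU-to-density curve, and no partial-volume correction anywhere.
* **Checkpoints** (`quantified`, `fitted`, `dosed`) are JSON files written
  per stage; doubles are serialised at 17 significant digits so resuming
  from a checkpoint reproduces an uninterrupted run exactly.
* **Randomness**: the only stochastic element is the phantom's Poisson
  draw, governed by the single seed in the spec/config; fits are
  deterministic by construction.
* **Problem sizes**: the test suite exercises most properties on 32³-scale
  grids and runs the end-to-end recovery at the full default
  128 × 128 × 96 grid, noiseless once and across 100 Poisson seeds
  (~1–2 s per run).

## Known limitations

* No projection/reconstruction simulation: quantification biases from
  scatter, attenuation, collimator response and partial volume are outside
  the model, as is their correction.
* Rotational misalignment is not modelled or corrected.
* Exponential families fit organ-level curves; voxel-level fitting uses
  trapezoid-with-tail only (`tiaMapVoxelTrapezoid()`).
* Cross-organ photon dose is represented only through the S-value table;
  the LED and DVK engines are local by construction.
* Tri-exponential and other extended families, uncertainty propagation,
  bone-marrow and tumour dosimetry, and radiobiological indices (BED/EQD2)
  are not implemented.
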