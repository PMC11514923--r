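---
title: "Quantitative T1 subtraction mapping of blood-brain barrier dysfunction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative T1 subtraction mapping of blood-brain barrier dysfunction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Blood-brain barrier dysfunction (BBBD) lets an intravascular gadolinium
tracer leak into brain parenchyma, where it shortens the local longitudinal
relaxation time T1. Quantitative T1 mapping (qT1) before and after contrast
injection therefore carries a leakage signal: subtracting a post-contrast
qT1 volume from a noncontrast one yields a map whose parenchymal values
reflect extravasated tracer. In focal epilepsy this is of particular
interest for the piriform cortex (PIC), hippocampus and amygdala, where
peri-ictal and interictal BBBD are candidate markers of disease processes.

`qt1bbb` implements the full analysis chain as reusable, tested components:

1. **Relaxometry** — forward SPGR signal model and voxelwise DESPOT1
   (variable flip angle) T1 estimation.
2. **Synthetic data** — a digital phantom producing three qT1 sessions per
   subject (noncontrast, interictal, postictal) and whole cohorts with a
   realistic covariate structure, so every downstream stage is testable
   without any patient data.
3. **Registration** — 6-DOF rigid intra-subject alignment of post-contrast
   sessions to the noncontrast volume.
4. **BBB mapping** — the two subtraction biomarkers
   (ΔqT1_ni = noncontrast − interictal, ΔqT1_ip = interictal − postictal),
   normalization by the superior sagittal sinus (SSS) and ROI readout.
5. **Cohort statistics** — Kruskal-Wallis with Dunn post hoc tests, Glass'
   Δ against the whole cortex, duration-of-epilepsy regressions, and
   memory-stratified analyses.
6. **Pipeline** — `run_subject()` / `run_cohort()` orchestration with a
   YAML config, deterministic given its seed.

## Relaxometry model

The spoiled gradient-echo steady state at flip angle α is

$$S(\alpha) = M_0 \sin\alpha \frac{1 - E_1}{1 - \cos\alpha\, E_1},
  \qquad E_1 = e^{-TR/T_1}.$$

With signals at two or more angles, plotting $S/\sin\alpha$ against
$S/\tan\alpha$ gives a line of slope $E_1$, so
$T_1 = -TR/\log(\text{slope})$ and $M_0$ follows from the intercept
(DESPOT1). With exactly two angles the fit is the exact two-point solution;
with more it is the unweighted least-squares line in the transformed
coordinates.

Defaults: TR = 16.4 ms, TE = 6.7 ms (TE is metadata only — at fixed TE the
T2* weighting is a constant factor absorbed into $M_0$, as usual in VFA
work), flip angles {4, 10, 18, 25}°. That schedule brackets the Ernst angle
of ≈1000 ms tissue at this TR (≈10°), giving T1 sensitivity from white
matter to blood. The schedule is fully configurable because acquisition
protocols vary.

Voxels with non-positive signals, a linearized slope outside (0, 1), or a
fitted T1 outside a plausibility window (default 50–10000 ms) are flagged
invalid. Invalid voxels are masked and propagated, never interpolated, so
they cannot bias ROI means silently.

Numerical behavior (verified by the test suite): the noiseless round trip
through the forward model is exact to float precision; the estimator is
unbiased under magnitude noise, with median relative T1 error ≈2.4% at
per-measurement SNR 50 and ≈1.2% at SNR 100 — the 1/SNR scaling expected
from VFA noise propagation for an unweighted fit at this schedule. B1
inhomogeneity is not modeled; in real data an uncorrected B1 error maps
into a proportional T1 error, which is a known limitation of the method.

## The phantom and what it does (not) emulate

The phantom is schematic geometry, not anatomy: an ellipsoidal brain whose
outer shell is cortex around a white-matter interior, central CSF,
bilateral ellipsoidal hippocampus, amygdala and piriform blobs, and an SSS
segment spanning exactly three consecutive coronal slices at the superior
midline (mirroring how the vascular reference ROI is delineated in
practice). The cortex-white-matter interface carries a fixed sinusoidal
folding pattern: besides being what cortex looks like, the folding breaks
the rotational near-symmetry of a smooth shell — which is exactly what
anchors intensity-based rigid registration in real brains. Baseline T1
values are typical 3 T figures (cortex 1300, white matter 850, CSF 4000,
hippocampus 1350, amygdala 1300, piriform 1300, blood 1650 ms), all
configurable.

**Partial-volume rendering.** Real voxels average tissue over the
acquisition point-spread function. The renderer therefore smooths the
crisp tissue assignment with a Gaussian of width `pv_sigma` (default 0.6
voxel); interiors keep exactly the tissue T1. Setting `pv_sigma = 0` gives
crisp labels for closed-form checks.

**Motion.** Session-to-session repositioning is simulated by re-rendering
the phantom analytically on the rigidly perturbed grid — a moved head is
re-acquired by the scanner, not interpolated from another image. (Creating
"motion" by interpolating a rendered volume injects a rotation-dependent
double-interpolation blur that has no physical counterpart and biases
registration; we measured 1–2° of spurious rotation before switching to
analytic re-rendering.)

**Contrast.** Gadolinium enters through the fast-exchange relaxivity model
$1/T_{1,post} = 1/T_{1,pre} + r_1 C$, with $r_1$ = 5 L·mmol⁻¹·s⁻¹ by
default (literature gadobutrol at 3 T). The vascular concentration at scan
time is a free parameter (the injected dose does not determine it — blood
volume, dilution and kinetics intervene), defaulting to 0.5 mmol/L at the
interictal and 0.6 mmol/L at the postictal scan. The two are independent
to emulate injection-to-scan latency variability; they are also chosen
distinct so the ΔqT1_ip map retains a nonzero SSS reference (with equal
concentrations the ip-map vascular difference is identically zero and
normalization is correctly refused).

**BBBD.** Leakage is parameterized as a fraction λ ∈ [0, 1] of the
concurrent vascular concentration, applied per region and session:
parenchymal concentration = λ · c_vasc. This is the simplest mechanism
that yields the observable of interest — a local T1 reduction proportional
to leaked tracer. Full pharmacokinetic (Tofts) modelling is intentionally
out of scope; λ is an effective, not a physiological, parameter.

What the phantom does **not** emulate: realistic cortical geometry and
thickness, B1/B0 field effects, flow artifacts in the sinus, lesions, and
scanner drift between sessions. Passing tests on the phantom therefore
demonstrate correctness of the computational chain and its statistical
behavior under the modeled effects — not performance on clinical data.

## Registration

6-DOF rigid registration (3 rotations, 3 translations about the volume
center) by multi-resolution Nelder-Mead over a trilinear resampler.
Normalized cross-correlation is the default cost — robust to the global
intensity offsets gadolinium introduces between sessions — with mean
squared error available for noiseless work. Both images are prefiltered
with a σ = 1 voxel Gaussian for the cost evaluation only (the output
volume is resampled from the unsmoothed input): the prefilter equalizes
interpolation-induced blur between the fixed (never interpolated) and the
moving (interpolated) image, removing a small rotation bias, and widens
the capture range. The finest level evaluates the cost on every second
valid voxel; 6-DOF rather than affine because intra-subject same-scanner
sessions need no scaling or shear.

Measured on the default 64³ phantom at SNR 30: perturbations up to 4 mm /
4° are recovered to < 0.1 voxel and < 0.4° (the acceptance suite enforces
< 0.3 voxel / < 0.6° across 20 seeded draws).

**A quantified limitation.** After genuine motion, the realigned volume
has passed through one trilinear interpolation that the noncontrast
reference has not. The resulting blur mismatch dilutes small-ROI readouts:
with 2–3-voxel-radius structures at 1 mm resolution, raw ΔqT1 ROI means
shift by roughly 10–60% of the (small) regional signal, and the 48-voxel
SSS reference reads ~10% low. The bias is systematic across subjects and
sessions, so the rank-based group comparisons, effect-size orderings and
regression slopes the pipeline reports are essentially unaffected, and the
SSS normalization absorbs part of it — the same argument the
internal-reference design makes for real data, where varying vascular
gadolinium would otherwise act through partial-volume effects. Exact
ground-truth equality is guaranteed (and tested) for unperturbed sessions.

## Subtraction biomarkers and readout

`compute_delta()` enforces the session arithmetic (ni: noncontrast −
interictal; ip: interictal − postictal) on co-registered grids with strict
session-label checks; the valid mask is the intersection of the inputs.

"Normalizing by the SSS" is implemented as division of the ΔqT1 map by the
mean ΔqT1 over the SSS label: the normalized biomarker is a dimensionless
fraction of the vascular enhancement, which removes between-subject
variation in central gadolinium concentration (latency, pharmacokinetics,
dose dilution). Division — not subtraction — is the reading consistent
with that purpose, and it makes the normalized map invariant to rescaling
the raw map. A reference mean below 10⁻⁶ of the map's dynamic range is
refused: it would signal no measurable vascular contrast, and dividing by
it would amplify noise without meaning. Normalization happens after
registration and subtraction, on the noncontrast grid.

ROI readout reports the mean and sample (n−1) SD over valid voxels; the
whole-cortex label excludes hippocampus and amygdala by construction
(disjoint labels), matching how those structures are analyzed separately.
Empty ROIs yield explicit missing values with a warning, never a silent
zero. Bilateral structures carry left/right labels; ipsilateral analyses
select the hemisphere recorded as the seizure-onset side and exclude
subjects with unknown side.

## Cohort statistics

* **Kruskal-Wallis** (tie-corrected, chi-square reference) compares the
  per-subject regional means across regions within a subgroup. The
  all-values-identical degenerate case is defined as H = 0, p = 1. Regions
  measured in the same subjects are compared with *unpaired* rank tests,
  replicating the published analysis design faithfully rather than
  switching to a paired alternative; with positively correlated
  within-subject values this choice is conservative (the type-I simulation
  in the acceptance suite confirms rejection rates well below nominal).
* **Dunn post hoc** z statistics use pooled mid-ranks with tie correction;
  two-sided normal p-values are Bonferroni-adjusted and capped at 1 by
  default (the capping is what makes reported values of exactly 1.0
  possible); Holm is available. The two-group case reduces to the
  large-sample rank-sum z, which the tests verify against a brute-force
  ranking oracle.
* **Glass' Δ** divides the mean difference by the *reference* (whole
  cortex) sample SD, with |Δ| > 0.8 flagged as large. One value per
  subject per region enters.
* **Linear models** are OLS with treatment coding and the whole cortex as
  the region reference level, so interaction coefficients read directly as
  slope differences from cortex. Rank-deficient designs are refused with
  the aliased columns named. The injection-to-scan latency enters every
  model; since the published coding is not fully specified, the interictal
  latency accompanies ΔqT1_ni and the postictal latency ΔqT1_ip (the
  natural pairing of injection to map). Note that stacked subject × region
  tables have within-subject correlation (shared intercepts), so naive OLS
  standard errors on them are anti-conservative — a property the published
  analysis shares; slope *estimates* are unbiased either way.
* **Memory impairment** is strictly score < 90 on the normative scale
  (mean 100, SD 10); 90 itself is unimpaired; missing scores exclude the
  subject from memory-stratified analyses. Verbal-memory analyses read the
  left hemisphere, figural the right (material-specific lateralization).
* No additional multiple-testing correction is applied across the scenario
  battery, matching the published analysis, which flags this itself as a
  limitation.

## Synthetic cohorts and calibration

`simulate_cohort()` draws covariates matching the study population:
durations of epilepsy from a clamped gamma (2–44 years, median ≈ 15),
memory scores from the normative N(100, 10²), log-normal latencies clamped
to 18–266 min with median ≈ 34.6, seizure-onset side known with
probability 28/37, subgroup sizes 14 (TLE) and 23 (ETLE) by default.
Biomarker summaries are baseline + group/region effect + duration slope ×
duration + subject intercept + residual on the normalized scale, with
defaults baseline 0.02, slope 0.001 per year, subject SD 0.01, residual SD
0.02 — magnitudes consistent with normalized ΔqT1_ni values of a few
percent of the vascular enhancement.

For the group-specific power scenario, a piriform effect of 0.045
(normalized units, ≈2 between-subject SDs) injected in the TLE subgroup
only was calibrated once by pilot simulation so that the TLE PIC-vs-cortex
comparison rejects while the ETLE one does not in well over 80% of
replicates at n = 14 per group; the calibrated value is frozen in the
acceptance suite.

## Problem sizes and numerical choices

The default phantom is 64³ voxels at 1 mm; module tests use 48³ where a
smaller grid suffices, and statistical simulations use 100–500 seeded
replicates of summary-level cohorts — sizes chosen so the full suite and
the acceptance script run comfortably on a single CPU. Every random draw
derives from an explicit integer seed; identical seeds give bit-identical
phantoms, cohorts and pipeline outputs (the cohort CSV replayed from a
config snapshot is byte-identical, which the tests enforce). Ties in ranks
use mid-ranks; Bonferroni caps at 1; the normalization floor, plausibility
window, and registration settings are all exposed as configuration with
the defaults above.

## Known limitations

* Interpolation partial-volume bias of small-ROI readouts after motion
  correction (quantified above); mitigated by normalization and the
  within-subject design, not removed.
* No B1 correction in the relaxometry; no Rician bias correction (Gaussian
  noise is the default simulation model, Rician optional).
* The leakage parameter λ is effective, not pharmacokinetic; latency
  dependence of vascular concentration is a free parameter, not modeled
  kinetics.
* Unpaired rank tests across within-subject regions replicate the
  published design; a paired alternative would have more power but would
  no longer reproduce the published analysis.
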