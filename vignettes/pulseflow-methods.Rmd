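---
title: "Measuring 3D brain pulsation velocities with PulseFlow: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D brain pulsation velocities with PulseFlow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Fast volumetric MRI sampled at 10 Hz (one whole-brain volume per 100 ms, 3 mm
cubic voxels) resolves the three physiological pulsations that drive
intracranial fluid motion: cardiovascular pulses near 1 Hz, respiratory
pulsations near 0.3 Hz, and slow vasomotor waves below 0.1 Hz. PulseFlow
estimates, voxel by voxel and frame by frame, the three-dimensional velocity
of these pulsations as a vector

$$\vec V = v_{s_x}\hat\imath + v_{s_y}\hat\jmath + v_{s_z}\hat k = v_s\,\hat v,$$

where $v_s = \sqrt{v_{s_x}^2 + v_{s_y}^2 + v_{s_z}^2}$ is the speed and
$\hat v = \vec V / v_s$ the unit direction. Everything downstream — cycle
averages, group contrasts, directional statistics — is built on this
decomposition (`decomposeVelocity()` enforces the identity to machine
precision).

## Dense 3D Lucas–Kanade flow

The velocity solver is a dense 3D Lucas–Kanade scheme: at each voxel the
brightness-constancy constraint $I_x u + I_y v + I_z w = -I_t$ is solved in
the weighted least-squares sense over a Gaussian-weighted window. Choices
that matter:

* **Window**: radius 2 (a $5^3$ window) with Gaussian weights,
  $\sigma = \text{radius}/1.5$. At the 3 mm / 10 Hz regime a cardiac
  displacement is about one voxel per frame, for which a $5^3$ support is
  the smallest window with a reliably conditioned structure tensor. The
  fast-flow phantom analysis uses radius 3 (see below).
* **Gradients**: central differences of the frame *average*, with a
  two-frame temporal difference. Averaging the frames before differentiation
  makes the solve exactly antisymmetric under frame exchange, a property the
  test suite checks.
* **Conditioning**: a voxel is rejected (flagged invalid, velocity zero)
  when the smallest eigenvalue of its $3\times3$ structure tensor falls
  below $10^{-4}$ times the tensor trace. No Tikhonov term is added; the
  threshold plays that role and is exposed in `FlowParams`.
* **Pyramid**: "depth" counts resolution levels above the base (factor-2
  downsampling with Gaussian anti-aliasing, trilinear warping, flow doubled
  on upsampling). Per-band defaults are depth 3 for cardiac, 1 for
  respiratory, 0 for vasomotor — faster pulsations move farther between
  frames and need coarser levels to stay inside the solver's linear range.
  Depth 0 with one iteration reduces exactly to the single-level solve.
  Every level must retain at least 8 voxels per axis, so a $32^3$ phantom
  grid caps the pyramid at depth 2.
* **Edges**: volumes are reflected at their boundaries so the output grid
  equals the input grid.

The solver is validated against an independent brute-force oracle (explicit
per-voxel window loops and `solve()` on the normal equations) to $10^{-8}$,
and against known translations: a 6-voxel shift is recovered to
$\pm 0.5$ voxels with a depth-3 pyramid while the single-level solver fails
it — in our implementation the failure mode is a large overshoot rather than
an undershoot, so the corresponding check asserts "far from truth" rather
than a direction of error.

**What the flow runs on.** Band separation precedes the flow; what the
solver should then consume depends on the displacement regime. In the
sub-voxel regime of the in-vivo bands (cardiac ≈ 1 voxel/frame and below)
the solver input keeps the per-voxel temporal mean
(`bandpassFilter(keepMean = TRUE)`): dense flow then tracks the static
tissue texture as it is carried by the band-limited motion, and the
recovered step equals the material displacement. At phantom flow speeds the
frame-to-frame displacement (7.33 voxels at 22 cm/s) exceeds the texture
correlation length, texture matching is ambiguous (motion modulo the streak
wavelength), and the solver instead runs on the mean-removed band-limited
signal, tracking the large-scale oscillation pattern of the jet — which is
the regime where this family of measurements operated. The sparse tracker
always follows a feature of the oscillatory signal itself (the pulse
nadir), so it always consumes the mean-removed series.

## Band separation and spectra

The canonical bands are cardiac 0.51–5 Hz (lower edge at the group minimum
cardiac rate; upper edge at Nyquist so the harmonics that shape the systolic
dip survive), respiratory 0.08–0.49 Hz (group min–max), vasomotor
0.01–0.08 Hz (fixed by convention, below the ~0.1 Hz Traube–Hering range),
and slow-delta 0.2–2 Hz for the EEG covariate. `deriveBandRanges()`
reproduces this construction from per-subject peak tables.

Filtering is zero-phase with the squared magnitude of an order-4 Butterworth
response (high-pass at the lower edge times low-pass at the upper edge) —
the transfer function of forward–backward Butterworth filtering — applied
spectrally on a mirror-extended record. Time-domain forward–backward IIR
passes were implemented first and abandoned: with the vasomotor band
occupying 0.2–1.6 % of the Nyquist range, order-4 recursions are unusable in
double precision as a single transfer function, and even stable biquad
cascades ring through a 60 s record from the padding kinks. The spectral
application has neither problem, is exactly zero phase (velocity timing is
phase-critical), and the only residual artifact is edge leakage confined to
the outer ~25 % of a record, which the amplitude-ratio estimator trims.
Filters are validated by tone retention (≥ 0.9 in-band), rejection (≥ 10×
one octave out), exact DC removal, and idempotence on in-band tones.

Power maps use a one-sided FFT periodogram with DC kept separately; with
4096 bins at 10 Hz this yields 2048 bins covering 0–5 Hz. The normalization
(two-sided $|X_k|^2/N$, folded) is chosen so Parseval's identity against the
time-domain sum of squares holds to $10^{-6}$ relative error, which the
suite asserts. Whether power or density normalization matched the original
analysis is unknowable from the text, so the object carries an explicit
normalization tag.

Aliasing arithmetic is the standard folding map
$f \mapsto |f - f_s\,\mathrm{round}(f/f_s)|$: a 5.7 Hz pump pulsation
sampled at 10 Hz appears at 4.3 Hz. Note a bookkeeping subtlety with
three-head peristaltic pumps: 30 % of a 20.1 Hz maximum pulse rate is
6.03 Hz, which folds to 3.97 Hz, whereas an observed 4.3 Hz alias implies a
true rate near 5.7 Hz; `generatePumpSignal()` therefore treats the maximum
pulse rate as a free parameter rather than hard-wiring either reading.

## Cycle-locked analysis

Triggers are local minima (signal dips) of the band-passed ROI mean signal —
the cardiac systolic dip in the ACA, respiratory dips in the 4th ventricle,
vasomotor dips in the PCC — with prominence at least 0.5 signal SD and
separation at least $0.5/f_{high}$ s. The trigger feature for the slower
bands is not dictated by any physiological convention we know of; minima are
used uniformly, with rising zero-crossings selectable.

Each inter-trigger cycle of the velocity field is linearly resampled to a
fixed length (9 / 60 / 200 frames for the 0.9 / 6 / 20 s cardiac,
respiratory, vasomotor cycles at 10 Hz) and averaged voxel-wise. Cycles
shorter than 0.4× or longer than 2.5× the median inter-trigger interval are
excluded and counted — a guard against missed and false triggers; the bounds
are deliberately loose so physiological variability is kept. Resampling
preserves the cycle-mean speed of band-limited input to within 2 %.

Directional spread is summarized per voxel by the mean resultant length
$\bar R$ of the unit directions over the cycle and the chord-based angular
deviation $\sqrt{2(1-\bar R)}$ in radians (0 when aligned, $\sqrt 2$ for
antipodal balance). The log-based alternative $\sqrt{-2\ln \bar R}$ is
selectable; the chord form is bounded and behaves better at the very low
$\bar R$ seen in noisy CSF voxels. The estimator is checked against the
closed-form $\bar R$ of the von Mises–Fisher distribution
($\coth\kappa - 1/\kappa$) on simulated draws.

## Group statistics

The awake/sleep contrast is a paired design run as a one-sample sign-flip
permutation test on the subject differences, with family-wise error control
by the permutation null of the map-wise maximum statistic. Sign flips are
enumerated exhaustively whenever $2^n$ does not exceed the requested
permutation count; otherwise they are sampled with the identity flip forced
into the null set (so p-values are never zero). TFCE enhancement uses the
field-standard parameterization $H = 2$, $E = 0.5$, $dh = \max/100$,
26-connectivity, and is validated against a brute-force threshold-sum oracle
and a closed form for uniform clusters,
$k^E h_0^{H+1}/(H+1)$.

Two-sidedness follows the reporting convention of separate positive and
negative contrasts; the calibration suite uses the max-$|t|$ two-sided mode,
which controls the empirical family-wise error at $0.05 \pm 0.02$ over 500
null simulations. Per-frame testing applies no correction across the
9/60/200 cycle frames — a fidelity choice mirroring the original design —
and an across-frame max-statistic mode is a trivial extension left to the
caller (test each frame's maps jointly by pooling).

Directional reversals split each direction component into positive and
negative parts and flag voxels where one part significantly rises while its
counterpart falls; component maps are combined by union (intersection
selectable — the union reading of "combining the resultant maps" is the
weaker and safer claim).

The slow-delta analysis correlates log band-power sums against log
slow-delta power sums after excluding subjects beyond 4 SDs from the mean in
either coordinate (Chebyshev-style stringent acceptance); exclusions are
reported, never silent.

## Synthetic ground truth

No public acquisition exists for this pipeline, so the package ships two
generators whose defaults *are* the study conditions.

**Flow phantom** (`generatePhantom()`): a streaked cylindrical "fruit" with
an impermeable rind, perfused through a 7 mm diameter axial bore, 3 mm
voxels, 10 Hz, 2 Hz pump pulsation, 22 cm/s true peak speed (the first pump
stage). The displacement field is separable — a fixed spatial jet pattern
(axial Gaussian spreading from the bore into the porous flesh, radial
outflow vanishing at the rind) times a sinusoidal temporal factor — and the
texture is advected by sampling a 4× supersampled master texture at
back-displaced positions, which conserves total intensity to well under 1 %.
The peak frame-to-frame displacement is normalized so that
voxels/frame × (voxel size/10) × f_s reproduces the nominal peak velocity
exactly; at 22 cm/s this is 7.33 voxels/frame, deliberately beyond the
single-level solver's range. Speed profiles over the pump cycle show the
characteristic double peak (two speed maxima per cycle at the crest and
nadir of sinusoidal displacement). The texture model (12 angular spokes, a
5.5-voxel axial wavelength, fine blurred noise) is an invention — no texture
model is published — and the peak-speed estimator mirrors the cross-section
practice of averaging per-voxel temporal maxima of the cycle-averaged field
over a bore-entry slice.

**Cohort** (`generateCohort()`): paired awake/sleep series per subject,
built from three band-limited displacement components along orthogonal axes:
a cardiac dip train (duty 0.25, so harmonics exist) at the subject's heart
rate drawn from 1.02 ± 0.15 Hz, a respiratory sinusoid at 0.27 ± 0.05 Hz,
and a 0.05 Hz vasomotor sinusoid. Awake peak displacements are 1 / 0.1 /
0.02 voxels per frame (≈ 3 / 0.3 / 0.06 cm/s), reproducing the magnitude
hierarchy of the three pulsations. Sleep scales the amplitudes inside a
central effect ROI by 0.78 (cardiac — awake exceeds sleep by 22 %), 1.29
(respiratory) and 1.21 (vasomotor), with a smooth transition zone whose
plateau makes the ground-truth ratios exact in the ROI core. The cohort
texture is smoother than the phantom's (4 spokes, 10-voxel axial wavelength,
1.2-voxel noise correlation) so that cumulative cardiac excursions of about
1.4 voxels stay well inside the trackable regime; with the finer phantom
texture, the intensity response saturates and all amplitude information is
destroyed — a generator defect we hit and fixed during development. Each
subject also carries physiological traces, awake/sleep hypnograms (30 s
epochs; sleep stage probabilities W 10 %, N1 43 %, N2 43 %, N3 1 %,
artifact 2 %), and a slow-delta power scalar drawn from a bivariate-normal
construction with correlation +0.5 to log vasomotor power and −0.5 to log
cardiac power — the published evidence fixes the signs, not magnitudes, so
|r| = 0.5 is a one-time choice. `volumes = FALSE` produces only the
subject-level scalars, which is what the 200-replicate coupling-sign checks
need; full 4D volumes at that replication count would be pointless
computation, as the coupling lives entirely in the scalar draws.

**What the generators do not emulate**: MRI physics (no $T_2^*$ weighting,
spin dephasing, or k-space), head motion, scanner drift, non-rigid
anatomy, or EEG waveforms (only stage labels and band-power scalars).
Passing tests therefore demonstrate that the *analysis* recovers known
kinematics under realistic amplitudes, rates and noise — not that the
acquisition chain is modeled.

## Problem sizes and numerical choices

The validation suite runs at deliberately chosen desk scales: the phantom at
$32^3$ voxels × 600 frames (60 s), with dense flow using window radius 3,
depth 2 (the $32^3$ cap), 3 warp iterations; cohort recovery with 2 subjects
at $16^3$ × 60 s per condition; permutation calibration with 500 null
simulations of an 8-pair, $6^3$ design at 500 sign flips (exhaustive: 256);
coupling-sign recovery with 200 scalar replicates at n = 22. Amplitude
ratios are measured as trimmed RMS speed ratios (central 50 % of frames)
inside the effect ROI — trimming exists solely because zero-phase filtering
of short records leaks at the edges. Degenerate inputs error loudly:
zero-TR headers, constant trigger signals, empty bands, all-excluded
regressions; a label with no voxels reports as missing rather than failing.

## Known limitations

* Speeds above ~1 voxel per frame per pyramid level bias the solver; at the
  phantom's 7.33 voxels/frame the recovered peak is accurate only after
  cycle averaging and within the validated 15 %.
* The RMS amplitude-ratio estimator carries a noise floor that biases ratios
  toward 1; at the vasomotor amplitude (0.02 voxels/frame) this costs
  roughly 5–8 % even after trimming.
* Permutation p-values are discrete (resolution $1/n_{perm}$); with 8 pairs
  the exhaustive null has 256 atoms.
* The sparse tracker follows a single extremum; it is included as the
  comparison method and is expected to be the less accurate of the two,
  which the phantom ordering test asserts.
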