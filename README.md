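# PulseFlow

Velocimetry of physiological brain pulsations from fast volumetric MRI.

Fast fMRI sequences sampling the whole brain at 10 Hz (100 ms per volume,
3 mm cubic voxels) capture the three rhythmic drivers of intracranial fluid
motion — cardiovascular pulses (~1 Hz), respiratory pulsations (~0.3 Hz) and
slow vasomotor waves (< 0.1 Hz) — that power CSF/interstitial exchange and
are implicated in glymphatic clearance, which strengthens during sleep.
PulseFlow turns such a 4D series into per-voxel, per-frame 3D velocity
estimates

&nbsp;&nbsp;&nbsp;&nbsp;**V** = v<sub>s<sub>x</sub></sub> **î** +
v<sub>s<sub>y</sub></sub> **ĵ** + v<sub>s<sub>z</sub></sub> **k̂** =
v<sub>s</sub> · **v̂**,

splitting each vector into its speed v<sub>s</sub> (cm/s) and unit direction
**v̂**, and carries the result through the full analysis used in this line
of work:

* **Dense (and comparison sparse) 3D Lucas–Kanade optical flow** with
  multi-resolution pyramids (depths 3/1/0 for the cardiac, respiratory and
  vasomotor bands), Gaussian-weighted 5³ windows, structure-tensor
  conditioning, and exact voxels/frame → cm/s conversion.
* **Spectral tools**: voxelwise FFT periodogram power maps (2048 one-sided
  bins over 0–5 Hz at the 4096-bin default), summed band-power maps,
  zero-phase Butterworth-response band-pass filtering, Nyquist aliasing
  arithmetic, and group band derivation from per-subject physiological
  peaks (cardiac 0.51–5 Hz, respiratory 0.08–0.49 Hz, vasomotor
  0.01–0.08 Hz).
* **Cycle-locked analysis**: trigger detection on ROI signal dips, cycle
  resampling to 0.9 / 6 / 20 s (9/60/200 frames at 10 Hz), cycle-averaged
  velocity maps, speed profiles (including the pulsatile double peak), and
  directional circular statistics (mean resultant vector, angular SD in
  radians).
* **Group statistics**: paired sign-flip permutation tests with TFCE and
  max-statistic FWER control, directional-reversal maps from
  component-wise positive/negative contrasts, spatial power–velocity
  correlation, and log band power vs log slow-delta EEG power regression
  with 4-sigma outlier exclusion.
* **Synthetic ground truth**: a pulsatile porous-medium flow phantom
  (streaked texture advected through a 7 mm bore by a peristaltic-pump
  waveform, with the exact displacement field returned) and paired
  awake/sleep cohorts with known per-band amplitude effects (cardiac ×0.78,
  respiratory ×1.29, vasomotor ×1.21 in sleep) and a coupled slow-delta
  covariate — so the entire pipeline is testable with no acquisition.

## A worked example

Generate the first-stage pump phantom (22 cm/s true peak at 2 Hz), run
dense optical flow on the pump band, and compare the recovered peak speed
with the ground truth:

```r
library(PulseFlow)

ph   <- generatePhantom(PhantomSpec(gridShape = c(32L, 32L, 32L),
                                    durationS = 60, pulseFreqHz = 2,
                                    peakVelocityCmS = 22, seed = 1L))
band <- BandDefinition("pump", 0.5, 5)
filt <- bandpassFilter(ph$series, band)
trg  <- detectTriggers(roiMeanSignal(filt, ph$boreMask), band, 10, "bore")
fld  <- toPhysicalVelocity(
          pyramidalFlow(filt, FlowParams(windowRadius = 3L,
                                         pyramidDepth = 2L,
                                         iterations = 3L)), 3, 10)
d3    <- dim(seriesData(ph$series))[1:3]
entry <- array(FALSE, d3); entry[, , 16:17] <- TRUE
peakSpeedEstimate(fld, ph$boreMask & entry, trg, 10L)
#> [1] 20.83177
cycleSpeedProfile(resampleCycles(fld, trg, 10L), ph$boreMask)$nMaxima
#> [1] 2
```

The recovered peak (20.8 cm/s against the 22 cm/s ground truth, −5%) and
the two speed maxima per pump cycle — flow peaks at both the crest and the
nadir of the sinusoidal displacement — reproduce the phantom validation
behavior. The sparse single-feature tracker on the same data gives
34.5 cm/s (+57%), illustrating why the dense method is the measurement of
choice.

Aliasing above the 5 Hz Nyquist limit:

```r
aliasFrequency(5.7, 10)
#> [1] 4.3
peakFrequency(generatePumpSignal(0.20, 20.1, 60, 10), 10, nfft = 8192L)
#> [1] 4.019775
```

A cohort condition effect, recovered end to end through filtering and flow:

```r
coh <- generateCohort(CohortSpec(nSubjects = 2L, durationS = 60, seed = 7L))
bandAmplitudeRatio(coh$subjects[[1]]$awake, coh$subjects[[1]]$sleep,
                   defaultBands()$respiratory, coh$effectRoi,
                   FlowParams(pyramidDepth = 1L))$ratio
#> [1] 1.220737
```

against the constructed sleep/awake respiratory multiplier of 1.29.

## Command line

A thin CLI over the same functions lives at `inst/cli/pulseflow.R`:

```sh
Rscript inst/cli/pulseflow.R all --config run.yaml --seed 1 --output-dir out/
```

with subcommands `simulate`, `power`, `flow`, `cycles`, `stats`, `all`, and
YAML configuration covering bands, pyramid depths, cycle lengths and
permutation settings (defaults: n_perm 5000, alpha 0.05).
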