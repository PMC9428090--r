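---
title: "Methods: simulating and evaluating a quiet MPRAGE acquisition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating a quiet MPRAGE acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quietmr)
```

## The problem

Most of the acoustic noise of an MRI examination comes from switching the
whole-body gradient coils inside the static field. A resonant head-insert
gradient that oscillates at ~20 kHz — above the audible range — can supply
extra readout encoding while the whole-body gradients run at a reduced slew
rate. The price of the slower whole-body switching is a longer echo and
repetition time (TE 8.9 / TR 17.6 ms here, against 1.9 / 4.2 ms for the
conventional variant), which degrades the T1 contrast an MPRAGE sequence is
run for unless the excitation flip angle is re-optimised.

`quietmr` implements that whole study at desk scale: extended-phase-graph
(EPG) signal simulation and flip matching, gradient waveform and trajectory
construction, a synthetic multi-coil brain phantom, CG-SENSE
reconstruction, A-weighted sound metering and prediction, image SNR/CNR
metrics, and the exact rating statistics (paired Wilcoxon signed-rank,
Cohen's kappa).

## Signal model

`simulate_mprage()` evolves the EPG configuration states through each shot:
inversion (a scalar efficiency in [-1, 1]; -1 is perfect, `NA` omits the
pulse), recovery to the first excitation, a train of spoiled gradient
echoes, and free recovery to the next inversion. Three modelling choices
matter:

* **Ideal spoiling.** Transverse states are discarded at the end of every
  TR. An MPRAGE readout is designed to operate in this regime, and it makes
  the simulator testable against the spoiled gradient-echo (Ernst) closed
  form: without inversion the steady-state echo matches
  $pd\,\sin\alpha\,(1-E_1)/(1-E_1\cos\alpha)\,e^{-TE/T_2^*}$ to 1e-6 over
  randomised parameters. Because spoiling leaves only the lowest
  configuration orders populated, the tracked order count is capped at 8;
  the result is identical to tracking `n_echoes + 2` orders and keeps
  four-thousand-echo convergence tests fast.
* **TI convention.** The protocol's inversion time is interpreted as
  inversion to the *central* echo of the train (configurable). Under linear
  phase-encode ordering the central echo acquires the k-space centre and
  therefore sets the image contrast; it is also the echo the CSF-nulling
  choice of TI = 1000 ms refers to. With the alternative reading
  (TI to the first excitation) the k-space centre of these protocols would
  fall ~1.9 s after inversion, far from any null.
* **T2\* decay.** Echo amplitudes decay with the *effective* transverse
  time: MPRAGE echoes are gradient echoes, and at 7 T grey/white T2\* is
  roughly 33/27 ms, far below spin-echo T2 (~47 ms). The distinction is
  load-bearing: with spin-echo values the long-TE quiet protocol would show
  *more* grey-white contrast than the conventional one at every moderate
  flip angle, the opposite of what the in-vivo comparison found. Default
  tissue values are therefore T1 2000/1200/4300 ms, T2\* 33/27/1000 ms,
  proton density 0.8/0.7/1.0 for GM/WM/CSF — overridable everywhere.

Echo train lengths are not part of the printed protocol; the defaults
(307 conventional, 107 quiet echoes per 3 s shot) are back-computed from
the printed acquisition times (2:24 / 2:44 min at 48 / ~55 shots) and the
matrix and acceleration settings, and fit inside the shot interval.

## Flip-angle matching

`optimize_flip()` sweeps the quiet protocol's flip over a grid (default
1-90 degrees in 0.5-degree steps) and returns the value whose grey-white
contrast is closest to the conventional protocol's, ties broken toward the
smaller angle. "Contrast" is the absolute difference of the mean-over-train
GM and WM signals; a ratio and a normalised difference are available via
`mode`. With the default tissue values the quiet contrast-vs-flip curve
crosses the conventional reference twice (near 6 and near 60 degrees) and
the grid minimum lands on the flatter upper branch; the printed choice of
13 degrees for this sequence pair is recovered only as the *extremum* of
the relative-contrast curves, which suggests the original optimisation used
tissue values or an objective that this package does not have access to.
The matched flip is therefore reported with its whole matching curve
(`$grid`) rather than treated as a single truth.

## Waveforms, trajectories and sampling

`make_trapezoid()` produces the shortest slew- and amplitude-limited lobe
of a requested area (exact after raster rescaling). `make_silent_gradient()`
builds the 20 kHz sinusoid and checks it against the insert coil's limits
(40 mT/m, 5,200 T/m/s; the default 28.6 mT/m drive has peak slew
2*pi*f*A = 3,594 T/m/s). `make_quiet_readout()` combines a reduced-slew
whole-body trapezoid on x with the silent sinusoid on z. Two details are
easy to get wrong:

* the flat top must span an integer number of oscillation periods (clean
  band structure), but the periods-per-sample ratio must *not* be an
  integer — otherwise every kx sample strobes the oscillation at the same
  phase and the zig-zag collapses to a constant kz offset. The default uses
  ~1.2 periods per sample with a period count kept incommensurate with the
  sample count.
* the kz oscillation is centred on each phase encode by a prewinder of half
  the excursion, so the modulation is
  $\kappa(k_x) = -\bar\gamma A/(2\pi f)\cos(2\pi f t(k_x))$, an excursion
  of ±9.7 1/m at the default drive.

At the desk-scale default grid (64 x 64 x 32 voxels at 3.5 mm — a
head-sized 224 x 224 x 112 mm field of view) the excursion spans ±1.09 kz
steps, i.e. three kz bands per readout, the same band structure as the
full-resolution acquisition the protocols describe. This is why the
phantom's voxel default is 3.5 mm rather than the printed 1.0 mm: shrinking
the voxel without shrinking the coil drive would make the silent gradient's
relative excursion physically meaningless at a 64-point matrix.

`caipi_pattern()` builds the sheared undersampling lattice;
`k_trajectory()` integrates waveforms into k-space paths
($\bar\gamma$ = 42.577 MHz/T); the text dialect written by
`write_trajectory()` doubles as the input format for externally measured
(field-camera style) trajectories via `load_measured_trajectory()`.

## Reconstruction

`encode()`/`cg_sense()` implement forward SENSE encoding and unregularised
conjugate-gradient inversion of the normal equations. Cartesian/CAIPI
sampling uses a centred unitary FFT with mask extraction. The quiet
readout's sampling is handled in hybrid space: FFT along x, multiplication
by the wave phase $e^{-2\pi i \kappa(k_x) z}$, FFT along y and z, then the
CAIPI mask — an exact treatment of the oscillating trajectory at Cartesian
cost. Arbitrary trajectories go through a Kaiser-Bessel gridding
interpolator (oversampling 2, kernel width 4, Beatty beta) built as a
sparse matrix, so the adjoint is the exact transpose; the adjoint identity
holds to 1e-6 for all three operator types. CG stops on the relative
normal-equation residual (default 1e-6, 30 iterations): the *data* residual
bottoms out at the noise floor and is recorded as history instead, where it
is monotonically non-increasing. No density compensation is used inside CG
(the normal equations absorb sampling density); none of the test problems
needs regularisation, but a Tikhonov weight is exposed.

## The phantom as synthetic data

`make_brain_phantom()` nests ellipsoids (CSF rim, GM shell, WM core, two
CSF ventricles) with seed-jittered axes; defaults give roughly 40/37/23%
GM/WM/CSF of in-head voxels. `make_sensitivities()` places localised
Gaussian loop lobes (sigma ~0.6 of the head radius) on two z-rings with
spatially varying phase, normalised to unit root-sum-of-squares — the
SENSE-friendly idealisation of a receive array (8 channels by default, a
desk-scale stand-in for a 32-channel array). `make_b1_map()` is a smooth
centre-bright transmit field of mean one, with an optional left-temporal
dip reproducing the left-right asymmetry seen at 7 T; the phantom pipeline
scales each voxel's flip angle by it (the inversion is modelled as
adiabatic, hence B1-robust). `simulate_acquisition()` encodes the
central-echo signal image through the coils onto the requested sampling and
adds complex Gaussian noise with standard deviation `noise_sd` times the
peak k-space magnitude (default 2e-4, which puts the conventional image's
thermal SNR in a realistic range).

What the phantom does *not* emulate: real anatomy and partial-volume
boundaries, susceptibility and off-resonance (T2\* enters only as a decay
constant), motion, and receive-chain imperfections. Passing tests therefore
demonstrate internal consistency of the methods under the stated model, not
in-vivo performance; in particular the in-vivo magnitudes (10% SNR, 20%
CNR, 76 vs 103 dB(A)) are hardware results that the package checks only in
direction.

## Acoustics

`spl_meter()` applies the closed-form IEC 61672 A-weighting in the
frequency domain (exact at every test frequency, no bilinear warping at
20 kHz) followed by an exponential RMS detector (fast = 125 ms, the meter
convention; the named "fast" setting does not fix the constant, so it is a
documented choice). A 1 kHz tone of 1 Pa RMS meters at 93.98 dB(A) — the
94 dB calibrator condition — and `calibrate()` inverts that relation for
recordings in arbitrary units. `predict_pressure()` filters gradient slew
through a `transfer_model()`: the default is a *synthetic* second-order
band-pass (1.2 kHz resonance, Q = 2, -40 dB/decade above 8 kHz) standing in
for a measured bore response and replaceable by a tabulated file. Under it,
the quiet readout (slow trapezoids plus a 20 kHz line that is both
A-attenuated and far above the resonance) predicts ~12 dB(A) lower peak
level than the conventional readout; only this direction is asserted, the
printed 27 dB gap being a property of the real hardware.

## Statistics

`wilcoxon_signed_rank()` discards zero differences (Pratt handling
available), midranks ties, and enumerates all sign assignments exactly up
to n = 15 (normal approximation with continuity and tie corrections above);
it is tested against an independent enumeration oracle and against
`wilcox.test` where the latter is exact. `cohens_kappa()` is the unweighted
estimator. `make_rating_table()` generates subject-experience tables from
target means/SDs for exercising `summarize_repeats()` and
`compare_conditions()`.

## Numerical choices and limitations

* Raster 2.5 us wherever a silent gradient is active (divides the 50 us
  period exactly); 4 us otherwise.
* Quiet whole-body slew limit defaults to 100 T/m/s — the sequence
  documentation says only "reduced"; configurable.
* k-space in 1/m, image grids centred with DC at index floor(N/2)+1,
  unitary FFTs.
* CSF nulling: at the k-space centre the conventional protocol sits in the
  nulling regime (CSF/WM ~ 0.16) while the quiet protocol's longer TR
  genuinely weakens the null (~0.40) — a real cost of the quiet variant,
  not a simulator artefact.
* Problem sizes: module tests run at 32 x 32 x 16 and 16-point grids; the
  full-pipeline checks run at the default 64 x 64 x 32. These sizes were
  chosen so the whole suite exercises every operator at realistic
  conditioning.
* Out of scope: RF pulse design, slice profiles, magnetisation transfer,
  eddy currents/pre-emphasis, room acoustics, autocalibrated sensitivities,
  and any reprocessing of in-vivo data.
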