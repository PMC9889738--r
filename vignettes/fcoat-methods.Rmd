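---
title: "Binary-phase wavefront correction through scattering media: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary-phase wavefront correction through scattering media: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcoat)
```

## The problem

Coherent light traversing a few hundred micrometres of biological tissue is
scattered into a random speckle field: the intended focus is destroyed and
the power that should excite a single target (an imaging voxel, or a neuron
expressing an optogenetic actuator) is spread over a wide granular pattern.
Wavefront shaping counteracts this by pre-distorting the incident wavefront
on a spatial light modulator (SLM) so that, after scattering, the
contributions of all SLM segments interfere constructively at the target.

This package implements, end to end and at desk scale, the *fast multidither
coherent optical adaptive technique* (fCOAT): a parallel, frequency-
multiplexed variant of COAT adapted to a ferroelectric SLM that can only
display two phase levels, 0 and $\pi$, but switches in about a millisecond.
Everything needed to exercise the method is synthesized in code — the
scattering media, the optics, the detector, and a calcium-imaging readout —
so that the method's focusing metrics (peak-to-background ratio, FWHM,
position error, measurement budget, decorrelation robustness) can be
computed and tested without any instrument.

## Scattering media

No tissue model is attempted. Two standard abstractions stand in for brain
slices, skulls, and living tissue, chosen because each has exactly known
statistics to test against:

* **Complex Gaussian transmission matrix** (`make_transmission_matrix()`):
  independent circular-Gaussian entries with $\langle|T|^2\rangle = 1$
  mapping the $M$ active SLM segments to output speckle modes. This is the
  canonical fully-developed-speckle model: the uncorrected output intensity
  is exponentially distributed (unit contrast), and binary-phase correction
  theory predicts an intensity enhancement of about $M/\pi$ at the target.
* **Random phase screen** (`make_phase_screen()`): $\exp(ig)$ on the pupil
  grid, $g$ a correlated Gaussian field with configurable RMS (radians) and
  correlation length (pixels), built by spectrally filtering white noise.
  The screen form feeds the Fourier-optics propagator and yields spatial
  metrics in micrometres. Thicker tissue is emulated qualitatively by larger
  RMS and shorter correlation length; no quantitative mapping from tissue
  thickness to screen parameters is claimed, since none is available.

The *standard strong screen* used throughout the test and acceptance suites
has RMS $2\pi$ rad and correlation length 2 pupil pixels: it fully develops
the speckle (uncorrected focal PBR $\approx$ 1), which is the regime of
interest.

**Dynamics.** Living tissue decorrelates. Media carry a decorrelation time
$\tau$ and a clock; `evolve_medium()` advances them by blending with fresh
draws (a complex Ornstein–Uhlenbeck step), so the field correlation with the
starting medium is exactly $e^{-\Delta t/\tau}$ for the matrix form. For the
screen form the underlying Gaussian phase field is blended with the weight
chosen so the complex field correlation of the *screens* equals
$e^{-\Delta t/\tau}$ for that step; this per-step calibration composes only
to first order across steps, which is ample for the sub-$\tau$ steps used
anywhere in the package. This choice gives an analytically known exponential
decay to test against without inventing tissue physics; it does not model
flow, breathing, or any spatially structured motion. $\tau$ defaults are
qualitative — measured decorrelation times for in vivo preparations are not
available, only focus lifetimes.

## Forward optics

The SLM is conjugated to the rear pupil of a low-NA objective (defaults:
$\lambda = 0.589\ \mu m$, NA = 0.1). The focal field is the centered unitary
2-D DFT of the pupil field (`propagate_to_focus()`), with focal pixel pitch

$$\Delta = \frac{\lambda\, d}{2\,\mathrm{NA}\, n}\ \mu m,$$

for pupil diameter $d$ pixels on an $n$-pixel grid — the calibration that
places the ideal filled-pupil Airy FWHM at $0.514\,\lambda/\mathrm{NA}$
(3.03 μm at the defaults). Note the deliberate modelling choice: the
experimental FWHM of ~3.6 μm reflects an unreported pupil fill factor, so
the model verifies the corrected focus against the documented $< 4\ \mu m$
bound rather than 3.6 μm exactly. The default grid (256 px, 128-px pupil)
oversamples the focal speckle grain 2×, the minimum for trustworthy peak
metrics; FWHM is additionally read off a tenfold-interpolated image.

**Segmentation.** `build_segment_grid()` tiles the square bounding the
pupil disk with $N \times N$ segments and activates those whose cell centre
lies inside the inscribed circle — the area covered by the incident beam.
For $N = 32$ this yields $M = 812$ active segments ($\approx \pi N^2/4$).
Pupil pixels outside active segments carry static (unmodulated) light that
is tracked exactly as part of the reference field. A binary state assigns 0
or $\pi$ to each active segment; by linearity the focal field is affine in
the per-segment phasors, and `precompute_segment_responses()` caches each
segment's complex contribution at the detection pixels so that a
several-thousand-pattern dither sequence reduces to one matrix product.

**Detection.** The feedback is a single scalar: the intensity integrated
over a detection aperture (`detection_aperture()`) emulating the
pinhole/fibre in front of a photomultiplier. The default aperture is one
focal pixel at the target. Enlarging the pupil-scale factor down to 0.2
(five-fold lower effective NA) or enlarging/reshaping the aperture both
produce an enlarged corrected focus; the two mechanisms are implemented
independently and the first is verified as a pure scaling law (FWHM × 5).
Optional detector noise (Poisson at a configurable photon budget plus
Gaussian read noise) exists but defaults to off: all headline metrics are
defined at noiseless feedback.

## The correction algorithm

One correction runs as follows (`run_fcoat()`):

1. **Partition.** The $M$ active segments are split into two halves
   (default: alternating "checkerboard" along the segment ordering, so both
   halves sample the whole pupil; a seeded random partition is available).
   The method itself does not fix the partition; the default keeps
   the reference field a well-mixed sum of $\sim M/2$ speckle contributions.
2. **Dither plan** (`plan_dither()`). Each modulated segment gets a distinct
   integer DFT frequency bin in $[T/4, T/2)$, with $T = 4\max(H_1,H_2)$
   samples per half: the sampling rate is twice the highest modulation
   frequency (Nyquist), and the lowest bin is half the highest so the
   coarsely-resolved low-frequency band is never used. Total budget:
   $2T = 4M$ patterns ($3248 \le 3500$ at $N=32$), at most $4N^2$.
3. **Square-wave dithering** (`build_pattern_sequence()`). A binary device
   cannot display a phase ramp, so segment $i$ toggles between its base
   phase and base $+\pi$ as $s_i(t) = \mathrm{sgn}\cos(2\pi k_i t/T)$ (ties
   to $+1$; at $t = 0$ every segment shows its base value). The unmodulated
   half holds the current mask and acts as the coherent reference.
4. **Demodulation** (`demodulate()`). The detected intensity contains, for
   each segment, the interference cross-term
   $2 A_i A_r \cos(\cdot)\, s_i(t)$ with the reference. Its DFT coefficient
   at bin $k_i$, after removing the dither waveform's own reference phase
   $\psi_i$ (computed from the DFT of the waveform actually displayed, so
   any waveform convention change is absorbed automatically), has its sign
   carried by $\cos\varphi_i$ where $\varphi_i$ is the segment-vs-reference
   interference phase. Binarization to $\{0, \pi\}$ uses the half-open
   quadrant rule: $[0, \pi/2) \cup [3\pi/2, 2\pi) \to 0$,
   $[\pi/2, 3\pi/2) \to \pi$ — exactly the nearest binary level. A bin with
   no signal keeps its base value.
5. **Two-half combination.** The first half is corrected against the second
   half at the base mask; the corrected first half then serves as the
   reference while the second half is dithered; the combined mask is
   re-binarized (the sum of two values in $\{0,\pi\}$ wraps to the binary
   set). One full pass is the default, matching the single-iteration
   operating mode; `iterations` allows more.

**Harmonic crosstalk — a deliberate imperfection.** A square wave carries
odd harmonics. With bins in $[T/4, T/2)$, the aliased third harmonic of
bins $\ge 5T/12$ lands back inside the band at 1/3 amplitude, and
intermodulation products of segment pairs also alias into the band. The
hardware has exactly the same spectra, so no filtering is attempted; the
cost is bounded instead: the per-segment decision agreement with the ideal
binary mask is ~0.85 (independent of $M$), and the achieved feedback
intensity is 0.6–0.85 of an independent greedy coordinate-descent optimum.
Consequently the enhancement slope versus $M$ is about
$0.75 \times 1/\pi \approx 0.24$ rather than the crosstalk-free binary
theory $1/\pi \approx 0.318$, and the corrected-focus PBR at $M = 812$ has
ensemble mean almost exactly 200 with a seed SD of ~40. The occasional low
outlier is the designed single-iteration failure mode — a first-half
reference field that happens to draw a small amplitude — and a second
iteration rescues such runs (verified in the test suite's diagnostics); the
default remains one iteration.

**Validation mode.** `ramp_intensity_series()` replaces the square wave by
the idealized continuous phase ramp; demodulating it recovers the full
interference phase of every segment to $< 0.2$ rad RMS. This mode exists
only to validate the demodulation chain against ground truth — a binary SLM
cannot display it.

**Oracles.** Two independent optimizers, used only in tests: exhaustive
enumeration of all $2^M$ masks ($M \le 16$) and greedy coordinate descent
to convergence. The greedy result matches the exhaustive optimum within 1%
on every tested instance.

## Focus metrics

The analysis pipeline is fixed: dark-offset subtraction (clamped at zero;
200 counts for synthetic camera frames, 0 for noiseless simulated images)
→ tenfold bicubic interpolation (separable Keys cubic convolution,
$a = -0.5$, original pixel centres preserved exactly; written in-package
because no installed package provides cubic-convolution image upsampling)
→ metric. All metrics, including the PBR peak, are read off the
interpolated image, since the focus is only ~2 px wide in the raw frame.

* **PBR** = peak / mean background. The background region is the frame
  excluding a disk of radius 3 nominal FWHM around the target — a
  definition insensitive to the focus itself (the experimental protocol
  does not pin down its background region).
* **FWHM**: horizontal and vertical section lines through the peak, width
  at half of (peak − background mean) with linear interpolation between
  samples; both reported, headline = mean.
* **Position error**: Euclidean distance from the interpolated-image peak
  to the intended target, in μm. Sub-pixel localization comes from the
  interpolation only — no fitting — mirroring the interpolation-based
  workflow the metrics emulate.

## Calcium-imaging readout

`synth_calcium_movie()` generates wide-field movies of disk-shaped neurons
at 10 frames/s: baseline fluorescence $F_0$, stimulation-locked transients
$(1-e^{-t/\tau_r})e^{-t/\tau_d}$ (normalized to unit peak so the configured
amplitude *is* the peak dF/F), per-pixel Poisson noise, and a 200-count
camera offset. The default protocol is 200 ms stimuli every 5 s, nine
stimuli, with a 5 s pre-stimulus baseline.

The response amplitude follows an explicit sigmoid dose–response
$A_{\max} / (1 + e^{-(I - I_{th})/s})$ in the illumination integrated over
the soma. This is a modeling choice, not a biological claim: it reproduces
the threshold phenomenology in which a corrected focus (concentrating the
same power ~200-fold) drives the neuron above threshold while uncorrected
speckle does not. The experimental dF/F figures (~74% strong vs ~23% weak)
set the default amplitude regime only; they are never asserted as targets,
because they depend on biology the generator does not model (indicator
expression, cell state, real dose–response shapes).

dF/F uses the standard $(F - F_0)/F_0$ with a fixed pre-stimulus baseline
window (the cited convention leaves sliding-versus-fixed baselines open;
fixed is chosen and documented here). ROI traces are circular-ROI means
minus a blank-area background ROI. The end-to-end recovery of generator
amplitudes through extraction → dF/F → per-stimulus peaks is within 10% at
default noise.

## What the synthetic tests do and do not show

Passing this suite shows the *algorithm* is implemented correctly and
behaves as the theory of binary-phase correction predicts on media with
exact speckle statistics. It does not validate tissue-specific numbers:
skull/ear PBRs, the 3.6 μm experimental FWHM, focus lifetimes of tens of
seconds, or any real neural response. Those depend on the instrument and
the biology and are represented here only by their statistical mechanisms
(speckle statistics, exponential decorrelation, enhancement scaling,
threshold dose–response).

## Numerical choices and problem sizes

* Grid 256 px, pupil 128 px, $N = 32$ ($M = 812$, $T = 1624$, 3248
  patterns) is the standard configuration for all headline suites: 10 seeds
  for the FWHM/position suite and 5 for the PBR suite, the suite sizes the
  protocol itself prescribes. One correction plus analysis takes a few
  seconds.
* Matrix-medium suites (enhancement scaling, oracle comparisons, dynamics)
  use a few hundred output modes — enough for stable background means.
* Determinism: every stochastic object takes an explicit integer seed and
  restores the caller's RNG state; identical seeds give bit-identical
  media, masks, and artifacts. Derived evolution seeds fold in the medium
  clock so repeated `evolve_medium()` calls draw fresh but reproducible
  noise.
* Degenerate inputs: zero-strength screens are exact identities; flat
  images raise an informative error in FWHM; an empty detection aperture is
  impossible by construction (it snaps to the nearest pixel); decisions on
  signal-free bins default to "no flip"; dynamic media faster than one
  pattern dwell warn and proceed (graceful degradation is the expected
  physics, not an error).

## Command-line interface

`inst/cli/fcoat.R` is a thin wrapper over `fcoat_cli()`, with subcommands
`run-fcoat`, `make-medium`, `metrics`, `calcium-demo`, and `sweep`
(PBR-versus-segment-count tables over $N \in \{16, 32, 64\}$). All
configuration is YAML; images are 32-bit TIFF (peak-normalized, scale in
the manifest); traces are CSV; reports and manifests are JSON carrying
every seed and a config hash, so any run can be reproduced bit-exactly
from its manifest.

## Known limitations

* Thin-screen or matrix media only: no multi-slice propagation, no
  polarization, no absorption.
* The screen form's decorrelation composes exactly only within a step;
  multi-step decay is first-order accurate.
* Harmonic crosstalk is accepted, not corrected; enhancement is
  correspondingly ~25% below crosstalk-free binary theory.
* The calcium generator's dose–response is phenomenological; nothing in it
  should be read as a claim about real neurons.
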