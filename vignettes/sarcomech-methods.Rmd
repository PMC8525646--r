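---
title: "Methods: sarcomere morphometry and muscle mechanics in sarcomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sarcomere morphometry and muscle mechanics in sarcomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcomech)
```

sarcomech implements the quantitative arm of a skeletal-muscle
structure/function study of a myosin-binding-protein-C myopathy model:
ultrastructural morphometry of thick myosin filaments, skinned-fiber
contractile fitting, whole-muscle normalization, calcium-transient
kinetics, tremor-plate burst detection, and two small quantification
helpers (droplet digital PCR allelic abundance and a radiographic
kyphotic index). Because studies of this kind rarely deposit raw
recordings, the package ships a first-class synthetic-data module that
generates every input with known ground truth; all claims the test suite
makes about recovery accuracy refer to those synthetic conditions.

## Electron-micrograph morphometry

### Image model

`gen_em_micrograph()` renders filament cross sections as bright disks
(radius *r*, default 9 nm) at the sites of a hexagonal lattice (center
spacing *d*, default 40 nm) with isotropic Gaussian positional jitter, on
a darker background. Intensities are 0.7 (filament) on 0.3 (background)
with additive Gaussian pixel noise; this matches the qualitative
appearance of osmium-stained transverse sections well enough to exercise
a threshold-based segmenter, and nothing downstream depends on the exact
values. The lattice orientation is drawn from the seed (a fixed
`orientation` can be supplied), so segmentation is exercised at arbitrary
rotations. The generator does **not** emulate photographic EM texture,
staining gradients, section-thickness artifacts, partially overlapping
myofibrils, or actin thin filaments; a pass on synthetic images therefore
demonstrates correctness of the measurement chain, not robustness to
every real-world imaging artifact.

### Segmentation chain

`segment_filaments()` applies, in order: median filter (default 5 px),
binarization (Otsu by default; a fixed threshold is available for
reproducibility across batches), morphological closing (disc radius 3
px), Gaussian convolution smoothing (sigma 1 px), Canny edge detection
(hand-implemented: Sobel gradients, four-direction non-maximum
suppression, hysteresis at 0.5x/1.5x the median nonzero gradient), filling
of closed edge contours, connected-component labeling, and an area filter
(defaults 50-2000 nm^2) with optional border exclusion. Kernel sizes are
stated as defaults, not inferences: they are small relative to a 10-20 px
filament diameter and all sit in `seg_params()`.

Two numerical choices matter:

* **Area measurement.** Pixel counts are taken from the thresholded mask
  restricted to each filled contour, not from the filled contour itself.
  The Canny edge ring sits on the boundary, so counting the filled
  contour inflates a disk of radius *r* by roughly
  \((r+0.5)^2/r^2\) (about +11% at r = 9 px), whereas the smoothed mask
  crosses the threshold at the true boundary and is unbiased to within
  rasterization error (< 2%).
* **Frame padding.** The mask is zero-padded before edge detection so
  that blobs clipped by the image frame still produce closed contours.
  Their truncated areas are flagged (`border`) but their centers remain
  available as spacing neighbors.

### Interfilament distance

`interfilament_distance()` computes, for each focal filament, the mean
center-of-mass distance to its six nearest neighbors (stable tie-break by
label), and reports the across-filament mean minus the equivalent-circle
diameter \(2\sqrt{\bar A/\pi}\). \(\bar A\) is the mean area of the
non-border filaments of the supplied set, or an externally supplied
pooled (e.g. per-genotype) diameter when several images are combined.
Two eligibility rules control edge bias:

* border-touching filaments are never focal (truncated areas) but do
  count as neighbors;
* a filament whose distance to the frame edge is smaller than its own
  6th-neighbor distance is also not focal, because part of its true
  neighborhood may lie outside the analyzed frame. Without this rule the
  6th neighbor of near-edge filaments jumps to the second lattice shell
  and the mean center distance is biased upward by several percent. The
  rule is exact: no unobserved out-of-frame point can be among the six
  nearest of an eligible filament.

A negative corrected distance (equivalent diameter exceeding the center
spacing) is returned with a flag, never clipped.

`estimate_spacing_fft()` provides an independent spectral cross-check:
the radially averaged 2-D power spectrum peaks at the hexagonal *plane*
spacing \(d\sqrt3/2\), so the implied lattice constant is
`spacing * 2 / sqrt(3)`. A peak is only reported when it exceeds 10x the
median in-window radial power; white noise returns an undefined flag.
The sampling protocol (three seeded regions per micrograph jointly
containing > 100 filaments) is enforced by `sample_regions()`.

## Skinned-fiber fitting

All fits use damped least squares (`minpack.lm::nlsLM`) with closed-form
initialization and a relative tolerance of 1e-8 or better; convergence
failures are returned as flagged results, not errors.

* **Force redevelopment.** \(F(t)=F_{res}+(F_{max}-F_{res})(1-e^{-k_{tr}t})\),
  with \(F(0)=F_{res}\) and \(F(\infty)=F_{max}\); \(k_{tr}\) is
  initialized from the 63% rise time. \(F_{res}\) is left unconstrained
  and flagged when negative. The estimate is invariant to uniform force
  rescaling.
* **Tension-pCa.** Submaximal tensions are normalized by the mean of the
  initial and final maximal activations (`normalize_tension()`). The
  sigmoid is the Hill form
  \(P/P_0 = 1/(1+10^{\,n_H(pCa-pCa_{50})})\) (the linearization
  convention presupposes it). Besides the Hill `pCa50`, the two
  x-intercepts of straight lines through the log-odds transform over the
  high- (> 0.5) and low- (< 0.5) activation subsets are reported; the
  split is configurable. Points outside (0, 1) are excluded from the
  linearization, which makes the intercepts noise-sensitive near
  saturation (the kept sub-unity values are selection-biased); on
  noiseless Hill data all three estimates coincide to < 1e-4, and the
  Hill fit is the robust estimator on noisy data.
* **Loaded shortening.** \(L(t)=Ae^{-kt}+C\) over the clamp window;
  velocity is the tangent slope of the fitted curve, reported at clamp
  onset as \(A\,k\). Non-decaying traces are flagged.
* **Force-velocity and power.** \((P+a)(V+b)=(P_0+a)b\) with \(P_0\)
  fixed at the measured isometric force; derived quantities
  \(V_{max}=bP_0/a\), power \(W(P)=P\,V(P)\), and the closed-form optimum
  \(P_{opt}=\sqrt{a(a+P_0)}-a\). Power can be expressed per \(P_0\)
  (relative loads) or absolute, and the fit is consistent between the two
  parameterizations.

## Whole-muscle and calcium features

CSA follows \(m/(L_0\,\rho)\) with \(\rho\) = 1.06 g/cm^3; specific
tension is force / CSA in mN/mm^2 with the cm-to-mm conversion handled
internally. Force-frequency features (peak force, +dF/dT, -dF/dT) are
taken from a baseline-corrected trace after a 5 ms moving-average
smoothing of the derivative — raw differentiation at 1 kHz amplifies
noise; the window is configurable and the features agree with a
central-difference oracle to < 1% on smooth traces. Calcium transients
are expressed as \(\Delta F/F_0\) with \(F_0\) the mean over a 100 ms
pre-stimulus window (gain-invariant by construction); release magnitude
is the peak, release rate the maximal smoothed slope during the stimulus
(time-to-peak is a possible alternative reading; maximal slope is
implemented), and uptake the time constant of a single-exponential decay
fit started where the transient has fallen to 90% of peak, avoiding the
shoulder at train cessation.

## Tremor detection

The recording (1 kHz, minutes-long) is band-passed to 55-65 Hz
(4th-order zero-phase Butterworth), an RMS envelope is computed over a 50
ms window, and bursts are runs where the envelope exceeds the baseline
mean + 3 SD for at least 100 ms (runs separated by < 50 ms are merged
across filter-transient dips). Baseline statistics come from the
lowest-power third of 1 s windows so bursts cannot contaminate them,
making the rule invariant to rescaling the whole signal. Because the
published burst definition is vibration *at* the tremor band, a candidate
event must also carry at least half of its raw-segment spectral power in
the band; broadband noise excursions (a few percent in-band) are thereby
rejected while a burst at signal-to-noise 10 (about 98% in-band) always
passes. Peak frequency per burst is read from the periodogram of the raw,
unfiltered segment, so the in-band check is not circular. An animal is
called positive at >= 3 bursts. The source of these thresholds is a
declared operationalization (the original rule was not published);
all of them are arguments of `detect_tremor()`.

## ddPCR and kyphotic index

Channel concentrations use the Poisson partition inversion
\(\lambda=-\ln(1-p)/v\) (droplet volume default 0.85 nL, the typical
commercial droplet size); the WT-allele fractional abundance
\(\lambda_{VIC}/(\lambda_{VIC}+\lambda_{FAM})\) is normalized to the mean
of the reference (WT) group, which makes a pure-WT sample exactly 1 and a
balanced heterozygote about 0.5 — the direction of normalization is fixed
by that expected pattern. Saturated channels (all droplets positive) are
errors, not infinities. The kyphotic index is the C7-L6 chord length
divided by the perpendicular distance from the dorsal apex to the chord
(the operative definition adopted here); it is similarity-invariant and
undefined (error) for collinear landmarks.

## Reference study conditions and problem sizes

The test suite and the acceptance script use: 20 micrographs of 512 x 512
px at 1 nm/px (about 170 interior filaments each; d = 40 nm, r = 9 nm,
jitter 1 nm, noise SD 0.05); 100 noisy force-redevelopment traces at
signal-to-noise 20; 50 tension-pCa datasets at noise SD 0.03; 50 tremor
recordings of 60 s (25 with five 0.5 s bursts at 60 Hz and amplitude/noise
ratio 10, 25 noise-only); and 20,000-droplet ddPCR samples. These sizes
were chosen so each stage has enough replication for stable medians while
the whole pipeline re-runs in a few minutes on a single core. Recovery
statements (e.g. median k_tr error < 2%) are computed by the tests and
`scripts/acceptance.R`, never asserted from memory.

## Known limitations

* The EM generator produces non-overlapping, equal-radius disks; merged
  or touching filaments, out-of-plane tilt and real EM texture are not
  modeled, and the area filter's upper bound (2000 nm^2) is the only
  defense against merged blobs.
* The linearized tension-pCa intercepts degrade quickly with noise near
  saturation (see above); they are reported for completeness, with the
  Hill estimate as the primary value.
* Tremor detection assumes a stationary noise floor; slow drift in
  platform noise would require re-estimating baseline statistics in
  blocks.
* `cohort_summary()` delegates all hypothesis tests to the standard
  routines and does not correct for multiple comparisons.
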