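# sarcomech

Quantitative analysis pipeline for skeletal-muscle structure/function
studies of sarcomeric myopathies, built around the measurements used to
characterize a myosin-binding-protein-C (MYBPC1) missense-variant mouse
model: electron-micrograph thick-filament morphometry, skinned
single-fiber contractile fitting, whole-muscle force normalization,
calcium-transient kinetics, force-plate tremor burst detection, and small
quantification helpers (ddPCR allelic abundance, kyphotic index). It is
aimed at muscle physiologists who want these measurements as tested,
scriptable functions rather than one-off lab scripts.

Because raw recordings in this field are rarely deposited, the package
includes a synthetic-data module (`gen_*` functions) that generates every
input with known ground truth, so the whole pipeline is verifiable end to
end.

## What it computes

* **EM morphometry** — thick filaments are segmented by median filtering,
  thresholding/closing, convolution smoothing and Canny edge detection
  with contour filling; per-filament cross-sectional area (CSA) is the
  thresholded pixel count times the squared physical scale. The
  interfilament distance is the mean center-of-mass distance of each
  focal filament to its 6 nearest neighbours minus the equivalent-circle
  diameter `2*sqrt(mean_area/pi)`. An FFT estimator provides an
  independent lattice-spacing cross-check (hexagonal plane spacing
  `d*sqrt(3)/2`).
* **Fiber mechanics** — force redevelopment
  `F(t) = F_res + (F_max - F_res)(1 - exp(-k_tr t))`; tension-pCa Hill
  fit `P/P0 = 1/(1 + 10^(n_H (pCa - pCa50)))` plus the two x-intercepts
  of the linearized (log-odds) fits; loaded shortening
  `L(t) = A exp(-kt) + C` with onset velocity `A*k`; Hill force-velocity
  `(P + a)(V + b) = (P0 + a) b` with power-load curve `W(P) = P*V(P)` and
  closed-form optimum load `sqrt(a(a+P0)) - a`.
* **Whole muscle / calcium** — CSA from `mass / (L0 * 1.06 g/cm^3)`,
  specific tension in mN/mm^2, force-frequency features (peak force,
  +dF/dT, -dF/dT), and calcium-transient metrics (peak dF/F0, maximal
  release rate, single-exponential uptake time constant).
* **Tremor** — 55-65 Hz band-pass, RMS envelope, baseline-relative
  threshold with band-power validation per burst; per-genotype incidence.
* **Quantification** — Poisson-corrected ddPCR fractional abundance
  normalized to the WT group; chord/perpendicular kyphotic index; cohort
  mean +/- SEM tables with standard tests.

## Worked example

```r
library(sarcomech)

m  <- gen_em_micrograph(c(512, 512), d_nm = 40, r_nm = 9, nm_per_pixel = 1,
                        jitter_sd = 1, noise_sd = 0.05, seed = 42)
fs <- segment_filaments(m)
mr <- interfilament_distance(fs)
c(csa = mr$mean_csa, ifd = mr$mean_interfilament_distance, n = mr$n_filaments)
#>       csa       ifd         n
#> 249.94706  22.20784 193.00000
```

The generator placed disks of radius 9 nm (true CSA `pi * 81 = 254.5`
nm^2) on a 40 nm hexagonal lattice; segmentation recovers the mean CSA
within 2% and the interfilament distance (center spacing minus
equivalent diameter, truth `40 - 18 = 22` nm) within 1%.

```r
tr <- gen_mechanics_data("ktr", list(F_max = 1, k_tr = 10, F_res = 0.05),
                         noise_sd = 0.95 / 20, seed = 1)
fit_ktr(tr)[c("F_max", "k_tr", "F_res")]
#> $F_max
#> [1] 0.9984727
#> $k_tr
#> [1] 10.02256
#> $F_res
#> [1] 0.05660792
```

The full study-shaped workflow lives in `analysis/01_simulate.R` ...
`analysis/06_quantify.R`: numbered drivers that generate synthetic
cohorts, run each measurement stage, print what they find, and write
tables under `results/`.

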