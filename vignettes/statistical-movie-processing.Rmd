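---
title: "Statistical movie processing for cryo-EM single-particle refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical movie processing for cryo-EM single-particle refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryopolish)
```

## The problem

Direct electron detectors record a cryo-EM exposure as a movie of F
dose-fractionated frames instead of one integrated image.  During the
~1 s exposure the particles move (beam-induced motion on the order of a
few Angstrom and one or two degrees), so the integrated image is blurred.
Each individual frame, however, integrates only ~1 e/A^2 and is far too
noisy to align on its own.  `cryopolish` implements the statistical
answer: align the whole-exposure average first, then re-align each frame
under a Gaussian prior centred on that alignment, using running averages
of a few frames to lift the per-frame SNR, and rebuild the map from the
per-frame poses ("polishing").  A movie simulator with known ground
truth, a gold-standard refinement engine, tilt-pair validation and
FSC-based postprocessing complete the workflow, so every stage can be
tested end to end without any external data.

## The model

A particle image is modelled in Fourier space as

$$X(\nu) \;=\; \mathrm{CTF}(\nu)\, P_\varphi V(\nu) \;+\;
  \varepsilon(\nu), \qquad
  \varepsilon(\nu) \sim \mathcal{N}\!\big(0, \sigma^2(|\nu|)\big),$$

where $V$ is the 3D map, $P_\varphi$ extracts the central slice at pose
$\varphi$ (three ZYZ Euler angles plus a 2D origin offset), and
$\sigma^2$ is a per-resolution-shell noise variance.  Alignment
evaluates, over a discrete grid of candidate poses,

$$\log L(\varphi) = -\sum_{\nu}
  \frac{|X(\nu) - \mathrm{CTF}(\nu) P_\varphi V(\nu)|^2}
       {2\sigma^2(|\nu|)},\qquad
  \Gamma(\varphi) \propto e^{\log L(\varphi)}\,\pi(\varphi),$$

with a flat prior $\pi$ for the exposure averages and, for movie frames,
the Gaussian prior

$$\pi(\varphi) = \exp\!\Big(-\frac{\Delta(\varphi)^2}{2\sigma_a^2}\Big)
                 \exp\!\Big(-\frac{\delta_x^2+\delta_y^2}{2\sigma_t^2}\Big),$$

centred at the pose of the F-frame average.  $\Delta$ is the geodesic
rotation angle between candidate and centre — the three Euler
perturbations are treated jointly, which keeps the prior independent of
the Euler convention (a per-angle Gaussian is a near-identical
alternative for the small angles involved).  Working defaults are
$\sigma_a = 1^\circ$, searches of $\pm 3^\circ$ in steps of
$0.45^\circ$ and $\pm 2$ px in steps of $0.5$ px, and running averages
of $W = 5$ frames whose alignment is assigned to the window's middle
frame only.  $\sigma_t$ defaults to the spread of the refined offsets
about the picked positions in the whole-exposure refinement.  The
assigned frame pose is the posterior mean over the local grid (MAP by
flag); the posterior-mean is smoother for very noisy frames.

## Gold-standard refinement

`gold_standard_refine()` splits the particles into two random halves
(seeded permutation, not even/odd, to avoid micrograph-order bias) and
refines each half against only its own reconstruction.  Per iteration:

* **Alignment.**  A quasi-uniform global orientation grid (tilt rings
  with `round(360 sin(tilt)/step)` in-plane points, psi sampled at the
  same step) combined with a coarse $\pm 1.5$ px shift grid, followed by
  a per-particle local search with fine translations.  The global pass
  runs in the first two iterations; afterwards particles keep their
  orientation basin and only local searches run.  The angular step
  follows the Crowther spacing $d/D$ radians (resolution $d$, particle
  diameter $D$, default $0.6 \times$ box width), clamped between the
  7.5 degree global sampling and a 1.875 degree floor: sampling much
  finer than the resolution supports would only fit noise.
* **Reconstruction.**  Direct Fourier inversion: each image transform is
  spread onto the central slice of its pose by trilinear interpolation
  on a 2x zero-padded grid (padding keeps the interpolation kernel's
  spectral leakage negligible), CTF-weighted, and normalized by
  $\sum \mathrm{CTF}^2$ plus a small ridge.  An optional per-shell
  Wiener term $\sigma^2/\tau^2$ (with $\tau^2$ from the standard SSNR
  relation $\tau^2 = \mathrm{FSC}/(1-\mathrm{FSC}) \times$ shell power)
  is available in `reconstruct()`, clamped so no shell is attenuated
  more than ~100x.  The maps that carry the half-map FSC are always the
  plain ridge reconstructions: strong per-shell attenuation followed by
  cropping of the padded grid leaks the (shared) low-frequency signal
  into empty shells and would correlate the half-maps spuriously.
* **Resolution bookkeeping.**  The unmasked half-map FSC is evaluated
  each iteration; the reported resolution uses the FSC = 0.143
  criterion.  References for the next iteration are low-passed at the
  more conservative FSC = 0.5 crossing, and the alignment resolution
  cap follows that estimate but may grow by at most 2 shells per
  iteration — both choices limit the feedback loop in which aligning
  noise against a shared starting reference inflates the FSC and then
  unlocks even more shells ("Einstein from noise").
* **Convergence.**  The run stops when the resolution changes by less
  than one shell for two consecutive iterations (the convergence rule is
  this package's choice), or at `max_iter`; if the resolution worsens
  three iterations in a row the run is flagged and the best iterate
  returned.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the acquisition the method was developed
on: 16 frames over a 1 s exposure at 16 e/A^2 total (so each frame
integrates at most 1 e/A^2), 1.77 A pixels, 300 kV, Cs 2.0 mm, 10%
amplitude contrast, defocus uniform in 1.3–3.8 um, optional tilt pairs
at 0/10 degrees, and beam-induced motion with exposure totals of
4.2 ± 2.3 A translation and 1.7 ± 1.2 degrees rotation.  Details worth
knowing:

* **Phantom.**  An asymmetric sum of anisotropic Gaussian blobs under a
  broad envelope.  Blob widths run from domain-sized lumps down to
  secondary-structure-scale detail and amplitudes carry mixed signs
  (density fluctuations about the mean interior density, as in
  solvent-flattened maps), giving the protein-like broad amplitude
  spectrum that orientation determination actually relies on; a phantom
  made only of large positive blobs concentrates >95% of its power in
  the first few shells and cannot be aligned at realistic SNR.
* **Noise.**  White Gaussian, scaled so the per-pixel variance SNR is
  linear in dose at `snr_per_dose` (default 0.05 per e/A^2: frame SNR
  0.05, exposure-average SNR 0.8).  A per-shell coloured option is not
  simulated; the noise model estimator is tested against the known flat
  truth.
* **Motion.**  Translation is a linear drift plus a small per-frame
  random walk (step sd 0.1 A); rotation is a linear ramp about a random
  axis.  Both are re-centred to dose-weighted zero mean, because
  refinement first aligns the exposure average and the per-frame prior
  is centred there.  Total magnitudes are drawn from a folded normal
  whose underlying parameters are moment-matched so that the realized
  mean/sd equal the configured values exactly (naive folding of
  N(1.7, 1.2) would bias the mean by +5%).  The per-frame trajectory
  shape is this package's choice; only the exposure totals are anchored
  to observed values.
* **Damage.**  A per-frame Gaussian amplitude decay
  $\exp(-B_f \nu^2/4)$ with $B_f$ = `damage_rate` (default 3 A^2 per
  e/A^2) times the dose accumulated at the frame midpoint — the
  simplest model that makes later frames align less accurately.
* **Not emulated.**  Detector MTF/DQE, charging, ice gradients, carbon
  edges, and micrograph-level correlated motion (each particle moves
  independently).  Passing tests therefore demonstrate the statistical
  machinery, not robustness to every property of real micrographs.

## Baselines and validation

`partition_average()` implements the naive alternative: contiguous
blocks of w frames (4 x 4 for a 16-frame movie; when F is not divisible
the last block is taken from the final w frames and overlaps its
neighbour, as in 3 x 6, so every frame is used).  The partition baseline
treats each block average as an independent particle and aligns it from
scratch — global search, then a local pass — against its half-set
reference, mirroring how the independent multi-frame data sets are
refined in the naive approach.

Tilt-pair validation measures alignment error experimentally: each
field is imaged untilted and at a known stage tilt (10 degrees), and the
relative rotation between the independently refined orientations of a
pair should equal the stage tilt.  `pair_error()` reports the geodesic
angle of $R_\mathrm{tilted} (R_\mathrm{geom} R_\mathrm{untilted})^{-1}$
(in-plane offsets excluded; the full-rotation geodesic is the standard
tilt-pair metric).  `precision_and_misaligned()` histograms the errors
from zero in 0.5 degree bins (bin width chosen to resolve a ~2 degree
peak; the source histogram's bin width is not stated), measures the
width of the first peak at half its maximum count with linear
interpolation between bin centres — a peak sitting in the first bin is
treated as centred at zero and its half-width mirrored — floors the
width at one bin, and counts pairs with errors beyond 3x the precision
as misaligned.

## Postprocessing

Masked FSC uses a soft spherical mask (raised-cosine fall-off over 5
pixels).  Resolution is the linearly interpolated FSC = 0.143 crossing
(Nyquist if the curve never crosses).  `mtf_correct()` divides the map
amplitudes by a tabulated detector MTF.  `estimate_bfactor()` fits the
Guinier line (log spherically-averaged amplitude against $1/d^2$,
$B = -4 \times$ slope) over a configurable range (default 10 A to the
Nyquist edge); this deliberately simplifies the reference-based
automated sharpening procedure to its reference-free, testable core,
and `sharpen()` applies $\exp(-B\nu^2/4)$ with a 2-shell cosine-edge
low-pass.  `rh_extrapolate()` solves the particle-number/SNR relation
$\ln(N_2/N_1) = (B/2)(1/d_2^2 - 1/d_1^2)$; with the published class-1
values (B = 160 A^2, 35,813 particles at 4.5 A) it predicts ~3.3 A at
one million particles.

## Numerical choices

* Unitary FFT convention; real-space and Fourier origins at 0-based
  index N/2.  Parseval checks are then exact and flat noise has equal
  variance in both domains.
* Central-slice extraction/insertion uses trilinear interpolation on a
  2x padded transform; no gridding kernel correction beyond that (a
  5000-projection self-reconstruction correlates with its source map
  >0.99 to 0.8x Nyquist).
* Subpixel shifts are Hermitian phase ramps (the unpaired Nyquist row
  gets the real factor $\cos \pi d$), so shifted real images stay real
  and band-limited round-trips are exact.
* Posterior normalization by log-sum-exp; Gamma sums to 1 within 1e-8
  even for defocus-scaled likelihoods.  Ties in the MAP are broken by
  the lowest grid index (deterministic).
* Shell width is one Fourier voxel, assignment by rounded radius, so
  FSC values are bit-reproducible.
* CTF sign convention: $-[\sqrt{1-w^2}\sin\gamma + w\cos\gamma]$ with
  underfocus positive, so protein contrast is dark before flipping; an
  `invert` flag exposes the opposite convention.

## Problem sizes

The test-suite and examples run at desk scale: boxes of 32–48 voxels at
1.77 A, hundreds to a thousand particles, and a phantom standing in for
the ribosome.  The ordering study (polished vs best fixed partition vs
plain exposure averages) uses 1,000 particles in a 48^3 box under the
default motion model; pose-recovery checks use the same dataset, and
drift tracking uses 200 particles.  At these sizes a full
simulate–refine–polish cycle takes a few minutes on one CPU.  Headline
resolutions from real micrographs are not reproducible at this scale —
what is reproducible, and what the tests assert, is the ordering of the
three processing routes, the recovery of known poses and trajectories,
and the self-consistency of every operation against closed-form or
brute-force oracles.

## Known limitations

* Reconstruction from the posterior uses a single pose per image (MAP
  or posterior mean); fully marginalized insertion over the grid is not
  implemented.
* Per-frame dose weighting of the polished reconstruction is a hook
  (uniform by default), not a tuned scheme.
* The simulator's particles move independently; micrograph-level motion
  models and tilt-pair phase-residual plots are out of scope.
* Beam tilt, anisotropic magnification and higher-order aberrations are
  not modelled.

## A worked miniature

```{r mini, eval = FALSE}
cfg <- run_config(n_particles = 200, box_size = 32, seed = 1)
out <- run_pipeline(cfg, dir = tempfile("run"))
str(out[c("resolution_average", "resolution_partition",
          "resolution_polished")])
```

The summary lists the masked FSC = 0.143 resolutions of the three
routes; on motion-blurred simulations the polished map is at least as
good as the best fixed partition, which is at least as good as the
plain exposure average.
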