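---
title: "Methods: desk-scale single-particle cryo-EM processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale single-particle cryo-EM processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cryopipe implements a complete single-particle electron cryo-microscopy
processing pipeline at desk scale: every stage runs in minutes on one CPU
against synthetic data with known ground truth. This vignette describes
the models, the tunable parameters, the numerical choices, and what the
synthetic benchmarks do and do not demonstrate about real data.

## Containers and conventions

Images and volumes are square/cubic real arrays with an even box side and
a physical pixel size in Angstrom (`em_image`, `em_volume`, `em_stack`);
all spatial frequencies are in 1/Angstrom with shell width
`1/(box * pixel_size)`. The real-space origin is the box center (side/2,
0-based); transforms use the unshifted convention with the Fourier origin
at array element [1,1]. The FFT pair is forward-unscaled / inverse-1/N,
so Parseval's relation reads `sum(x^2) = sum(|X|^2)/N`. Euler angles are
Z-Y-Z intrinsic: `R = Rz(phi) Ry(theta) Rz(psi)`, with the projection
direction the rotated z axis. Maps are stored as MRC2014 mode-2 float
files with the pixel size in the cell parameters.

A subtlety worth recording: the Fourier-slice operators rotate about the
*array origin*, while images store the object at the *box center*. All
projection and insertion routines therefore carry explicit centering
phases ((-1)^(hx+hy)) and the accumulation grid holds the object rolled
to the origin; `finalize_reconstruction()` rolls the map back.

## CTF model and determination

The CTF is the standard phase-aberration model with astigmatic defocus,
spherical aberration, amplitude contrast and an optional phase-plate
shift: `CTF = -sin(chi + atan(w / sqrt(1 - w^2)))` with
`chi = pi lambda g^2 (df(theta) - lambda^2 g^2 Cs / 2) + phase`.
Determination proceeds in two stages: an exhaustive one-dimensional
search (defocus, optionally phase shift) against the rotationally
averaged, background-subtracted power spectrum, then local refinement of
(defocus1, defocus2, astigmatism angle, phase shift) against the 2D
spectrum under a radial sine-edged mask that is 0 at the origin and 1
from 1/4 per-Angstrom outward. The refinement uses a Nelder-Mead
derivative-free maximizer rather than a conjugate-gradient scheme; the
objective surface is smooth at this scale and the contract — a local
optimum no worse than the start — is optimizer-agnostic. Because the
astigmatism angle is multi-modal from a round start, the driver refines
from four angle seeds and keeps the best optimum.

Background subtraction removes a running-median plus Savitzky-Golay
smoothed radial background. The fit quality is a per-shell correlation
between the fitted CTF^2 and the radial spectrum over a moving window
(default 9 shells); the fit resolution is the first shell where it stays
below 0.3 for 3 consecutive shells, scanning only beyond 30 Angstrom
(the shells before the first Thon ring carry no fit information). A
warning is raised when the local CTF oscillation period, from the
derivative of the aberration phase, falls below two spectrum pixels.
Spectra from movies use sub-sums of frames (about 4 e-/A^2 each is a good
choice); spectra finer than 1.4 A/pixel are clipped to an edge of
1/2.8 per Angstrom. Diagnostics always use the background-subtracted but
non-masked spectrum.

## Movie alignment and exposure weighting

Whole-frame alignment iterates leave-one-out correlation: each frame is
aligned against the sum of all other currently-shifted frames, the x(t)
and y(t) trajectories are smoothed with a Savitzky-Golay filter (cubic,
window 7 by default), the mean shift is removed, and iteration stops when
the largest change drops below 0.1 Angstrom (configurable). Sub-pixel
shifts are Fourier phase ramps with parabolic peak interpolation; a
B-factor (default 1500 A^2, smaller values favor feature-rich synthetic
scenes) damps the correlation. Exposure weighting uses the published
critical-exposure curve `Nc(g) = 0.245 g^-1.665 + 2.81` e-/A^2 with the
constants exposed; the weighted sum is renormalized per frequency by
`sqrt(n/sum(w^2))` so filtered signal power is restored. Weights are 1 at
zero frequency and decay with accumulated exposure.

## Particle picking

The picker correlates a noise-whitened micrograph with a CTF-convolved,
soft-edged disk. Micrographs are Fourier-cropped to half the picking
resolution (default 30 A, hence 15 A pixels) and high-pass filtered above
a few particle diameters. The background noise spectrum is the average
rotational power spectrum of the 50 lowest-local-variance areas
(Hann-windowed tiles; the window suppresses spectral leakage that would
otherwise tilt the estimate), and both the micrograph and the template
are divided by it — a matched filter. Scores are normalized so the
particle-free null is ~N(0,1): the analytic normalization is finished by
a robust rescale using the negative side of the score distribution,
which particles (all positive mass) cannot bias. The detection threshold
is therefore directly a number of standard deviations of the null.

Local mean/variance statistics are computed at the micrograph's native
sampling, where per-pixel particle contrast is realistically weak, and
resampled to the working grid; areas above Mo+2FWHM in variance (8 FWHM
under phase-plate phases in (0.1 pi, 0.9 pi)) or outside Mo±2FWHM in
mean are excluded. Greedy non-maximum suppression enforces the
user-specified minimum distance, with ties broken by scan order. Dense
particle packing inflates the background estimate and depresses scores —
a documented property of the approach; thresholds should be lowered on
crowded micrographs.

## 2D classification

Maximum-likelihood classification marginalizes, per particle, over
classes x in-plane rotations x bounded translations. The angular step is
`dalpha = R/D` (resolution limit over particle diameter); the resolution
limit ramps linearly between `R_start` and `R_finish` (package defaults
40 and 8 A; desk-scale boxes should start nearer 30 A because a 96-pixel
box holds almost no orientation information at 40 A); random subsets
follow the three-tier rule (300K/N early, 0.3 mid, 1.0 late, each capped
at 1). Particles are whitened by the square root of the radially
averaged noise power spectrum measured outside the particle mask (up to
2000 random particles), leaving ~unit variance per Fourier coefficient,
and the background mean is set to zero. Class averages are fully
CTF-corrected probability-weighted sums (CTF^2 plus a small Wiener
constant, 0.1 x class occupancy, in the denominator) and, at the start of
each iteration, values below -0.3 x max are reset to that threshold.

Two numerical choices matter for stability and are the package's own:
class average band power is equalized across classes before the E-step
(otherwise the class with the larger amplitude wins for every particle at
once), and early iterations apply deterministic annealing — the
assignment temperature is derived from the median inter-class margin and
ramps to 1 over the first three quarters of the run — so per-view
preferences, not shared amplitude effects, drive the separation. The
per-particle noise scale is estimated from the best residual.

## 3D refinement

The matched-filter objective correlates a whitened particle with an
SNR-scaled, CTF-multiplied reference projection. The particle transform
is divided by its own radially averaged amplitude spectrum and amplified
by `sqrt(1 + SNR(g))`; the reference slice is CTF-multiplied, scaled per
shell to `sqrt(SNR)` (keeping the CTF sign structure), with
`SNR = PSSNR x CTF^2`. The normalized cross-correlation runs over a
[R1, R3] band; an optional signed-CC limit R2 makes the (R2, R3] band
contribute the absolute value of its cross terms. A quadratic shift
restraint `-(sigma^2/2M)[(x-xbar)^2/sx^2 + (y-ybar)^2/sy^2]` is added and
the total is reported x100 as the particle score (perfect unshifted
match = 100).

Projections are central Fourier slices with trilinear interpolation from
a 2x zero-padded reference transform; insertion uses the same kernel as
its adjoint, with Friedel mates kept explicitly. Global searches
evaluate a quasi-uniform Euler grid as one band-limited matrix product
per particle (reference slices x phase-shifted particle vectors), cache
the scaled reference matrix across particles sharing a CTF, locally
refine the top h (default 20) candidates with Nelder-Mead, and break
exact ties by grid order. Per-particle defocus offsets are a 21-point
grid (±500 A in 50 A steps) applied to both defocus values; resolving a
50 A offset requires the many Thon rings of a finely sampled box —
coarse desk-scale boxes quantize the ring pattern too heavily. 3D
masking binarizes a user volume at zero, applies a cosine falloff of the
requested width (successive-erosion depth), and keeps the outside as
zero or a down-weighted low-pass copy blended at the edge.

## Reconstruction, resolution and sharpening

Reconstruction inserts `(q/sigma^2) w CTF F(X)` into a complex numerator
and `(q/sigma^2) w CTF^2` into a real denominator along the central
slice, with per-frequency score weights
`w = exp(-(BSC/4)(score - mean) g^2)`; the map is
`IFFT(num / (den + 1/PSSNR))`. Accumulators merge additively, which is
also the parallelization contract. Particles are background-whitened for
reconstruction: the noise spectrum comes from a copy whose interior is
replaced by the mask-edge mean, and the result is scaled to unit pixel
variance. Likelihood-based blurring inserts each particle over a grid of
in-plane rotation and shifts weighted by its normalized likelihood, with
the denominator from the single best insertion.

FSC curves are per-shell normalized cross-correlations of half maps
(Savitzky-Golay smoothed, window 7); solvent correction uses
`f FSC / (1 + (f-1) FSC)` with f the mask-to-particle volume ratio and
particle volume `Mw / 0.81` A^3/Da (the squared variant applies against
noise-free model maps). Resolution is the first linear-interpolated
crossing (0.143 reported, 0.5 inside auto-refinement). PSSNR per shell
is `2 FSC/(1-FSC)` doubled from half- to full-dataset; no CTF^2-coverage
factor is tracked. For the control loops the PSSNR is floored at 10% of
the molecular-weight default: zeroing high shells would both erase the
signal the next FSC needs and strip the reference of the detail the next
refinement aligns against. Sharpening masks (hollow sphere or custom),
whitens the radial power beyond 8 A by default, applies
`exp(-B g^2 / 4)`, optionally filters by `sqrt(2 FSC/(1+FSC))`, and
applies a final cosine-edged cutoff.

## 3D classification

Class densities are Gaussian log-densities of the masked residual
(image minus CTF-multiplied projection) over the pixels of a circular or
projected-sphere (focused) mask, in the log domain with log-sum-exp;
occupancies are the softmax against class priors, priors the dataset
mean of occupancies. No marginalization over alignment parameters is
performed. The reference scale is a nuisance — reconstructions and
whitening leave it arbitrary — so it is fitted per class by least squares
inside the mask; without this, unit mismatches between references and
whitened images dominate the residuals. The projected focus sphere
follows each particle's orientation and shift and carries a 2-pixel
cosine edge.

## Ab-initio reconstruction and auto-refinement

Ab-initio starts from uniformly random orientations, reconstructs, and
iterates: a global search over a random pool (3p of the stack) at the
scheduled resolution limit, with the per-particle result drawn uniformly
from all grid candidates within the top 15% of the score range; the
highest-scoring p fraction is reconstructed with sigma reset to 1, score
weighting off, and PSSNR capped by a flat molecular-weight default
(first three iterations use the default outright); automatic masking
follows (threshold at mean, 50 A low-pass, binarize at
`t = mean_f + 0.03 (top500_f - mean_f)`, largest 6-connected component,
centered spherical mask). Resolution ramps 20 to 8 A and the included
fraction from 2500K/N_eff to 10000K/N_eff (both capped at 1; at a few
hundred particles the caps make every iteration use the full stack,
exactly as the formulas dictate). For symmetric particles the first 2/3
of iterations run in C1; the map is then aligned to its symmetry axes by
a brute-force rotation grid scored by normalized correlation peaks
between each test projection and its symmetry mates (the operator acts
on the map, i.e. left of the view matrix), and symmetry is applied for
the rest.

Auto-refinement locally refines a random subset against the automasked
current map, reconstructs half maps, and estimates resolution as the
FSC = 0.5 crossing minus 2/D_mask (the mask-induced half-map
correlation). The subset fraction follows
`p_l = max(8000 K exp(75/R^2)/N_eff, p_{l-1})` on improvement and
`1.5 p_{l-1}` otherwise, capped at 1; at least five iterations run and
refinement stops at p = 1 with no improvement (beyond 0.1 A) for three
iterations; sigma estimation and score weighting stay off until the
resolution is better than 7 A. One deviation is deliberate: the
*refinement band* follows the previous half-map FSC crossing and never
coarsens, while the 2/D_mask-corrected estimate is what is reported and
what drives the subset schedule and stopping. At desk scale 2/D_mask is
a quarter of the crossing frequency itself, and feeding the corrected
estimate back as the refinement band makes the loop stall or diverge;
at realistic box sizes the two schedules coincide because the correction
is a few percent.

## Synthetic data and what the benchmarks mean

The default phantom is a pseudo-atomic design: a weak broad envelope, an
asymmetric arrangement of eight domain-scale Gaussians (sigma 5 A) that
carries the orientation signal in the 15-40 A band, and a deterministic
golden-ratio cloud of sixty sharp (sigma 2.5 A) Gaussians approximating
the roughly flat spectrum of a real macromolecule out to high
resolution. Both features are necessary: a smooth-blob phantom has
nothing to align at ab-initio resolutions, and a featureless envelope
has no high-resolution signal for FSC-based validation. SNR is defined
as signal variance over noise variance inside the particle mask, at the
native sampling. Micrographs image particles and solvent noise through
the CTF, add detector noise, and modulate both the noise power (±15%)
and the additive background with smooth fields emulating ice-thickness
variation — these fields are what the picker's histogram statistics and
high-pass filter are built to tolerate.

Desk-scale problem sizes used by the test suite and the acceptance
script: boxes of 32-48 pixels at 3 A (plus 96 pixels at 1.5 A where ring
sampling matters), 120-300 particles, ab-initio runs of 25 iterations at
an angular step floored at 9 degrees, auto-refinement stopping by its
own rules (typically 7-9 iterations). The end-to-end benchmark (300 particles, SNR 0.4) reaches an
FSC of 0.5 against the ground-truth phantom beyond 2/3 Nyquist (9 A at
3 A/pixel) after ab-initio plus auto-refinement; the map is aligned to
the phantom (including handedness, which projection data cannot
determine) before comparison. Passing these benchmarks demonstrates the
machinery is self-consistent and recovers known ground truth under
honest noise; it does not demonstrate performance on real detector data,
which adds non-Gaussian noise, beam-induced local motion, structural
heterogeneity and magnification distortions that the generators do not
emulate.

## Known limitations

Magnification refinement is carried in the parameter model but not
searched. There is no per-particle (local) motion correction, no
tilted-specimen CTF, no Ewald-sphere correction, and no helical or
point-group-specific refinement beyond C/D symmetrization. The
2/D_mask-corrected resolution estimate is conservative at small box
sizes (see above). Dense particle packing degrades the picker's
background estimate, as documented.
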