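---
title: "Per-particle electron tomography of flexible antibodies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-particle electron tomography of flexible antibodies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ipetr)
```

# The problem

Antibodies are too flexible for averaging-based structure determination:
their two Fabs and the Fc move around a disordered hinge, so every particle
adopts its own conformation. Individual-particle electron tomography (IPET)
sidesteps averaging entirely: each negatively stained particle is imaged as
its own tilt series (here -45 to +45 degrees in 1.5 degree steps, 61
images), reconstructed into its own ~15-20 A density map, and interpreted by
docking rigid domain models into the envelope. Statistics over an ensemble
of such per-particle models quantify conformational flexibility - for an
IgG, the distances and angles between the Fab domains and between the two
halves of the Fc (CH2 and CH3 domains).

This package implements that pipeline end to end, together with a synthetic
data generator that produces antibody-like phantoms with *known*
conformational geometry, so every stage can be validated by parameter
recovery.

# The simulator and what it does (and does not) emulate

A phantom is a handful of smooth solid domains: each Fab is a dumbbell
(length 85 A, width 45 A), each half-Fc a capsule-shaped rod (length 80 A,
width 30 A, its hinge-proximal half standing in for CH2 and its distal half
for CH3), an intact Fc an ellipsoid. The X-shaped class takes four geometry
parameters - CH3-CH3 mass-centre distance, CH2-CH2 axis angle, Fab-Fab
distance and angle - and realizes them exactly by construction; layouts are
volume-weighted mass-centred so the simulator's particle centre coincides
with the reconstruction's centre-of-mass gauge. The CH2-CH3 centre spacing
inside a rod is fixed at twice the analytic half-capsule centroid
(35.36 A), so the construction parameters are exactly what the downstream
centroid-based measurement reports on a perfect fit.

Projection is a parallel-beam line integral: the volume is rotated
right-handedly about the image's vertical axis (the tilt axis) and summed
along the beam axis, with trilinear interpolation. Image formation applies
the standard phase-contrast CTF (defocus 0.6-0.9 um underfocus, 120 kV,
Cs 2.0 mm, 10% amplitude contrast - the aberration constants are typical
instrument values and configurable), then a uniform per-image translational
jitter (up to a few pixels, emulating imperfect particle tracking), then
white Gaussian noise scaled to the signal standard deviation, so
`noise_sigma = 1` means SNR 1 and `noise_sigma = sqrt(2)` means SNR 0.5.
Protein is positive density throughout; the stain layer, substrate,
beam-induced motion and dose-dependent damage are *not* modelled - the
single `noise_sigma` dial subsumes them. Passing tests therefore demonstrate
correctness of the computational chain under this idealized noise model,
not robustness to every artefact of real negative-stain data.

Default acquisition geometry mirrors common practice for this kind of data:
256 px windows at 1.48 A/px, binned by 2 to a 128 px working grid at
2.96 A/px, 61 tilts. The heavier validation studies below run at a reduced
64 px / 3.4 A grid; the vignette states these problem sizes explicitly with
each study.

# Reconstruction

The per-particle map is built by back-projection: each image is smeared
through the volume along its beam direction. The plain operator (the exact
adjoint of projection, used for all adjointness and linearity checks)
over-weights low frequencies by 1/|f| in the tilt plane; the refinement
therefore builds its maps with the classical r-weighted variant, which
multiplies each image by a |f| ramp along the axis perpendicular to the
tilt axis first. Map building, alignment references, and both half-maps use
the same weighting, so FSC estimates are internally consistent.

Iterative refinement alternates: build a map from the current shifts,
project it at every tilt angle, low-pass filter and soft-mask both the
projection and the (re-centred) raw image, and update each image's shift by
FFT cross-correlation with parabolic sub-pixel interpolation (ties broken
toward the smallest shift). The automatic filter schedule is a geometric
progression of Gaussian low-pass cutoffs from 16x to 4x the pixel size
(47 -> 12 A at 2.96 A/px); the first half of the iterations use a soft
circular mask (1.2x the expected particle radius), later iterations a
particle-shaped mask thresholded from the current reference at background
mean + 2 sd with a smoothed, dilated edge. Iteration stops when the largest
shift change drops below 0.5 px *after* the schedule has reached its finest
level, or at the iteration budget.

Two properties of the joint alignment problem deserve explicit treatment
because they dominate validation:

* **The centre gauge.** A rigid offset of the particle inside the box
  changes every per-image shift by a predictable, angle-dependent amount
  without changing the reconstruction at all. The refinement pins this
  gauge by re-centring the map's density centroid each iteration;
  comparisons against simulator truth remove the residual rigid component
  by least squares (`shift_residuals`).
* **Soft collective modes.** Smooth angle-dependent shift patterns beyond
  the rigid gauge deform the map almost self-consistently and can lock in
  during the coarse-filter iterations when starting far from the solution.
  For boxes of 96 px and larger the refinement therefore first converges on
  a 2x binned copy of the series and starts the full-sampling iterations
  from the upscaled shifts (`multigrid = TRUE`). With this, simulated
  jitter up to 6 px is recovered to better than 0.5 px (noise-free) and
  1 px (SNR 0.5) on 128 px series. With a CTF applied and corrected by
  phase flipping, the contrast notch around the CTF's first zero costs
  roughly another half pixel of alignment accuracy; the reproduction
  script reports the CTF and CTF-free conditions separately.

The missing wedge (the unmeasured +/-45..90 degree region of Fourier space)
is compensated by constraint-set iteration: alternate enforcing
non-negativity and a loose spherical support (radius 0.45 box) in real
space with restoring the measured Fourier coefficients from the input.
Measured data are preserved to floating point; on the 48^3 sphere study
below the axial elongation ratio drops from 1.74 to 1.56 after the 100
cycles used in validation (convergence is not monotone cycle-by-cycle, and
longer iteration drives the ratio toward unity). The
underlying algorithm class is standard projection-onto-constraint-sets; the
exact constant choices (support radius, cycle count) are package defaults,
configurable, and applied either every refinement iteration (the
`refine()` default) or once on the final map (`wedge_every`); the ensemble
pipeline uses the final-map option, which preserves map quality at a
fraction of the cost.

Resolution is estimated by Fourier shell correlation between maps
back-projected from the odd- and even-index aligned images, with shells one
Fourier voxel wide; the first downward crossings of 0.5 and 0.143 are
linearly interpolated in frequency. Noiseless odd/even halves decorrelate
slightly at high frequency purely from their angular interleave, so the
self-consistency ceiling of this estimator sits below Nyquist even without
noise. A model-to-map variant rasterizes a placed atomic model on the map
grid and reports the same thresholds. Display maps are low-pass filtered to
20 A.

# Docking rigid domains

Atomic (or pseudo-atomic) models rasterize as mass-weighted Gaussians whose
FWHM equals the requested resolution. A single body is docked by an
exhaustive coarse search - rotations sampled sphere-uniformly at the given
angular step, translations scored for every rotation by locally normalised
cross-correlation (fast-NCC: the map's mean and variance are computed under
the body's own support at every shift via FFT) on a 2x binned grid -
followed by Nelder-Mead refinement of all six rigid parameters at full
resolution from the best few candidates. Local normalisation matters: with
a plain global correlation a small body prefers parking over the crowded
particle centre rather than on its own domain.

Multi-domain docking cannot proceed greedily per body, because an antibody's
domains come in near-identical pairs packed closely together. The default
strategy mirrors how practitioners dock homologous domains into a compact
low-resolution envelope: dock the *whole* multi-domain template rigidly
first (a large asymmetric object whose global fit is unambiguous), then
polish each body locally from its docked position - largest first, with the
density claimed by already-placed bodies subtracted - and finally re-polish
every body against the map with all *other* bodies subtracted. Two constants
matter here and are documented defaults: the polish is leashed to 15 A
around its starting position (so a body cannot migrate to a neighbour's
already-claimed peak), and subtraction is deliberately scaled to 75% of the
least-squares amplitude, because full subtraction eats the shared density at
domain junctions and biases the remaining bodies outward. A candidate-
assignment strategy (several coarse candidates per body, joint selection
under a pairwise overlap bound) and plain greedy subtraction are available
as alternatives.

Because an axially symmetric half-Fc rod has no observable polarity in the
density, each fitted rod is flipped end-over-end if needed so its CH2 half
lies nearer the particle centre - the biologically correct orientation for
a hinge-linked domain. Fitted bodies are never deformed; hinge connectivity
is instead checked after placement: for each linked pair the distance
between the anchor atoms (the mutually closest atoms of the two bodies in
the input model) must not exceed the fully extended length of the
connecting loop at 3.8 A per residue.

The interior of each domain never moves relative to itself, so this
rigid-multi-body treatment reports conformations only at the domain level;
flexible (force-field) fitting is intentionally out of scope.

# Flexibility statistics

Geometry records are measured exactly as a structural biologist would read
them off a fitted model: mass centres of the labelled domains, Euclidean
distances between them, and angles between domain axis vectors. A domain's
axis runs between the centroids of the backbone atoms within 10 A of the
two extremes of its principal axis (the end-cap depth is configurable), with
its sign disambiguated to point away from the particle centre; the CH2-CH2
angle uses the CH2-to-CH3 centroid vector of each half-Fc. All statistics
are invariant to global rigid motion, and ensembles are superposed on their
CH2 pairs (least-squares, Kabsch) only for display - the superposition is
checked to leave every statistic unchanged.

Histograms (12 bins over the data range by default) are fitted by
deterministic least squares: a 1-term Gaussian initialised from moments, a
2-term Gaussian initialised by a median split with a fixed second restart,
both via Levenberg-Marquardt with positive-amplitude bounds, or a
sixth-degree polynomial by ordinary least squares. Constant input or
non-convergence yields a flagged result rather than an error. Range
fractions use closed intervals at both ends.

# The validation studies and their sizes

* Fourier-slice identity: 64^3 smooth random volumes; the oracle slices a
  3x zero-padded FFT of the corner-shifted volume, so its own interpolation
  error stays well under the 5% band checked.
* Shift recovery: one 61-tilt series at the full 128 px / 2.96 A working
  scale, jitter up to 6 px, noise-free and at SNR 0.5.
* Ensemble recovery: 50 X-phantoms with CH3 distance ~ N(90 A, 10 A) and
  CH2 angle ~ N(100, 25) degrees, random in-plane orientation with a 10
  degree out-of-plane wobble (adsorbed particles lie nearly flat), run at
  64 px / 3.4 A with CTF and SNR 0.5 through simulate -> reconstruct ->
  dock -> measure. The whole-template dock exploits the near-flat
  orientation prior (out-of-plane search limited to 40 degrees, both
  flips); the per-particle measurement does not see any per-particle truth.
  Recovered CH3-distance statistics carry a small (~+3-4 A) outward bias
  from docking into blurred, wedge-compensated maps; this is a property of
  the measurement, reported as such, and sits within the +/-5 A band the
  recovery study checks.
* Wedge compensation: a soft sphere, 48^3 at 2 A, +/-45 degrees in 3 degree
  steps, 100 constraint cycles.

# Known limitations

* Only translational alignment is refined; per-image rotations, defocus
  refinement, dual-axis geometry and dose weighting are out of scope.
* CTF handling is phase flipping only; amplitudes stay attenuated.
* The histogram bin count and the far-end cap size shift fitted angle
  statistics by a few degrees; both are configurable and documented rather
  than hidden.
* The i-shaped (half-antibody) and bowtie classes ship as fixed compact
  layouts; only X and Y expose conformational parameters.
* Docking assumes one particle per map, roughly centred, as produced by the
  windowing convention of the simulator and reader.
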