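---
title: "Methods: two-photon VNC imaging analysis with vncactivity"
author: "vncactivity authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-photon VNC imaging analysis with vncactivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vncactivity)
```

# The analysis problem

Two-photon imaging of the ventral nerve cord (VNC) in a fly walking on a
spherical treadmill yields two simultaneously acquired fluorescence
channels: a GCaMP6s activity reporter and tdTomato, an activity-independent
structural fluorophore. Three properties of these recordings drive the
design of every stage in this package:

1. **The tissue deforms.** Leg movements deform the VNC non-rigidly, far
   beyond what affine models capture, so frames must be registered to a
   reference with a dense per-pixel motion field.
2. **Activity confounds motion estimation.** GCaMP intensity changes with
   neural activity, so all matching and registration use the structural
   channel only, and single-neuron signals are reported ratiometrically
   (%ΔR/R of GCaMP over tdTomato) so that shared intensity fluctuations
   cancel.
3. **Behavior is measured on its own clocks.** Treadmill optic flow,
   behavior video and imaging run at different rates; signals are linearly
   interpolated onto the grid of the highest-rate signal before joint
   analysis.

# Non-rigid motion correction

Each structural-channel frame $I_t$ is registered to a reference $I_r$
(frame 1 by default, overridable) by minimizing

$$E(\mathbf w)=\sum_{\mathbf x\in\Omega}\bigl|I_t(\mathbf x+\mathbf w(\mathbf x))-I_r(\mathbf x)\bigr|
\;+\;\gamma\sum_{\mathbf x\in K}\bigl\|\mathbf w(\mathbf x)-\mathbf m(\mathbf x)\bigr\|_1
\;+\;\lambda\sum_{\mathbf x\in\Omega}\|\nabla\mathbf w(\mathbf x)\|_2^2 ,$$

an $\ell_1$ intensity-conservation data term (robust to residual intensity
change), a sparse feature-matching term pulling the field toward block-matching
correspondences $\mathbf m$ on a keypoint grid $K$, and a quadratic
smoothness penalty. Intensities are normalized internally to an
8-bit-equivalent range (0–255, set by the reference) so that $\lambda$ and
$\gamma$ mean the same thing across acquisitions; all quoted $\lambda$
values refer to that scale.

The correspondences come from normalized cross-correlation block matching
(default: keypoints every 8 px, patch radius 4, search radius ±8 px,
matches kept above correlation 0.5, keypoints kept above a gradient floor).
This matcher was chosen over descriptor-based alternatives because the
contract needed here is narrow — sparse, reliable, intensity-robust integer
correspondences — and NCC block matching delivers it with no additional
machinery. A featureless image yields an empty match set and the $\gamma$
term simply vanishes.

## Optimization

The energy is minimized by ADMM with two splitting variables, one carrying
the smoothness term and one the feature term, inside a warp-and-linearize
outer loop over a three-level coarse-to-fine pyramid (×0.5 per level,
stopped above 12 px). Each sub-problem is solved in closed form:

* the data-term update is the per-pixel soft-threshold step along the local
  image gradient familiar from TV-L1 optical flow;
* the smoothness update is a screened Poisson equation
  $(\mu I-2\lambda\Delta)z=\mu v$ under reflecting boundaries, solved
  exactly by diagonalization in the DCT-II basis;
* the feature update is shrinkage toward the matched displacement.

The ADMM penalty is fixed at $\mu=10$; inner sweeps default to 8 per outer
iteration, outer iterations are capped at 100 and stop when the energy
improves by less than `convergence_tol` (default $10^{-4}$, relative). Raw
ADMM iterates are not monotone in the true energy, so the solver tracks the
best (lowest-energy) iterate seen; the recorded outer-iteration energy
trace is therefore non-increasing by construction, and that is the sequence
the tests assert on.

Because linearized descent is local, two exact coordinate-descent
refinements run on the true (non-linearized) energy after the pyramid: a
tile-fusion pass that applies uniform integer displacement moves to whole
tiles (whole image, halves, quarters, sixteenths) with locally computed
energy deltas, and a red-black per-pixel pass over offsets of 1, 0.5 and
0.25 px. Both accept a move only when it lowers the energy, so monotonicity
is preserved; together they let the solver escape basins in which an entire
region sits at the wrong displacement — the failure mode of purely
linearized schemes. A weighted median filter (5×5, weights a Gaussian of
structural-intensity difference with σ = 10 % of the dynamic range)
post-processes the field and is kept only when it does not increase the
energy.

## Artifact rejection and parameter selection

Registration failures concentrate as strong sinks in the estimated field.
`detectArtifacts()` computes the divergence by central finite differences
(one-sided at borders), thresholds at −1.2, labels 4-connected components,
and flags any cluster of more than 20 pixels (results are similar with a
cardinality-5 rule). `gridSearchRegistration()` registers a frame subsample
(every 5th frame by default) at each (λ, γ) candidate, discards candidates
that produce any flagged field, and among the survivors picks the pair
maximizing the sharpness of the temporal mean image, measured as its mean
gradient magnitude; ties go to the larger λ, and if everything is flagged
the candidate with the fewest flagged frames wins. Loose smoothness weights
are the artifact-prone regime — a local intensity decrease (for example an
activity transient bleeding into the structural channel, or photobleaching)
can be "explained" by contracting the bright structure into a sink — and
stiff weights suppress it. The λ value at which artifacts appear scales
with image area, since the data term is a sum over pixels: on the 64×64
synthetic images used throughout the tests the transition sits around
λ ≈ 20–100, while λ in the thousands is appropriate for larger fields of
view. For the synthetic study conditions (64×64, 3 px deformations with a
12 px correlation scale) λ = 50, γ = 1 is used; the package default of
λ = 2000 suits larger images and is deliberately conservative.

# Behavior quantification

Raw two-sensor optic flow arrives as rotations s⁻¹ about the
anterior-posterior, medial-lateral and yaw axes. Traces are smoothed with a
200 ms centered running average (truncated at the edges; a trailing window
would lag the behavior) and converted with the 10 mm-ball calibration
1 rot s⁻¹ = 31.42 mm s⁻¹ for translation and 1 rot s⁻¹ = 360° s⁻¹ for yaw.
Bout segmentation resamples the forward velocity to 1500 samples s⁻¹,
smooths over 0.2 s, and classifies samples as forward above +0.31 mm s⁻¹,
backward below −0.31 mm s⁻¹, still otherwise; turning uses ±10.8° s⁻¹ on
the rotational velocity, classified independently (a sample can be both
forward and turning). Threshold ties are resolved by strict inequality. A
bout is a maximal run of one non-still label.

Video annotation subtracts consecutive frames, median-blurs the absolute
difference (radius 5 px), counts non-zero pixels (strictly positive after
blurring, with a 10⁻⁹ tolerance for floating-point frames) in two ROIs — a
hind-leg region for walking (threshold 400) and a front region for grooming
(threshold 5) — and applies a minimum-run-length hysteresis filter (8
frames for walking, 10 for grooming), implemented by repeatedly absorbing
the shortest sub-minimum run into its surroundings until a fixed point,
which makes it idempotent. Grooming is subservient to walking: front-leg
motion during walking is ignored (the grooming sequence is forced to zero
wherever walking is active, before and after its own hysteresis pass).

# Behavior-regression maps

Pixel-wise ΔF/F uses a baseline image $F$ averaged over ten sequential
quiescent frames. Choosing that window is a judgment call on real data;
`proposeBaselineWindow()` operationalizes "minimal and unchanging" as: among
the candidate windows in the lowest decile of total intensity, the one with
the smallest total temporal variance. (Variance alone is not enough — under
noise a window inside a behavioral bout can be perfectly stable yet
activity-contaminated, which silently inverts the regression.) Pixels whose
baseline falls below 1 % of the movie's dynamic range are masked out of the
regression to avoid division blow-ups.

Binary behavior sequences are convolved causally with a calcium impulse
response — a peak-normalized exponential with half-life 1.1448 s (the
GCaMP6s fluorescence decay constant), truncated at five half-lives — and
each pixel's ΔF/F trace is regressed on the resulting regressor with
no-intercept ordinary least squares, $w=(X^TX)^{-1}X^Ty$. Raw (unsmoothed)
ΔF/F is used. Weight maps are displayed normalized to their maximum;
normalization cancels in the regression up to scale, so map rankings are
unaffected by the kernel's normalization and truncation choices.

# ROI signals and event detection

Candidate neuron ROIs on a reference frame come from Gaussian smoothing
(σ = 2 px), Otsu thresholding, a 1 px erosion and connected components
(area ≥ 3 px); selection among candidates is the caller's, and a manual
elliptical ROI is available as fallback. Tracking maximizes normalized
cross-correlation of the structural-channel reference patch within a
bounded integer search window (±10 px default); the structural channel is
used because the activity channel's intensity varies with activity. Frames
whose best score falls below 0.5 are flagged for review.

%ΔR/R uses the per-frame ratio of mask-mean GCaMP to mask-mean tdTomato.
With no stimulus to define rest, the baseline $R_0$ is taken as the minimum
of the trace averaged in non-overlapping 2.5 s bins — fixed bins and a
single global minimum, chosen because transients occupy a minority of the
recording, so the quietest bin estimates a stationary baseline without
chasing noise minima the way a per-sample minimum would.

Event detection thresholds the first derivative (first difference divided
by the sample interval) of %ΔR/R at a percentile of the derivative values
pooled across all traces of a neuron class — fluorescence kinetics are a
property of the cell class, not of one experiment. The convention is the
linear-interpolation percentile (R type 7) on signed pooled derivatives;
97.5 suits classes with occasional transients, 90 suits transient-rich
classes where a higher threshold would overlook real events. The pooled
percentile is rank-based, so it is only meaningful when transient rise
samples make up at least the complementary fraction of the pool — with
sparser events the threshold drops into the noise tail, which is why the
synthetic event-recovery experiments plant events every ~4 s. For each
upward threshold crossing the onset is the nearest preceding derivative
zero-crossing (the last non-positive derivative sample); crossings with no
intervening zero-crossing compress into one event at the first time point,
and onsets within 10 s of either trace end are dropped, matching the ±10 s
presentation window.

Bilateral pairs are reconciled by covariance class. Strongly covarying
pairs (left/right correlation near 1): events on both sides within 2 s are
paired greedily in time order by nearest-available matching and kept;
unpaired events are copied to the partner at the same timestamp (flagged
`copied_from_partner`; copies that would land in the partner's
edge-exclusion zone are dropped). Independent pairs: events on both sides
within 0.25 s are discarded from both, on the logic that coincident
bilateral activation cannot be attributed to either cell.

Event-triggered summaries window every signal to ±10 s around each onset,
resample to 500 samples s⁻¹, subtract the %ΔR/R value at 0 s (so the
summary is exactly zero at the onset), and report the pointwise mean with
percentile-bootstrap 95 % confidence intervals over events (1000 replicates
by default, seeded). Time-shuffled controls replace the onsets with uniform
random time points away from the edges and run the identical computation.
Exemplar events are ranked by the treadmill statistic characteristic of
each behavior: backward walking by the mean forward velocity in the 2 s
after onset (ascending), push-down by the difference between the 2 s after
and the 1 s before, turning by the mean rotational velocity in the 2 s
after, with the sign per side.

# The synthetic-data generator

Every stage is tested against `generateSyntheticExperiment()`, which
produces all pipeline inputs with known ground truth: a structural template
(bright blobs on a textured background), per-frame smooth deformation
fields, a two-channel movie, optic-flow traces coupled to a behavior
schedule, and a two-region behavior video.

* **Deformations** are spatially low-pass-filtered Gaussian noise (FFT
  filter, correlation scale `deformation_smoothness`), temporally smoothed
  by a 3-frame moving average, anchored to zero at frame 1 and rescaled so
  the maximum displacement equals `deformation_amplitude`. Defaults are
  3 px amplitude and a 12 px correlation scale on a 64×64 image — tissue-
  scale deformation (~20 % of the field of view, displacements ~5 % of it)
  rather than pixel-scale jitter, large enough to visibly corrupt naive
  averaging yet small enough that the deformation remains invertible.
* **Rendering** warps the template with the numerically inverted field
  (fixed-point iteration) so that the field registering each frame *back*
  to the reference equals the stored ground-truth field up to interpolation
  error; registration accuracy can then be scored directly as endpoint
  error. Warping is bilinear with edge clamping, the same interpolation the
  registration uses, keeping ground truth self-consistent.
* **Activity** multiplies the template by $1+g\,a(t)$ on per-source pixel
  masks before deformation, so the structural channel stays
  activity-independent by construction. Source activities are planted event
  trains convolved with the calcium kernel (instantaneous rise,
  exponential decay), or behavior-coupled regressors for the map tests.
* **Noise** is additive Gaussian on both channels — a detector-noise proxy;
  the downstream arithmetic is noise-model agnostic.

The generator does **not** emulate scanning artifacts (line shear,
bidirectional offset), photobleaching, slow drift, indicator rise kinetics
or 3-D (out-of-plane) motion. Tests passing on this data therefore
demonstrate the correctness of the implemented computations, not robustness
to every artifact of real recordings.

Movies persist as multi-page 16-bit TIFF (the standard acquisition bit
depth) with affine intensity scale factors in a YAML sidecar, so a write →
read round trip is exact to 16-bit quantization and idempotent thereafter;
traces, annotations and event series travel as CSV.

# Problem sizes and reproducibility

The test suite and the acceptance script use 64×64×100-frame movies for
registration recovery, 8×8 instances for brute-force oracle comparisons,
~140 s single-plane recordings at 8 Hz for the event pipeline and 280-frame
recordings for map recovery — sizes at which every property can be checked
against exhaustive enumeration or closed-form ground truth. All generators
and all stochastic analysis steps (bootstrap, shuffled controls) are
deterministic given their seeds; `runPipeline()` writes a manifest with
parameter snapshots and output checksums, and two runs with the same seed
produce bit-identical deterministic outputs.

# Known limitations

* Registration is 2-D; out-of-plane motion appears as intensity change and
  is only mitigated by the $\ell_1$ data term and the ratiometric readout.
* The λ/γ scale depends on image area; grid search should be rerun per
  acquisition geometry rather than reusing values across image sizes.
* The percentile event threshold presumes transient-rich traces of a given
  class; on nearly silent cells it degenerates toward the noise tail and
  the detector will report spurious events at the complementary rate.
* The bilateral copy rule inherits the partner's timestamp unchanged; no
  sub-second realignment between hemispheres is attempted.
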