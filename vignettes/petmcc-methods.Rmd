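---
title: "Quantifying small-airway mucociliary clearance from dynamic PET/CT"
author: "petmcc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying small-airway mucociliary clearance from dynamic PET/CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmcc)
```

## The measurement problem

Mucociliary clearance (MCC) — transport of mucus and any particles
embedded in it out of the airways by ciliary beating — is classically
measured by depositing a radiolabelled tracer in the airways and watching
the activity leave a region of interest. Planar single-photon assays
integrate over minutes and over the whole lung, which hides the small
airways (conducting airways under ~200 µm in diameter in newborn pigs):
their clearance turns out to be largely over within the first few minutes
after deposition. Dynamic PET of a positron-emitting tracer
(⁶⁸Ga-labelled macroaggregated albumin, half-life 68 min) acquired in
list mode can be re-binned into 10-s frames and localised in 3-D, which
is fast and precise enough to watch small-airway clearance directly.

`petmcc` implements the complete quantification chain for such data, plus
a digital phantom that generates synthetic CT + dynamic PET with known
clearance kinetics so every stage can be validated against ground truth.

Two complementary ROI schemes are provided, because clinical CT cannot
resolve the small airways themselves:

* **peripheral shell** — a rind of the lung mask of fixed physical
  thickness (default 1.5 mm) inscribed at the pleural surface, where
  most sub-200-µm airways live. Micro-CT-scale data can check that
  premise with `shell_depth_enclosing()`, which reports the depth
  enclosing a chosen fraction of the small-airway skeleton.
* **distal cylinder / disks** — the main-airway centerline is thinned,
  spline-smoothed, extrapolated along its terminal tangent to the
  pleura, and the PET signal is sampled in a 2-mm-diameter cylinder
  around the extrapolated line (or in perpendicular disks as a function
  of distance to the pleura).

The shell also contains alveoli, so tracer trapped in the alveolar space
biases shell clearance downward; the cylinder begins at the last
CT-resolvable airway (~2 mm diameter), so it contains some larger,
gland-bearing airways and biases clearance upward. The two schemes
bracket the quantity of interest.

## From frames to %Cleared

For a chosen ROI, each frame contributes one point of a time-activity
curve (`extract_tac()`), indexed by the frame midpoint in minutes.
Physical decay is removed with `decay_correct()`
(`A × 2^((t − t_ref)/T½)`, T½ = 68 min), referenced to the first
post-delivery frame. Clearance is then

> %Cleared(t) = 100 · (A₀ − A(t)) / A₀,

with A₀ the decay-corrected activity of the **first post-delivery
frame**, not the nominal syringe dose: residual activity in the delivery
catheter is unknowable from the images, so the first frame is the only
baseline actually available in-image. Values are not clamped — a
negative %Cleared means net inflow into the ROI.

## The two-phase clearance model

Observed clearance shows an immediate brisk phase over the first few
minutes followed by much slower clearance. We fit the three-parameter
two-phase exponential association

> pct(t) = 100 · (1 − f·e^(−k_fast·t) − (1 − f)·e^(−k_slow·t)),

which starts at 0% and plateaus at 100% (all tracer eventually clears),
with fast fraction `f ∈ [0, 1]` and rates in 1/min constrained to
`k_fast ≥ k_slow ≥ 0`. Among three-parameter forms that start at 0%,
this one is identifiable and matches the qualitative observation that
curves keep rising without reaching a plateau within the acquisition. A
free-plateau alternative (plateau, k_fast, k_slow with fixed f) was
considered and rejected as the default because the plateau is far outside
the observed window and trades off almost perfectly against k_slow.

Fitting is deterministic multi-start Levenberg–Marquardt
(`minpack.lm::nls.lm` with analytic Jacobian) over the grid
f ∈ {0.25, 0.5, 0.75} × k_fast ∈ {0.1, 0.5, 2} × k_slow ∈
{0.005, 0.02, 0.1} 1/min; the best residual sum of squares wins, and
label switching is removed by swapping rates (and mapping f → 1 − f)
whenever the "slow" rate comes out faster. Group fits pool every frame
observation of every curve in the group with equal weight, mirroring the
presentation of group mean curves; subject-level random effects are out
of scope.

On noiseless model data the fitter recovers (f, k_fast, k_slow) to below
1e-4 relative error across f ∈ {0.2, 0.5, 0.8}, k_fast ∈ {0.2, 1},
k_slow ∈ {0.01, 0.05}; with 1% Gaussian noise on the 10-s grid over the
15-min acquisition the median relative error stays within 10% for all
three parameters (the test suite checks both).

## Statistics

* **Extra sum-of-squares F test** (`compare_fits_f_test()`): the pooled
  one-curve model is nested in the per-group model, so
  F = ((RSS₁ − RSS₂)/(df₁ − df₂)) / (RSS₂/df₂) with the p-value from the
  upper tail. If the RSS reduction is negative or below 1e-10 relative
  (both models fit essentially perfectly, e.g. noiseless phantoms), F is
  reported as 0 — the reduction is numerical noise, not evidence.
* **Responders** (`classify_responders()`): a subject responds when its
  %Cleared at the endpoint (default 12 min, linearly interpolated
  between frame midpoints) strictly exceeds the threshold (default 20%;
  "more than 20%" reads as a strict inequality).
* **Fisher's exact test** (`fisher_exact()`): two-sided p by direct
  hypergeometric enumeration — the sum of probabilities of all tables
  with the observed margins no more probable than the observed one
  (relative tolerance 1 + 1e-7 on the comparison, the same convention as
  `stats::fisher.test`, which serves as an independent cross-check in
  the tests). A zero margin returns p = 1 with a warning.
* **Summaries**: group mean ± SE (sd/√n) of the endpoint %Cleared; SE is
  reported as missing for n = 1.
* Significance is flagged at α = 0.01 in pipeline reports; p-values are
  always printed in full.

## Geometry: segmentation, shell, centerline

Airway lumen and lung parenchyma are segmented by threshold region
growing (26-connected flood fill of `HU < −700` and `HU < −200` from
user seeds). The lung mask is closed with a Euclidean ball (default
radius 2 mm — the toolchains this emulates do not document their kernel,
so the radius is configurable) followed by filling of any background
cavity not 6-connected to the grid border.

The peripheral shell is defined through the exact Euclidean distance
transform rather than erosion iterations: `d(v)` is the distance from a
voxel centre to the nearest voxel centre outside the mask, and the shell
is `{v : 0 < d(v) ≤ thickness}`. This makes the physical thickness
independent of voxel spacing and anisotropy, and gives one well-defined
geometry at both clinical (~1 mm) and micro-CT (~0.03 mm) scales. The
distance transform is the separable lower-envelope algorithm
(O(n) per axis, exact, anisotropic); the test suite proves voxel-set
equality of the shell against a brute-force all-pairs oracle on randomly
generated masks. One caveat: voxels beyond the grid edge are *not*
background, so masks should not touch the volume edge (pad first) —
otherwise the shell is open on that side and closing cannot recover it.

The centerline comes from homotopic thinning with the standard (26, 6)
digital-topology pairing: border voxels are deleted in increasing
distance-transform order when they are simple points (deletion preserves
both object and background topology) and not curve endpoints; the
deletion order keeps the surviving curve medial. Any homotopic thinning
satisfying the one-voxel-wide, 26-connected contract would do; this
variant is chosen for determinism and because it needs no parameters.
The main path is the weighted longest path from the skeleton voxel
nearest a user-supplied proximal seed (Dijkstra over the skeleton's
26-adjacency graph with Euclidean edge lengths); side branches are
thereby pruned, and ties among equally distant terminals go to the
lexicographically smallest voxel so repeated runs agree. The caps of a
thick tube necessarily round off during thinning, so the path ends about
one radius short of the anatomical end — the pleural extrapolation step
makes this immaterial for the distal ROI.

The path is smoothed by independent cubic smoothing splines in x, y, z
against the chord-length parameter; the smoothing level is chosen by
generalised cross-validation and then relaxed (if necessary) until the
3-D residual RMS at the input voxels is at most one voxel spacing —
thinning output is quantised at voxel scale, and we want to remove that
jitter without distorting geometry (a helix fixture's arclength is
recovered to 0.2%). The terminal tangent is extrapolated in straight
0.25-voxel steps until the ray leaves the lung mask; disk assignment
sends each voxel within the disk radius to the nearest plane along
arclength (half-open, ties distal), which makes the disks a partition of
the swept cylinder — their activities sum to its total exactly.

## The phantom: what it emulates, and what it does not

`generate_airway_tree()` builds a dichotomous tree (generation g has 2^g
branches) with daughter length and radius ratios per generation, a
branching half-angle with jitter, and an azimuthal plane that rotates
~90° between generations, inside an ellipsoidal lung; branches that
would exit the lung are truncated at its surface and stop branching.
Defaults: 6 generations at desk scale (anatomical trees run ~22), root
radius 2 mm, ratios 0.72/0.7, 35° ± 5°. With ratio 0.7, a 1.5-mm root
tapers to 176 µm radius by generation 6 — the small-airway scale.
`rasterize_ct()` voxelises branches as capsules into HU classes (lumen
−1000, parenchyma −500, soft tissue +50) chosen to straddle the
−700/−200 segmentation thresholds with wide margins.

`simulate_dynamics()` deposits the tracer in a distal region (default:
the 1.5-mm peripheral shell, standing in for small-airway deposition —
the deposition target of a distally wedged catheter) and clears it with
two-phase kinetics. Cleared activity is removed from the grid in the
default open-system mode (mucus transported centrally and ultimately
swallowed or suctioned leaves the measured region); closed-system mode
re-deposits it uniformly in the proximal airway lumen (generations 0–1)
so that total decay-corrected activity is exactly conserved — the
conservation tests run in that mode. Regional activity at the frame
midpoint t is `A₀·(1 − pct(t)/100)·2^(−t/68)`; frames are evaluated at
midpoints rather than integrated over the frame (at 10-s frames the
within-frame curvature of the kinetics is negligible relative to
counting noise). The frame image is blurred with an axis-aligned
anisotropic Gaussian PSF (FWHM 5.5/4.5/6 mm radial/tangential/axial,
σ = FWHM/2.3548, kernel truncated at 4σ and renormalised, so total
activity is preserved away from grid edges), then Poisson counts are
drawn at `activity × 37 kBq/µCi × 7.3 cps/kBq × duration` and decoded
back to µCi. The phantom does **not** simulate respiratory motion,
attenuation, scatter, randoms, or tomographic reconstruction — its noise
is idealised Poisson counting on the true image. Passing tests therefore
show the *analysis chain* is correct and calibrated for Poisson-like
noise; they do not certify robustness to motion blur or reconstruction
artefacts in real scans.

Per-subject biological variability in `make_cohort()` is multiplicative
log-normal on the rate constants and logit-normal on the fast fraction
(respecting the parameter bounds), default σ = 0.1. Group kinetics
presets place the true 12-min shell clearance near the group means seen
in vivo in newborn pigs (non-CF ≈ 25%, CF ≈ 15%, non-CF+UTP ≈ 21%,
CF+UTP ≈ 13%), with the fast phase essentially over by 5 min. Every
stochastic draw descends from one integer master seed (subject s of
group g uses `seed + 1000·g + s`), so cohorts regenerate byte-identically.

Ground truth is recorded in two conventions: `pct_true` references t = 0
(the model curve) and `pct_true_frame` references the first frame
midpoint — the latter is what the pipeline's baseline convention
measures, and the closed-loop tests assert exact equality against it in
noiseless, PSF-free runs.

## Numerical and design choices worth knowing

* Frames are half-open `[start, start + Δ)`; an event exactly on a
  boundary belongs to the later frame; a trailing partial frame is kept
  with its true duration. The vendor console's exact binning convention
  is not documented, so this is a stated choice, not a reproduction.
* Voxel indices are 1-based in R; world = origin + (index − 1)·spacing
  (voxel-centre convention). Event CSVs use 0-based indices on disk.
* "Most of the small airways" is quantified as the 0.95 quantile of
  pleural depth (`enclosure_fraction`), configurable, since no number is
  standard.
* Disk sampling and cylinder ROIs use the dense-sampled spline (step =
  half the smallest voxel dimension); nearest-curve distances are exact
  to that sampling.
* Degenerate inputs: empty masks warn and return empty results;
  sub-voxel disk radii and cylinder diameters fall back to
  nearest-voxel sampling with a warning; curves shorter than the
  endpoint are excluded from responder tables with a warning.
* Problem sizes in the test suite are desk-scale by design: phantoms of
  40³–72³ voxels and 2–6 tree generations, 100-mask oracle suites up to
  32³, and 1000-replicate null calibrations at 3 subjects per group.
  These sizes were chosen so the whole suite validates every contract in
  about two minutes on one core while still exercising each code path at
  realistic anisotropy and noise levels.

## Limitations

* The shell ROI includes alveolar signal by construction; the package
  quantifies, but cannot remove, that bias.
* Group fits pool observations; inference ignores within-subject
  autocorrelation, exactly as the classic extra-sum-of-squares workflow
  does. The null calibration test shows the F test holds its nominal
  size under the simulated noise model, not under arbitrary correlation
  structures.
* The centerline module handles one main path per run; full-tree
  centerline graphs are out of scope.
* Masks touching the grid edge have no pleural surface there; the shell
  and closing operators treat out-of-grid as foreground-adjacent, so pad
  your volumes.
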