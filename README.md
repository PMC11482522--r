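# petmcc

Quantification of mucociliary clearance (MCC) in the small airways from
dynamic PET/CT.

Mucociliary clearance — the transport of mucus, and of tracer particles
embedded in it, out of the airways by ciliary beating — is impaired in
cystic fibrosis, and the disease is suspected to begin in the small
airways (< 200 µm diameter in newborn pigs). Classic planar single-photon
clearance assays are too slow and too coarse to see those airways:
small-airway clearance is mostly over within minutes. Dynamic PET of
⁶⁸Ga-labelled macroaggregated albumin, acquired in list mode and binned
into 10-s frames over a co-registered CT, is fast and precise enough to
measure it. `petmcc` implements the complete analysis chain for such
studies, together with a digital airway-tree phantom that generates
synthetic CT + 4-D PET with known ground truth for validation.

## What it computes

Two complementary ROI schemes for the small airways:

* **Peripheral shell** — segment the lung (`HU < −200` region growing),
  close it, and take the rind of fixed physical thickness (default
  1.5 mm, via an exact anisotropic Euclidean distance transform) at the
  pleural surface, where most sub-200-µm airways live.
* **Distal cylinder / disks** — segment the airway lumen (`HU < −700`),
  thin it to a centerline (homotopic 3-D thinning), smooth with a cubic
  spline, extrapolate the terminal tangent to the pleura, and sample the
  PET signal in a 2-mm-diameter cylinder around the extrapolated line or
  in perpendicular disks versus distance to the pleura.

ROI activity per frame becomes a time-activity curve; decay correction
(`2^(Δt/68 min)`) and normalisation to the first post-delivery frame give
the clearance curve

    %Cleared(t) = 100 · (A₀ − A(t)) / A₀,

which is fit with the three-parameter two-phase exponential association

    pct(t) = 100 · (1 − f·e^(−k_fast·t) − (1 − f)·e^(−k_slow·t)),

(f = fast fraction, k_fast ≥ k_slow in 1/min, curve starts at 0% and
plateaus at 100%). Groups are compared with the extra sum-of-squares
F test (pooled single-curve fit vs per-group fits), responders
(> 20% cleared at 12 min, strict) are counted per group, and group
contingency tables get two-sided Fisher exact p-values by hypergeometric
enumeration. Group means ± SE at the endpoint round out the report.

## Worked example

Simulate one "non-CF-like" subject (two-phase truth with ~25% cleared at
12 min, Ga-68 decay, anisotropic PSF blur, Poisson counting noise) and
analyse it with the shell scheme:

```r
library(petmcc)

spec <- phantom_spec(dims = c(64, 64, 64), lung_semiaxes_mm = c(23, 21, 27),
                     tree = airway_tree_spec(generations = 4, root_length_mm = 12),
                     seed = 42)
phantom <- rasterize_ct(generate_airway_tree(spec), spec)
dyn <- simulate_dynamics(phantom, kinetics_presets()[["non-CF"]], seed = 42)

report <- run_subject(phantom$ct, dyn$series,
                      seed_airway = c(32, 32, 56),   # voxel in the root lumen
                      seed_lung = c(15, 32, 32),     # voxel in the parenchyma
                      config = pipeline_config("shell"),
                      subject_id = "pig01", group = "non-CF")

cu <- report$curves$shell
fit <- fit_two_phase(cu)
print(fit)
cat(sprintf("measured %%Cleared at 12 min: %.1f (truth %.1f)\n",
            approx(cu$times_min, cu$pct_cleared, xout = 12)$y,
            approx(dyn$truth$times_min, dyn$truth$pct_true_frame, xout = 12)$y))
```

```
<two_phase_fit> f = 0.171, k_fast = 0.7097 /min, k_slow = 0.0076 /min
  rss = 21.41 on 90 obs (df 87)
measured %Cleared at 12 min: 24.3 (truth 24.6)
```

The fitted fast phase (k_fast/k_slow ≈ 90) reproduces the brisk initial
clearance followed by a slow late phase; the 12-min estimate lands within
the counting noise of the generative truth. `make_cohort()` +
`run_cohort()` do the same for multi-subject, multi-group studies and add
the F test, responder table, Fisher p and group summaries to a JSON
report. A thin CLI over these functions lives in `inst/cli/petmcc.R`
(`simulate`, `run`, `stats`).

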