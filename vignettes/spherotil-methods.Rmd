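---
title: "spherotil: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spherotil: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
measurement models, their assumptions, the tunable parameters that matter,
what the synthetic-data generators do and do not emulate, and the places
where the underlying methodology left genuine design freedom. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

# The experimental system

CD8⁺ cytotoxic T lymphocytes (CTL) kill tumor target cells through an ordered
series of cytoskeletal polarization steps: directed migration (leading
lamella, trailing uropod), tight couple formation at the immune synapse, and
sustained polarization toward the target. Tumor microenvironments suppress
these steps. The measurements packaged here quantify that suppression at
three scales: (i) 3D tumor spheroids co-cultured with CTL, imaged as
confocal z-stack time series with a spheroid marker, a T-cell reporter, and
the viability dye DRAQ7 that enters only dead cells; (ii) single cell-couple
DIC movies at 10-s resolution; (iii) caliper-measured tumor growth in mice.

# Spheroid segmentation

## Acquisition geometry and mirror completion

Spheroid stacks are acquired in 3 µm z-steps from the bottom of the spheroid
to its **widest plane** (usually ~40 steps): light scattering makes the upper
hemisphere unreliable, and the lower half plus the equator determines the
rest under the approximate axial symmetry of a spheroid.
`mirror_concatenate()` reflects the stack about its last (widest) slice,
producing `2Z − 1` slices. The widest plane is deliberately **not
duplicated**: duplicating it would double-count the equatorial volume slab.
With the sphere's equator exactly on the last slice the reconstruction is
exact; a spheroid whose true equator falls between slices incurs at most one
slice (`dz`) of bias.

## Segmentation chain

`segment_spheroids()` runs: binarisation → 26-connected labeling →
alpha-hull gap filling → anisotropy-aware Euclidean distance transform →
marker-based watershed → minimum-volume filter. Volume is voxel count ×
`dx·dy·dz`; SIL density is T-cell count / spheroid volume in mm³.

Numerical and design choices:

* **Binarisation** defaults to Otsu's criterion computed per stack on a
  256-bin histogram; a fixed threshold is available. A *signal guard*
  prevents pathological thresholding of empty channels: the foreground is
  accepted only if the between-class mean separation exceeds 4 pooled
  within-class standard deviations. Splitting pure Gaussian noise yields a
  separation near 1.6σ against a within-class SD near 0.6σ (ratio ≈ 2.7),
  while a genuine fluorescence channel separates by the full
  signal-to-background contrast, so the guard cleanly rejects channels with
  no rendered signal (e.g. the dead channel at kill rate 0) without any
  free intensity parameter.
* **Connectivity** is the 26-neighbourhood; the method description names
  connected components without a connectivity, and 26 is the permissive
  choice that does not fragment voxelized spheres.
* **Alpha-hull fill.** Fragmented labeling (gaps toward spheroid centres) is
  repaired by fitting each object with an alpha shape and voxelizing the
  enclosed region. No 3D alpha-shape (Delaunay) library exists in this
  R environment, so the fill uses the *union-of-balls characterisation* of
  the alpha hull directly on the voxel grid: morphological closing with a
  Euclidean ball of radius α (two anisotropy-aware distance transforms),
  followed by filling of internal cavities not connected to the stack
  border. This is the voxel-space complement construction of the alpha
  hull; it is extensive (output ⊇ input) by construction, which the test
  suite asserts. `alpha = "auto"` mimics the critical-alpha default of
  reference alpha-shape implementations: the smallest α on a doubling grid
  (starting at the largest voxel dimension) at which the foreground
  component count stops decreasing — large enough to heal fragmentation,
  small enough not to bridge separate spheroids. Degenerate tiny components
  are handled by the same closing + hole-filling path, which reduces to
  morphological closing.
* **Watershed.** The distance transform is computed in physical units, so
  the 3 µm z-step versus in-plane pixel size is handled correctly. Seeds
  are local maxima of the distance map separated by at least
  `expected_radius_um` (default 40 µm, a typical spheroid radius); every
  connected component is guaranteed at least one seed. Flooding is
  priority-ordered (deepest first) and 6-connected so fronts cannot leak
  diagonally; distinct seeds can never merge.
* **T cells** are segmented from their channel without the alpha-hull step
  (single cells have no labeling gaps to repair), filtered at
  `min_cell_volume_um3` (default: an 8 µm diameter sphere, ≈ 268 µm³), and
  assigned to the spheroid label containing their centroid; detections
  outside every spheroid count toward the scene total only. Counting is by
  connected components, not by volume division — blobs are well separated
  at realistic SIL densities (≤ ~10⁴ cells·mm⁻³ means ≥ ~40 µm typical
  spacing).
* **Dead volume** is the thresholded dead channel **intersected** with the
  spheroid labels. Whether the original workflow restricted DRAQ7⁺ volume
  to spheroid boundaries is not recoverable from the text; intersection is
  the conservative choice (debris outside spheroids is not "spheroid
  death") and is documented as such. The per-series death metric is
  Σ dead volume(t) − Σ dead volume(t₀), i.e. the *increase* in DRAQ7⁺
  volume.

## What a green segmentation test establishes

On noiseless rendered spheres (r = 30/60/90 µm) the pipeline recovers
volumes within 5% (the residual is voxelization error at 3 µm sampling);
touching pairs at 0.9× the radius sum are split into exactly two objects
within 5% each (the geometric lens shared by the overlap is < 1.5% of a
sphere volume at that separation); T-cell counts are exact on well-separated
blobs. This isolates *algorithmic* error: real data add optical blur along
z, intensity attenuation with depth, touching cells, and irregular spheroid
shapes that the generator does not emulate.

## Mirrored T-cell counts

A T cell below the widest plane appears twice in the mirrored
pseudo-complete spheroid. The generator therefore places cells strictly
below the mirror plane with a clearance margin and its truth object records
both the physical and the doubled (mirrored) count; the pipeline's count is
compared against the latter. SIL *density* is unaffected because the
mirrored volume doubles too — this is exactly the situation with real
half-acquired stacks, where density is the reported quantity.

# Cytotoxicity kinetics

The killing statistic is the steepest ordinary-least-squares slope of the
red-object area over a sliding window, optionally restricted to
[killing onset, eradication]. The default window is 8 samples = 2 h at the
15-min acquisition interval: long enough to average acquisition noise,
short enough to sit inside a 4–8 h decline phase. Auto-detection of the
onset/eradication bounds (first sustained decline; area below 5% of peak)
is provided but off by default — the bounds are an analyst decision in the
original procedure.

**Normalization** to control growth is implemented as a *difference of
slopes* (`control_slope − target_slope`, evaluated on the same time
window): the method description says only "normalized to the growth of"
control cells. Subtraction keeps units interpretable (µm²/h), is zero under
no killing, and is positive when killing outpaces growth; a ratio
convention is available via `normalization = "ratio"`. This ambiguity is
flagged as unresolved; switching conventions is a one-argument change.

The generator's logistic decline has analytic steepest slope
−(A₀ − floor)·s/4, but a finite OLS window measures a *window-average*
gradient, which for the default geometry is ~3% shallower. The truth object
therefore stores both the analytic value and the exhaustive-enumeration OLS
truth on the noiseless series; recovery tests compare against the latter,
which is the quantity the estimator actually targets.

# Cell-couple morphodynamics

The classifiers operationalise observational definitions whose numeric
thresholds were never published; defaults are documented package choices,
*not* inferred author values:

* **Tight coupling** (`find_coupling_frame`): the earlier of (a) the first
  frame with a "maximally spread" synapse — operationalised as interface
  length ≥ 95% of the track maximum (`spread_fraction = 0.95`) — and
  (b) contact + 2 frames, clamped to the movie end.
* **Uropod** (`detect_uropod`): a boundary protrusion (contiguous vertices
  ≥ 20% above the median centroid distance) whose direction lies within
  ±45° of the anti-motion vector and whose base carries curvature of
  opposite sign to the cell's mean boundary curvature, sustained ≥ 1 min
  (6 frames at 10 s).
* **Off-interface lamella** (`detect_lamellae`): newly added outline area
  between consecutive frames whose direction lies > 90° from the synapse
  direction (`sector_deg = 90`), reaching ≥ 10% of cell area
  (`area_frac = 0.10`), followed by retraction of the protruded sector to
  below 25% of its peak excess within 2 min. The retraction check compares
  each frame in its own centroid frame so that cell *translation* (e.g.
  during translocation) is not mistaken for sustained protrusion.
* **Translocation** (`classify_translocation`): strict inequality —
  synapse displacement must *exceed* one interface diameter, measured at
  the coupling frame. The tie case and the diameter's reference frame are
  package decisions.

Outline analysis uses radial profiles about the cell centroid (exact for
star-shaped outlines, which the generator produces; deeply folded shapes
would be smoothed). All classifiers are invariant under rigid motion of the
scene, which the test suite verifies by rotating and translating whole
tracks.

Generated tracks inject events at `margin` (default 1.5) times the
classifier thresholds: translocation displacement 1.5 interface diameters,
lamella area 1.5 × 10% of cell area, uropods of 8 frames against the 6-frame
rule. At that margin classifier accuracy against generator truth is 100%
(asserted in the acceptance suite); the margin is a parameter precisely so
boundary behaviour can be probed deliberately.

**Survival analysis.** Time to first off-interface lamella is analysed with
the product-limit estimator and the standard (O − E)²/V two-group log-rank
statistic (1 df chi-square, tied events pooled per distinct time). Couples
with no lamella by movie end (15 min) enter censored. The chi-square p is
validated against the permutation distribution of the statistic within
Monte-Carlo error, and the statistic itself against `survival::survdiff`.

**Fura-2 ratios** subtract field-averaged backgrounds from both excitation
channels before ratioing, mask frames with non-positive denominator, and
re-zero time at the coupling frame.

# Tumor growth statistics

* **Volume**: the modified elliptical formula V = 0.5·L·W² (mm³), with
  length defined as the larger caliper dimension.
* **R-value**: the printed construction multiplies a cell count by a rate
  (`c·(dc/dt)`), which cannot carry the stated units of 1/time; the package
  implements `(dc/dt)/c`, which does, and which reduces algebraically to
  (V_f − V_i)/(V_i·Δt) because the cells-per-volume constant
  q_g = 2.76 × 10⁵ mm⁻³ cancels. The implementation nevertheless computes
  the explicit q_g form so the cancellation is an identity of the code (the
  acceptance suite checks it to machine precision), and q_g is retained for
  unit bookkeeping. Δt is fixed at 8 h — the stated division period of the
  cell line (three divisions per 24 h) — regardless of the measurement
  interval, and the early-growth window defaults to days 12–16.
* **Classification**: responder = volume below the treatment-start volume
  on ≥ 2 consecutive measurements (a single sub-start dip is measurement
  noise at caliper precision); relapse = a responder whose volume later
  reaches or exceeds the start volume; stable remission = both caliper
  dimensions < 5 mm over ≥ 8 days. The 2-consecutive rule is a package
  decision; the source gives no numeric rule.
* **Outlier exclusion** is one-sided: only growth rates above
  mean + 1 SD are dropped. "Deviating from the mean" is directionless in
  the source, but the stated purpose (excluding abnormally aggressive
  tumors from treatment comparisons) is one-sided; a zero-spread cohort
  excludes nothing.
* **Exact tests**: `fisher_exact()` sums hypergeometric probabilities of
  all tables at fixed margins with probability ≤ the observed table's
  (relative tolerance 1e−7, validated against a `choose()`-based
  enumeration oracle). `boschloo()` is the exact *unconditional* test: the
  ordering statistic is the one-sided Fisher p, and the p-value is the
  supremum over a grid (default 200 points) of the common nuisance success
  probability of the binomial probability of tables at least as extreme;
  two-sided by doubling, capped at 1. Boschloo's p is never larger than
  Fisher's (uniform power dominance), which the tests assert, and the grid
  supremum is stable to < 1e−3 beyond 200 points on the tables tested.
* **Sample size**: n = (2/d²)·c_p,power with c_p,power = 11.7 (80% power at
  p < 0.01 on Altman's nomogram), rounded up, floor 1.

# Marker-combination PCA

Per-sample features are the percentages of gated cells positive for every
AND-combination of the marker panel. The published analysis reports 308
variables from "all combinations of the eight markers", which is not
derivable from the text (2⁸ − 1 = 255 AND-subsets; the deposited data would
be needed); the combination set is therefore caller-configurable with the
all-AND-subsets default, and the realised feature count is reported by the
pipeline. Percentages are arcsine-square-root transformed *as fractions*
(asin√(p/100) — the scaling is not stated in the source; the fraction
convention maps [0, 100]% onto [0, π/2]); tumor volume enters as log₁₀.
Columns are standardized to mean 0, SD 1 with the n−1 sample SD; constant
columns carry no correlation-scale information and are dropped with a
warning rather than propagating NaN.

PCA is the eigendecomposition of the correlation matrix (via SVD of the
standardized data; covariance-scale available by flag). Components with
eigenvalue > 1 are retained. Variable coordinates are loading·√λ, cos² is
the squared coordinate, and the contribution of a variable to a component
is 100·cos²/Σcos², summing to 100 per component. With fewer samples than
variables the trailing eigenvalues are exactly zero and the eigenvalue sum
still equals the variable count (the correlation-matrix trace).

**Group ellipses** use the population-covariance chi-square construction —
semi-axes √(χ²₀.₉₅,₂ · eigenvalues of the score covariance) along its
eigenvectors — matching common factor-map implementations; this is a
*data* ellipse (95% of the group's scores), not the t-based confidence
ellipse of the group mean. Its Monte-Carlo coverage on bivariate normal
scores is 95% ± 1% at n = 10⁴ (asserted in the acceptance suite).

The marker generator draws per-cell positivity from a per-mouse latent
suppression score; the treated group's score is shifted by `effect_axis`.
Because the within-group latent SD is 1 and the 95% ellipse extends
√χ²₀.₉₅,₂ ≈ 2.45 within-group SDs along each axis, *non-overlapping* group
ellipses require a latent shift exceeding ≈ 2 × 2.45 SD; the
ellipse-separation suite therefore states a strong-suppression contrast of
`effect_axis = 6`, chosen from that closed form rather than tuned. The
default `effect_axis = 1.5` describes a realistic moderate effect in which
PC1 separates group *means* while individual mice overlap.

# Synthetic data: what is and is not emulated

The generators emulate the *geometry and bookkeeping* of the real assays:
half-stack acquisition with a shared widest plane, 3 µm z-steps, 2-h
timepoints; a concentric dead core whose volume fraction grows as
f(t) = min(1, f₀ + k·t) — the simplest monotone model consistent with an
increasing DRAQ7⁺ volume (the real spatial pattern of death is not
localized by the measurement); Gaussian PSF blur plus additive read noise
and optional Poisson shot noise, with defaults mild enough that Otsu
separation is unambiguous, so segmentation tests isolate algorithmic error;
parametric star-shaped cell outlines with events injected at stated
margins; triphasic growth (6-day growth, 8-day response, open-ended
relapse) from a day-12 start at ~62.5 mm³ (5 × 5 mm) with lognormal caliper
noise; Bernoulli marker matrices from a latent suppression score.

They deliberately do not emulate: depth-dependent attenuation and
anisotropic PSFs, irregular spheroid morphology, cell-cycle or motility
dynamics inside spheroids, DIC image formation (classifiers consume
outlines, not pixels), inter-mouse covariance structure beyond a single
latent score, or FlowJo-style gating hierarchies. Green tests therefore
certify the *estimators*, not robustness to every property of real
microscopy data.

All generators restore the caller's RNG state and are bit-identical under a
fixed seed; every truth quantity is recoverable from the returned truth
object without re-simulation.

# Known limitations

* The alpha-hull fill is a voxel-space ball-closing construction, not a
  Delaunay alpha complex; for highly non-convex objects at coarse voxel
  sizes the two can differ near deep concavities.
* The original workflow's alpha value and threshold method live in
  deposited workflow files and are not printed; defaults here are
  package choices validated on synthetic ground truth.
* Outline classifiers assume star-shaped cells (radial resampling about
  the centroid).
* `boschloo()` enumerates (n₁+1)(n₂+1) tables per nuisance grid point;
  it is intended for the small group sizes of animal experiments
  (n ≤ ~50 per arm).
* The killing-rate normalization convention (difference vs ratio) is an
  unresolved ambiguity of the source method, switchable by configuration.
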