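---
title: "fluoquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fluoquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fluoquant` is a toolkit for semi-automated quantification of fluorescence
micrographs — background-illumination correction, Bradley mean adaptive
thresholding with a seed-driven parameter tuner, and per-cell intensity
measurement — together with the downstream endpoint analyses that typically
accompany such studies of cell metabolism: mono-exponential TCSPC lifetime
fitting, mitochondrial morphology and network metrics, scratch-wound and
BrdU quantification, mito-stress-test (OCR) metrics, and one-way ANOVA with
Tukey–Kramer post hoc comparisons. A synthetic-scene generator with full
ground truth makes every stage testable without real specimens.

This vignette records the models, parameter choices, and numerical
decisions. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The segmentation and quantification pipeline

The pipeline processes a grayscale intensity image `I` (a.u., non-negative)
in five stages:

1. **Despeckle.** Gaussian smoothing with a small kernel
   (`sigma_small`, default 1 px) suppresses shot noise. A 3×3 median
   filter is available (`method = "median"`) since "despeckling" often
   denotes a median filter, but the Gaussian is the default. Kernels below
   0.25 px degenerate to the identity. Borders are handled by reflection,
   which avoids the dark rims a zero-pad would produce; the image mean is
   consequently preserved only approximately (well within 0.1% at the
   despeckle scale on 64×64+ frames).

2. **Background estimation.** Vignetting and other illumination
   inhomogeneity are estimated from cell-free pixels only. In the default
   `mask_excluded` mode, candidate foreground is found by a coarse
   pre-threshold (median + 3·MAD of the despeckled image) unless the caller
   supplies an exclusion mask; the estimator then (a) fits a quadratic
   polynomial surface to the background pixels and (b) smooths the residual
   with a large-kernel Gaussian (`sigma_large`, default 52 px = 4× the
   expected cell diameter of 13 px) as a normalized convolution over
   background support. The detrend step matters: a plain large-kernel blur
   flattens genuine gradients near image borders, because reflective
   padding cannot extrapolate a trend; with detrending, a pure planar
   gradient is recovered exactly everywhere (a test asserts this). In
   `sampled_rois` mode the quadratic surface is fit to user-supplied
   cell-free rectangles instead. Masks covering more than 90% of the frame
   are rejected as insufficient support.

3. **Background correction.** The image is divided by the unit-mean field,
   `I / (B / mean(B))` — division, not subtraction, because vignetting is
   multiplicative; the unit-mean normalization preserves the global
   intensity scale. Subtraction is available behind
   `correct_background(method = "subtract")` for comparison.

4. **Bradley adaptive threshold.** Pixel `p` is foreground iff
   `I(p) > (1 − s) · mean_w(p)`, where `mean_w` is the mean over the w×w
   window centered on `p`, computed in O(1) per pixel from a summed-area
   table. Windows are *clipped* at borders (mean over the in-bounds part),
   never padded, and the comparison is strict — so a uniform image is all
   foreground for any `s > 0`, a deterministic edge case. The sensitivity
   `s ∈ (0, 1)` grows permissive: other conventions map as `s = 1 − t` for
   a threshold fraction `t`, or `s = p/100` for "percent below the local
   mean". The implementation is bit-exact against a brute-force per-pixel
   evaluation of the same rule (an acceptance criterion).

5. **Labeling, filtering, seed selection, measurement.** Connected
   components (8-connectivity by default) are labeled in raster-scan order
   of their first pixel, filtered by area (`min_area`/`max_area`,
   defaults 30/5000 px², rejecting speckle and flooded backgrounds), and
   intersected with user seed points (0-based x = column, y = row): a seed
   is *detected* iff it lands on a labeled pixel; only seeded components
   are measured; two seeds in one component count one object and log a
   merge. Per-cell mean intensity is taken over exactly the labeled pixels
   of the corrected image.

**The tuner** evaluates the full threshold→label→filter→seed-match chain on
a grid of (w, s) and reports the seed-detection success-rate surface and
its argmax. Ties are broken toward larger w, then smaller s — the smoother,
less noise-sensitive segmentation. Errors at a grid point are logged and
scored as rate 0 rather than aborting the sweep.

## Synthetic scenes: what they emulate, and what a green test means

`make_cell_scene()` renders ~20 bright cells per 192×192 frame —
anisotropic Gaussian intensity profiles truncated at 2.5σ (the truncation
ellipse *is* the ground-truth mask, giving an unambiguous true mean
intensity), semi-minor radii 5–8 px, eccentricity 1–1.6, peak intensities
400–800 a.u. on a base of 100 a.u. — over a background composed of a planar
gradient (peak-to-peak 50 a.u., i.e. 50% of base) plus a smooth
low-frequency field, with Poisson noise by default. Placement enforces a
minimum center-to-center spacing that guarantees disjoint masks, so the
truth mask always has exactly `n_cells` components.

Defaults are stated once here and are not tuned per test. Two were chosen
for internal coherence of the simulated world rather than from any
published value: the smooth background component has correlation length
128 px (two thirds of the frame) and amplitude one eighth of the gradient —
"illumination" structure much finer or stronger than that could not be
corrected by *any* large-kernel estimator, including the one this package
implements, so such a world would contradict the premise of the method
being modeled. A green pipeline test therefore establishes that the
implementation recovers what the method can in principle recover; it does
not establish robustness to confounds the generator does not model:
overlapping/touching cells, intensity-dependent (non-Poisson) camera noise,
focus drift, debris, or autofluorescence texture.

`make_mito_scene()` renders star-polyline networks (1 arm = a plain
tubule; 3–5 arms = one junction) with 3-px tube width and arm lengths
12–20 px, and records the generating graph (branches, junctions, summed
arm lengths) as ground truth — deliberately independent of any
re-skeletonization. `make_decay()` inverts the mono-exponential model
`A·exp(−t/τ) + b` with optional Poisson counting noise;
`make_stress_trace()` produces 4-phase plateau traces with Gaussian noise.

## Lifetime fitting

`fit_monoexp()` fits `I(t) = A·exp(−t/τ) + b` by weighted least squares
with Poisson weights `1/max(counts, 1)` over a window starting at the peak
bin (tail fitting — no instrument-response deconvolution, since the IRF of
the modeled instrument is unavailable and pixel-decay tail fits are the
norm for this kind of data). For fixed τ the model is linear in (A, b), so
the solver profiles τ by 1-D golden-section minimization of the weighted
RSS with (A, b) solved in closed form at every step; this cannot diverge,
is exact (to optimizer tolerance ~1e-8) on noise-free model data, and makes
τ̂ invariant to uniform count rescaling. The initial τ comes from the
log-linear slope of the top decade of counts; a non-negative slope raises a
non-convergence error, and peak counts below `min_counts` (default 20)
raise a low-signal error rather than returning garbage. The baseline b is a
free parameter, not pre-subtracted — robust to dark counts without a
pre-pulse convention.

ROI averaging (`roi_lifetimes()`) is an unweighted mean ± SEM over ROI
lifetimes with a hard minimum of 18 ROIs (3 per cell × 6 cells, the
standard scheme for this assay); a non-converged fit in the set is an
error, never a silent exclusion. ROI decays should be pooled (summed)
pixel histograms: per-pixel fits at realistic counts are noise-dominated.

## Morphology and network metrics

Per-object descriptors: area = pixel count; perimeter = Crofton
4-direction estimator, `P ≈ (π/8)(N0 + N90 + (N45 + N135)/√2)` with N the
boundary-crossing counts along each line family — low bias on smooth shapes
(a naive exposed-edge count, whose analytic bias on disks is 4/π ≈ 1.27,
is available behind a flag); form factor = `P²/(4πA)`, ≥ 1 with circle = 1 (the inverse,
circularity, is emitted as a derived column); aspect ratio = √(λ₁/λ₂) of
the central second moments with the 1/12 square-pixel correction, making
single-pixel-wide objects finite. Objects under 4 px are flagged degenerate
and excluded from form factor / aspect ratio.

Skeletonization uses **Guo–Hall** two-subiteration thinning. Zhang–Suen was
implemented first and rejected: on rendered tubules it can erase entire
thin diagonal branches (a known weakness), which destroyed
branch recovery; Guo–Hall preserves them. Residual 2×2 blocks are cleaned
by removing a corner only when its 3×3 neighborhood stays 8-connected.
Optional spur pruning (`prune`, default 0; 4 px in the mito pipeline)
removes endpoint-terminated side branches shorter than the threshold that
attach to a junction; isolated segments are never pruned.

Network metrics classify skeleton pixels by degree in a *reduced* pixel
graph — diagonal edges that shortcut an orthogonal 2-step path are dropped,
since staircase corners would otherwise read as spurious degree-3
junctions. Junction pixels cluster into nodes (8-adjacent clusters count
once, because thinning spreads one biological node over adjacent pixels);
`junction_merge_dist = 2` additionally merges junction pixels separated by
one bridge pixel, which thinning routinely produces where many tubules
meet, and absorbs such bridges into the node instead of counting them as
branches. The default (1) is the plain adjacency-cluster rule. Branches are
the connected components of the non-junction pixels — maximal paths,
cycles (one branch each), or isolated pixels — with length 1 per orthogonal
and √2 per diagonal step plus the connection steps into adjacent nodes.

## Wound closure and BrdU

Scratch area is texture-based: cell monolayers are textured while the
scratch is smooth, so intensity alone cannot separate dim confluent cells
from empty scratch. The local variance over a sliding window (default
25 px ≈ 2 cell diameters) is thresholded by Otsu on log-variance; the
largest low-variance component, dilated back by half the window (the
variance window straddles the boundary and erodes the core), is the
scratch. Two guards make the confluent case an error instead of a random
region: a minimum textured/smooth variance contrast (default 5×) and a
minimum area fraction (1%). Closure is `(A₀ − A_t)/A₀`. BrdU positivity is
counted by centroid containment — a nucleus is positive when its
DAPI-channel centroid falls inside any BrdU-channel object — which
tolerates small channel misregistration.

## Ratios and statistics

Treatment effects are expressed as the ratio of group means
(treated/control), not the mean of per-cell ratios: cells are unpaired
across wells. Its SEM uses first-order propagation,
`ratio·√((SEM_t/mean_t)² + (SEM_c/mean_c)²)`, validated against a bootstrap
oracle in the tests. Pooling is per-cell by default; per-image aggregation
is a caller choice (pass image means instead).

`anova_tukey()` is a from-scratch one-way decomposition with Tukey–Kramer
studentized-range adjustment (`ptukey`) for unequal n, cross-checked in the
tests against `aov`/`TukeyHSD` to 1e-8 in F and 1e-4 in adjusted p. Zero
within-group variance with unequal means is reported as `F = Inf` with an
`exact_separation` flag rather than NaN. A Shapiro–Wilk normality pre-check
warns but never blocks — the modeled workflow always proceeded
parametrically. OCR group comparison treats wells as the independent unit
and can enforce the standard n = 6 design in strict mode.

## OCR metrics

Phase conventions follow the vendor protocol for the 4-phase mito stress
test: non-mitochondrial respiration = mean of the final
(rotenone/antimycin-A) phase; basal = last pre-oligomycin measurement −
non-mito; ATP-linked = last pre-oligomycin − minimum post-oligomycin
(this is the oligomycin-sensitive OCR in pmol O₂/min, which is how "ATP
production" panels are usually computed — it is labeled as such and is not
a vendor-derived ATP rate in pmol ATP/min); maximal = maximum post-FCCP −
non-mito; spare = maximal − basal. The decomposition is exactly
shift-equivariant (adding c to the whole trace shifts only non-mito) and
malformed phase structures are rejected, never reinterpreted. A negative
basal is flagged, not clipped.

## Numerical and I/O choices

* Coordinates are 0-based (x = column, y = row) in all user-facing tables;
  R's 1-based matrix indexing is internal.
* Label masks persist as 16-bit TIFF (≤ 65535 objects). The package
  carries its own minimal baseline-TIFF codec (uncompressed grayscale,
  8/16-bit unsigned and 32-bit float, little/big-endian read) because the
  target installation has no TIFF package; it was validated against an
  independent TIFF implementation during development. Integer pixels are
  promoted to float *without rescaling* so raw counts survive round trips;
  multi-page files and RGB require an explicit `page`/`channel` choice.
* Configuration is YAML; unknown keys are rejected rather than ignored.
  Output CSVs carry a `# fluoquant <version> config=<hash>` provenance
  line (FNV-1a hash of the serialized configuration).
* All stochastic operations take an explicit integer seed and restore the
  caller's RNG state; fixed-seed Monte-Carlo tolerances in the tests (e.g.
  the 2% single-fit lifetime recovery band) were frozen from oracle runs
  of the estimator's empirical recovery distribution before the tests were
  written.

## Known limitations

* No watershed splitting: touching cells merge (the generator never
  renders them, and the seed workflow logs merges instead of resolving
  them).
* The background estimator assumes illumination varies smoothly at the
  `sigma_large` scale; structured autofluorescence backgrounds violate it.
* Lifetime fitting is strictly mono-exponential tail fitting; no IRF
  deconvolution, multi-exponential decomposition, or phasor analysis.
* Network metrics are 2-D; overlapping tubules in projection create
  junctions that do not exist in 3-D.
* The wound detector needs a texture contrast between monolayer and
  scratch; phase-contrast-like texture is assumed.
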