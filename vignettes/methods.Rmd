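---
title: "Bulk-density synthetic CT from multi-sequence MRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulk-density synthetic CT from multi-sequence MRI: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Radiotherapy dose calculation needs electron densities, which CT provides
and MRI does not. The bulk-density approach synthesizes a CT from MR
images by segmenting a small set of anatomies and assigning each one a
single representative CT number. `synthct` implements that pipeline for
the head — eight classes: air, body (residual soft tissue), eyeball, lens,
cavity (internal air spaces), ventricle, brainstem, bone — plus the
evaluation methodology used to judge the result against a reference CT:
overlap coefficients for the segmentation, histogram similarity for global
agreement, and a gamma index on CT numbers for local agreement.

Two synthetic CTs are produced. The water-equivalent `WCT` uses only the
body mask (interior 0 HU, exterior −1000 HU) and serves as the baseline a
bulk-density `BCT` must beat; the `BCT` assigns air −1000, body 0,
eyeball 300, lens 300, cavity −1000, ventricle 15, brainstem −50 and bone
1000 HU. The table is configurable (`hu_table()`); the defaults are the
conventional bulk assignments for these tissues. Eyeball and lens
intentionally share 300 HU, and cavity shares −1000 with external air,
which is why a `BCT` from the default table takes six distinct values.

# Coordinate and I/O conventions

All volumes live on a common grid with axis order (slice, row, column),
voxel sizes in mm, and the voxel-center convention: the world position of
0-based index *i* is `origin + i * spacing`. NIfTI-1 is the interchange
format (spacing in `pixdim`, origin in the sform/qform translation);
orientation metadata beyond spacing and origin is deliberately ignored,
since the pipeline never resamples and co-registration is assumed. Every
two-volume operation calls `check_same_grid()` first (shapes exact,
spacing within 1e-6 mm, origin within 1e-3 mm) and refuses mismatched
grids rather than resampling — registration is out of scope by design.

# The digital head phantom

`phantom_spec()` / `generate_case()` produce co-registered cases so the
pipeline can be exercised and tested without patient data. Geometry is
analytic — ellipsoids and spheres rasterized at voxel centers: a head
ellipsoid, a skull shell between two scaled copies of it (outer/inner
fractions 0.92 / 0.82, i.e. a 5–11 mm thick shell), paired eyeballs with
lenses at their anterior poles, two lateral ventricles, a brainstem and an
air-filled sinus cavity. The default grid is 40 slices of 128 × 128 at
2.5 × 2.34 × 2.34 mm — 2.5 mm slices over a ~30 cm field of view, a
typical planning-CT geometry. Per-case geometry jitter (±4 % multiplicative
on sizes, ±2 mm on positions, seeded) makes every cohort member distinct;
containment (structures strictly inside the head, lens strictly inside the
eyeball) is verified analytically on the jittered parameters by sampling
~200 directions per structure, and violations are a hard error rather than
a silent clip.

MR intensities follow a piecewise-constant class model in arbitrary units,
`mean · (1 + bias) + noise`, clamped at 0: the bias is a smooth
multiplicative field (default amplitude 5 %) emulating coil shading, and
the noise is Gaussian (default SD 3 against class-mean separations of
15–50). The means encode the sequence contrasts that the segmentation
rules rely on: CSF dark on T1 / bright on T2, the lens the reverse, bone
and internal air dark on both, and bone distinguishable from air only on
PETRA. The full table is printed in `?phantom_spec`.

The reference CT is deliberately **not** the ideal bulk CT, otherwise the
evaluation metrics would saturate and could not rank `BCT` above `WCT`:
class means sit near but not at the bulk values (body 30, ventricle 20,
brainstem −40, eyeball 290, lens 320, cavity −980, bone 970 HU), Gaussian
noise of 10 HU (a typical head-CT noise level) covers the volume, and a
smooth additive artifact field (default ±30 HU) is applied inside the head
only, mimicking object-induced beam-hardening/scatter; open air carries
noise alone. The artifact field is a stationary random field — unit
cosines at 2–3 cycles per FOV with random phases — so its value
distribution is identical across cases while its spatial arrangement
varies; per-case random amplitudes would make the cohort variance an
artifact of the simulator rather than of the imaging physics being
emulated. Values are floored at −1000 HU, the air calibration point.

What the phantom does *not* model: partial-volume mixing at class
boundaries (voxels are pure classes), MR relaxometry and k-space effects,
geometric distortion, lesions, immobilization devices, and couch/table
structures. Passing tests on the phantom therefore demonstrate the
*correctness of the pipeline and metrics under separable contrasts*, not
clinical segmentation accuracy; real-data accuracy would be limited
precisely by the effects the phantom omits.

# Automatic segmentation

`segment_body()` thresholds PETRA — the one sequence in which the whole
head, bone included, retains signal — at a fraction (default 0.5) of a
robust reference percentile (default p99), keeps the largest 3D connected
component and fills internal holes slice-wise, which pulls air-filled
cavities into the body. Connected components are computed by 2D labeling
per slice merged across adjacent slices with a union-find.

`classify_tissues()` applies a deterministic rule cascade inside the body
mask, in the order bone → cavity → ventricle → eyeball → lens → brainstem,
with residual voxels becoming body and everything outside the mask air.
Each rule is a conjunction of per-sequence intensity bounds; the first
matching rule wins, which is the entire tie-breaking policy — the order
puts the high-confidence, globally-identifiable classes (bone, cavity)
first. The localized classes are additionally gated by atlas-style priors:
generous axis-aligned ellipsoids (2–4× the expected structure extent)
expressed in the frame that maps the body bounding box to the unit cube.
This is the minimal form of locational information — it requires no
inter-subject registration, and the priors gate rules rather than
delineate anatomy, so their exact extent is uncritical as long as they
cover the structure and exclude look-alike tissue elsewhere (e.g. the
ventricle and eyeball share a T1-dark/T2-bright signature and are
separated purely by location).

Default thresholds are calibrated to the phantom's intensity table, and a
percentile normalization hook (`normalization_pct`) is provided for data
on other scales. Cleanup removes per-class connected components smaller
than 3 voxels (relabeled as body); the lens is exempt because it is the
smallest structure and can legitimately be a couple of voxels. Optional
morphological opening/closing radii exist but default to 0: at
2.3–2.5 mm voxels the skull shell and lens are only 1–2 voxels thick, and
a radius-1 opening would destroy exactly the structures that are hardest
to segment.

# Evaluation metrics and numerical choices

**Overlap.** `overlap_scores()` implements DSC / FND / FPD in percent from
voxel counts. FND and FPD are not clamped — an empty segmentation against
a nonempty truth gives FND = 200, which is what the definitions yield —
and the identity `FND + FPD = 200 − 2·DSC` is enforced in tests as an
exact algebraic property. Cohort SDs use the n−1 convention; a
single-case cohort reports SD 0 with an explicit degenerate flag rather
than NaN so that report tables stay rectangular. Two empty masks make the
metric undefined and raise an error.

**Histograms.** 256 bins over [−1000, 1000] HU by default — the span of
the bulk table — applied identically to both images, with out-of-range
values clipped into the end bins and unit-sum normalization (required for
the intersection's perfect-match value of 1). Histograms are global (full
grid) by default, with an optional ROI. Correlation uses mean-centered
histograms, the convention under which a perfect match scores 1 and no
correlation 0; a zero-variance histogram makes correlation undefined —
`hist_correlation()` raises, while `compare_histograms()` reports NA with
a degenerate flag and still computes the other three. Chi-square uses the
symmetric denominator `H₁+H₂` (both-zero bins contribute 0), making all
four measures symmetric under swapping the inputs. The Bhattacharyya
distance is implemented in its Hellinger form, which satisfies the 0 =
perfect / 1 = total-mismatch anchors.

**Gamma.** The gamma index combines a distance-to-agreement criterion
Δd_M (mm) and a value-difference criterion ΔD_M (percent of a
normalization value) into `γ(r₁) = min_{r₂} √(Δr²/Δd_M² + ΔD²/ΔD_M²)`;
a voxel passes at γ ≤ 1 (inclusive, the standard convention). Choices
that the classical dose-space formulation leaves open here:

- *Normalization.* ΔD_M is a percentage of the reference's dynamic range
  (max − min) within the ROI. CT numbers are negative-valued, so a
  max-based normalization would need an arbitrary shift; the dynamic range
  is shift-invariant and deterministic. A constant reference in the ROI is
  a degenerate-normalization error.
- *ROI.* The minimum axis-aligned rectangle covering the body, per axial
  slice (2D mode, the default — planar gamma maps are the convention in
  treatment-plan QA) or as a single 3D box. Candidate points r₂ may lie
  outside the ROI but inside the grid.
- *Search.* Exhaustive over voxel centers within a search radius of
  `search_radius_factor × Δd_M` (default factor 2). Any candidate beyond
  that radius contributes γ > factor from its distance term alone, so
  every reported value up to the factor — and every pass/fail decision at
  γ ≤ 1 for any factor ≥ 1 — is exact; larger reported values are upper
  bounds, and the cap is recorded on the `gamma_map`. Setting the factor
  to `Inf` makes the search exhaustive over the grid, which is how the
  test suite proves the engine identical to an independent brute-force
  all-pairs implementation on random images.
- *Interpolation.* None by default: γ is evaluated at voxel centers, the
  defined discrete rule that brute-force equivalence is proved against. An
  optional integer in-plane upsampling of the evaluated image (bilinear)
  refines the distance-to-agreement search toward sub-voxel matches in 2D
  mode.

Tightening both criteria scales both γ terms up, so per-voxel γ is
monotone and pass rates are automatically ordered
3 mm/3 % ≥ 2 mm/2 % ≥ 1 mm/1 %.

# Cohort statistics

`welch_t_test()` implements the unequal-variance two-sample t statistic
with Welch–Satterthwaite degrees of freedom and a two-sided p-value;
`t.test()` serves as an independent cross-check in the test suite, not as
the implementation. When both samples have zero variance and equal means
the statistic is undefined and is reported as t = 0, p = 1 with a
degenerate flag. `required_sample_size()` uses the two-sample normal
approximation `n = ⌈2(z₁₋α/₂ + z_power)²/δ²⌉` — at power 0.9 and α = 0.05
a standardized effect of 1 needs 22 per group. The study's "improvement"
rows are defined as the signed mean difference in the direction favoring
`BCT` (higher correlation/intersection/pass rate, lower
chi-square/Bhattacharyya); the definition is stated because summary tables
in this literature do not always make their improvement arithmetic
explicit, and it is applied consistently.

`run_study()` chains phantom → segmentation → synthesis → all metrics per
case and aggregates; it is deterministic given the phantom seed (every
random draw is derived from (seed, case id, volume) triples), errors are
tagged with the case id and stage, and a single-case study produces a
degenerate-flagged report with no tests rather than failing.

# Problem sizes

The default study is 20 cases on the full 40 × 128 × 128 grid — about a
minute of compute — and is what `scripts/acceptance.R` runs. Unit tests
use a quarter-scale phantom (24 × 64 × 64) with identical physics, and the
gamma engine's exactness is proved on 24 × 24 single-slice images where
the all-pairs brute force is cheap.

# Known limitations

- Default segmentation thresholds are calibrated to the phantom's
  documented intensity model; on real scanner data they would need the
  normalization hook and likely re-tuned bounds, and no claim is made that
  phantom overlap scores predict clinical ones.
- The gamma engine reports upper bounds beyond the search-radius cap
  (exact values require `search_radius_factor = Inf`, at a cost).
- 3D gamma mode does not support upsampling; 2D mode upsamples in-plane
  only.
- The phantom's reference CT heterogeneity is a stylized stand-in for
  acquisition physics; absolute metric levels on the phantom are not
  comparable to values measured on patient data, only the relative
  WCT-vs-BCT structure is.
- DICOM import, registration, resampling between grids, dose calculation
  and DVH analysis are out of scope.
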