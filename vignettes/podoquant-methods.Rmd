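---
title: "podoquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{podoquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

podoquant quantifies the image-based readouts of podocyte mechanobiology:
focal-contact morphometry, filtration slit density, filopodia, spreading,
migration, adhesion under stretch, and the numerical post-processing
around them. This vignette records the models behind each pipeline, the
parameters that matter, and the design decisions taken where the methods
literature leaves the operator under-specified.

## Conventions

All coordinates are 1-based `(row, col)` pixel positions, following R's
native matrix indexing; everything reported to the user is in physical
units (µm, µm², µm/min, µm⁻¹) derived from the isotropic pixel size of
the scene. Pixel size is deliberately a *required* input: published
figures rarely state the acquisition scale, and silently assuming one
would corrupt every downstream unit. `readImageScene()` takes it from
TIFF resolution tags when present (including the ImageJ convention of
resolution unit "none" meaning pixels per micrometre), then from the JSON
sidecar written by `writeImageScene()`, then from an explicit override —
and errors otherwise. Time-lapse frame intervals default to 20 min, the
lower end of typical live-cell acquisition cadence for migrating
podocytes.

## Focal-contact segmentation

The segmentation chain is a gradient-gated adaptive threshold:

1. **Local threshold.** Foreground is `I > mean_w + k * sd_w` in a
   square window (`window = 31` px, `k = 1`). The window is about twice
   the diameter of a large adhesion at 0.1 µm/px, so the local statistics
   are background-dominated.
2. **Boundary-gradient gate.** A candidate component is kept only if the
   mean Sobel gradient magnitude on its boundary exceeds the
   `gradientQuantile = 0.95` quantile of the scene-wide gradient
   distribution. This is the specificity mechanism: pixel clusters
   assembled from noise cross the local threshold with boundary gradients
   on the order of the noise sd, while genuine adhesions present an
   intensity step of half their amplitude per pixel. Empirically the two
   populations are separated by a factor of four; a lower quantile (say
   0.75) sits *below* the selection-biased gradient of noise clusters and
   admits them wholesale in sparse scenes, so the stricter default is the
   one that actually delivers precision ≥ 0.9 at SNR 10.
3. **Area gate.** 0.1–20 µm²; podocyte adhesions average ~1.2–1.8 µm².
4. **Centre/periphery filter.** Centre = innermost 25% of component
   pixels by distance transform; periphery = 3-px ring outside the
   component, excluding pixels of other components (so a close neighbour
   does not inflate the reference). Components with centre/periphery
   ratio < ρ = 1.2 are removed. A component whose ring would fall
   entirely outside the image is retained with a warning rather than
   silently judged on a truncated ring.
5. **Splitting.** Components with several internal distance-transform
   maxima deeper than `splitDepth` × (component max distance) are split
   along the watershed lines of the distance map; unassigned ridge
   pixels are flood-assigned to the nearest child so the total pixel
   count is conserved exactly, and children below the minimum area are
   re-merged into the sibling they touch most. `splitDepth = 0.2`: for
   the canonical test geometry — two discs of radius 5 px whose centres
   are 8 px apart — the saddle of the distance map sits at ~4 px against
   maxima of ~5.1 px, a relative depth of 0.22, so a deeper requirement
   (e.g. 0.4) can never separate even this clearly bimodal shape.
   Degenerate case: a convex component has one maximum and is returned
   unchanged; the operation is idempotent on its own output.

Components are 8-connected throughout (implemented as a union-find merge
over the 4-connected labelling, since the underlying labeller is
4-connected). Shape descriptors come from second central moments with the
1/12-px self-variance term; axis lengths use the 4√λ convention, and
orientation is the major-axis angle to the x (column) axis. Both mean and
integrated intensity are reported, since conventions differ between
tools. Contacts straddling two cells are assigned by centroid only.

Within-cell position: `radial_position` is the ratio of
(cell centroid → contact centroid) to (cell centroid → cell boundary
along the same ray), marched in 0.25-px steps and clipped to [0, 1].
Contacts whose centroid lies on background are flagged and retained.

## Filtration slit density

FSD = total slit length / capillary area (µm⁻¹). The slit channel is a
2D projection (z-colorized super-resolution stacks are consumed after
projection; reconstruction is out of scope). Thresholding defaults to
Otsu; a constant image yields an empty mask with a warning rather than an
error.

**Skeleton length.** The mask is thinned (Guo–Hall two-subiteration
thinning, implemented here because no installed package provides 2D
skeletonization) and measured by the orthogonal/diagonal step metric:
1 px per orthogonal neighbour pair, √2 per diagonal pair — a plain pixel
count underestimates diagonal curves by up to 29%. The raw step metric,
however, systematically *over*estimates digitized oblique curves (+8% at
22.5°, +5.4% on a rasterized circle), so by default three corner-cutting
smoothing passes are applied to chain pixels (degree ≤ 2; endpoints and
junctions stay fixed) before summing Euclidean segment lengths. On
straight orthogonal or diagonal chains the smoothed estimate equals the
raw metric exactly; on a rasterized circle of radius 10 µm it is within
0.3% of 2πr. `skeletonPathLength(..., smooth = 0)` recovers the raw
metric. No branch pruning is applied: the generators' curves are simple,
and pruning heuristics would trade a known small positive bias for an
unknown negative one.

**Capillary area.** An explicit ROI polygon when given (the
operator-delineation route); otherwise the filled morphological envelope
of the slit mask — closing at 1 µm, which bridges foot-process-scale gaps
between slits without merging separate capillaries, then hole filling.

## Cell-level quantification

* **Seeded segmentation** — Gaussian smoothing (σ = 2 px), Otsu
  foreground, then marker-controlled region growing from the seed points;
  one label per seed, partitioning the foreground. A seed on background
  is an error naming the seed, not a silent skip.
* **Nuclei** — scale-normalized Laplacian-of-Gaussian filtering at the
  blob scale, 3×3 local maxima, non-maximum suppression at the blob
  radius, and per-axis quadratic subpixel refinement. The subpixel step
  matters downstream: integer-pixel centroids alias random-walk steps and
  depress tracked speeds by ~20%. This classical detector deliberately
  replaces a trained-network detector: it needs no weights, is fully
  testable, and is adequate for well-separated stained nuclei. Two
  nuclei closer than the blob scale merge into one detection — a
  documented limitation, not a defect.
* **Tracking** — greedy nearest-neighbour frame-to-frame assignment
  under a maximum displacement (default 30 µm) with gap closing
  (default 1 missed frame), rather than a global assignment solver; with
  spacing above twice the step size the greedy solution is exact, which
  the tests verify (zero identity switches). Mean speed = total path
  length / total duration; net displacement is also emitted because the
  distance convention varies between studies.
* **Filopodia** — the cell body is the morphological opening of the mask
  at 2 µm; protrusions (mask minus body) touching the body are
  skeletonized and measured by geodesic (Dijkstra, √2-weighted) distance
  from the base — the skeleton pixel nearest the body, with the residual
  base offset added — to the farthest tip. Filopodia shorter than 1 µm
  are discarded. Neither radius nor minimum length is stated in the
  methods literature; 2 µm is well above a filopodium's width and well
  below a cell body's radius, and 1 µm suppresses boundary roughness
  left by the opening.
* **Spreading** — per-timepoint mean and sd of cell areas; an empty
  timepoint is recorded as missing (`NA`), never as zero area.

## Statistics

Two groups: two-sided unpaired t test, pooled variance by default (Welch
optional). More than two: one-way ANOVA as a gate, then all pairwise
unpaired t tests with Benjamini–Hochberg adjustment across the pairs —
the natural reading of "ANOVA followed by a BH post-hoc test". BH itself
is `stats::p.adjust(method = "BH")` behind a validating wrapper, checked
in the tests against the hand-computed step-up recursion. Under the null
the gated procedure's family-wise rate runs below the nominal 5% (the
gate is conservative); the tests bound it at 7% over 1000 simulations.

The volcano filter treats thresholds as inclusive and the down threshold
as the reciprocal of the up threshold (symmetric on the log scale); a
flag accepts log2 fold changes, since deposited tables use either
convention. Non-positive fold changes are an error naming the offending
row.

The stretch membrane is modelled as a spherical cap: a centre deflection
h on a clamped circular membrane of radius a gives ΔA/A = (h/a)² and
mean linear strain √(1 + ΔA/A) − 1, so an 11% area increase is a 5.36%
(≈5%) linear strain — a conversion that is model-independent. The
membrane radius has no default: it is apparatus-specific (the radius
consistent with a 6 mm deflection producing 11% is ≈18.1 mm under the
cap model).

Pfaffl ratio: E_t^ΔCt,t / E_ref^ΔCt,ref with efficiencies validated to
[1, 2.2]; at E = 2 for both genes it reduces exactly to the ΔΔCt model,
which the tests assert.

## Synthetic scenes: what they emulate, and what they do not

Every generator is deterministic given its seed, stores physical truth
(µm-based, never pixels), and is scored without reference to the
analysis code.

* **Focal-contact scenes** (defaults: 640×640 px at 0.1 µm/px, 200
  contacts, gamma-distributed areas with mean 1.32 µm² and CV 0.35, axis
  ratios 1.5–3): elliptical plaques with a centre-bright generalized
  Gaussian profile (exponent 8 — a plateau with a steep rim, as adhesion
  plaques appear in IF), amplitude ratio 2 between centre and rim,
  truncated at the ellipse edge so the planted mask is the measurable
  object support; a blurred cell-shaped diffuse background; optional
  just-touching pairs; Poisson (gain 1) then Gaussian noise, with SNR
  defined as peak amplitude / Gaussian sd (default 200/20 = 10).
* **Slit scenes** (defaults: 0.02 µm/px, capillary radius 4 µm): a
  family of parallel, in-phase sinusoids (amplitude 0.6 µm, wavelength
  3 µm, random global orientation/phase/register) — in-phase so the
  perpendicular spacing stays constant and skeletonization cannot merge
  neighbours. The scene's true capillary mask is the filled 1-µm-closing
  envelope of the curves, the same definition the measurement applies;
  curve spacing is calibrated in 2–3 passes so the planted length/area
  ratio lands within 1% of the target density, and an unreachable target
  (spacing below twice the line width) errors.
* **Filopodia scenes**: a disc body with straight, 3-px-wide protrusions
  at well-separated angles; planted geodesic length is exact by
  construction (the drawn tip is pulled in by the rasterization cap
  radius).
* **Nuclei time lapses**: Gaussian spots under drift + isotropic
  Gaussian random walk, with margins sized so no track leaves the frame;
  truth speeds are path length / duration per track.
* **Proteome tables**: exactly n_up rows passing both up-thresholds,
  n_down passing both down-thresholds, and the remainder constructed to
  fail at least one criterion strictly.

Passing these benchmarks shows the pipelines recover known geometry and
statistics under a realistic noise model. It does **not** show
performance on real micrographs: the generators have no uneven
illumination, no out-of-focus haze, no autofluorescent debris, no
touching *cells*, and adhesion/slit geometry far tamer than diseased
tissue. The acceptance-style tests therefore validate the *operators*,
not any biological claim.

## Problem sizes and reproducibility

The test suite exercises: 20 focal-contact scenes of 200 contacts for the
recovery benchmark; slit scenes at planted densities 2, 4.25, 4.57 and
6 µm⁻¹ with two groups of six capillaries in 12 ordering replicates; 20
paired filopodia scenes planted at −35% count and −47% length; and 1000
null simulations for the multi-group error rate — sizes chosen to give
each estimate comfortable statistical margin on a single CPU. All
randomness flows through explicit seeds; `scripts/acceptance.R` derives
every generator seed from its `--seed` argument.

## Known limitations

* The centre/periphery ratio is undefined (component retained, ratio
  `NA`) when the periphery ring is empty or dark; callers filtering on
  the ratio should treat `NA` explicitly.
* Thinning-based length measurement needs curves at least ~4 px apart at
  the working resolution; below that, merged skeletons inflate length —
  the generator refuses such densities rather than producing them.
* Greedy linking is exact only for well-separated objects; crossing
  tracks can swap identities where a global solver would not.
* The TIFF writer emits 16-bit samples; intensities above 65535 are
  refused rather than rescaled.
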