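# podoquant

Quantitative image analysis and statistics for podocyte cell biology.

Podocytes are the terminally differentiated epithelial cells whose
interdigitating foot processes form the kidney's filtration slits. Their
mechanobiology is read out through a handful of image-based quantities:
the size and position of focal contacts (integrin-based adhesion plaques
visible as bright puncta in vinculin/talin/paxillin immunofluorescence),
the filtration slit density of the glomerular capillary, filopodia number
and length, cell spreading and migration speed, adhesion under cyclic
stretch, and threshold-filtered differential-proteome tables. podoquant
implements each of these readouts as a tested, reusable pipeline, and
pairs every pipeline with a seeded synthetic-scene generator that carries
exact ground truth, so the whole toolbox can be benchmarked end to end
without any microscope.

## What it computes

**Focal-contact morphometry.** Contacts are segmented by an adaptive
local threshold (local mean + *k*·sd in a *w*×*w* window), gated by the
mean boundary gradient against a scene-wide gradient quantile and by
physical area. A centre/periphery specificity filter removes flat,
unspecific blobs: for each candidate the innermost 25% of pixels (by
distance transform) must be at least ρ-fold brighter than a 3-px ring
outside the component. Slightly connected contacts are separated along
watershed lines of the distance transform seeded at deep internal maxima
(pixel-count conserving). Each contact is reported with area (µm²), axis
lengths, eccentricity, orientation, mean/max/integrated intensity, and —
given a seeded cell segmentation — its cell and normalized radial
position in [0, 1].

**Filtration slit density (FSD).** The slit-diaphragm signal of a
projected super-resolution image is thresholded (Otsu or fixed), thinned
to a one-pixel skeleton, and measured with a diagonal-corrected step
metric (1 / √2 pixel steps, with corner-cut smoothing of chain pixels to
remove staircase digitization bias). The capillary area is an explicit
ROI or the filled morphological envelope of the slit signal, and

&nbsp;&nbsp;&nbsp;&nbsp;FSD = slit length / capillary area  [µm⁻¹].

**Cell dynamics.** Seeded (semi-automatic) cell segmentation by
marker-controlled region growing; spreading areas over time; nuclei
counting by scale-space Laplacian-of-Gaussian blob detection with
subpixel refinement; adhesion change as 100·(n − n_ref)/n_ref; migration
tracking by greedy nearest-neighbour linking with gap closing, mean speed
= path length / duration (µm/min); filopodia as skeletonized protrusions
left by morphologically opening the cell mask, each measured by its
geodesic skeleton length.

**Statistics.** Unpaired two-sided t tests (pooled or Welch) for two
groups; one-way ANOVA followed by all pairwise t tests with
Benjamini–Hochberg adjustment for multi-group designs; the
efficiency-corrected qPCR ratio E_target^ΔCt,target / E_ref^ΔCt,ref
(Pfaffl model); volcano filtering of differential tables (up: FC ≥ 1.5
and p ≤ 0.05, down: FC ≤ 1/1.5 and p ≤ 0.05, thresholds inclusive);
spherical-cap membrane strain geometry ΔA/A = (h/a)², strain =
√(1 + ΔA/A) − 1; mean fluorescence intensity inside a mask.

## Worked example

```r
library(podoquant)

# a synthetic immunofluorescence scene: 50 focal contacts, SNR 10
sim <- synthFaScene(faSceneSpec(nFa = 50, seed = 1))
res <- quantifyFocalAdhesions(sim$scene)
nrow(res$contacts)                      # 50
mean(res$contacts$area_um2)             # 1.237
mean(res$contacts$center_periphery_ratio)  # 2.63

# a slit-diaphragm scene planted at 4.57 µm^-1
slit <- synthSlitScene(slitSceneSpec(targetFsd = 4.57, seed = 2))
measureSlitDensity(slit$scene)
#> SlitNetwork
#>   slit length   : 228.74 µm
#>   capillary area: 49.696 µm²
#>   FSD           : 4.603 µm⁻¹

# stretch geometry: 6 mm centre deflection on an 18.09 mm membrane
membraneStrain(6, 18.09)
#> MembraneGeometry (spherical cap)
#>   deflection h  : 6 mm
#>   radius a      : 18.09 mm
#>   area increase : 11.00%
#>   linear strain : 5.36%
```

The 50 planted contacts are all recovered (detection precision and
recall 1.0 on this scene); the measured mean single-contact area of
1.24 µm² sits within 7% of the planted 1.32 µm² mean — the residual is
threshold erosion of the dim contact rim at this noise level. The slit
scene's measured density of 4.60 µm⁻¹ is within 1% of the planted 4.57.
An 11% membrane-area increase corresponds to a 5% mean linear strain.

## Command line

A thin launcher (`inst/cli/podoquant`) exposes the pipelines as
subcommands over TIFF/CSV/YAML files:

```sh
podoquant simulate fa --seed 1 --out out/
podoquant fa-quant out/fa_scene.tif --out out/
podoquant fsd slit.tif --pixel-size 0.02 --out out/
podoquant strain --height 6 --radius 18.09
podoquant volcano-filter table.csv --out out/
```

Every run writes its results as CSV plus a plain-text log of all resolved
parameters and the seed; a YAML config (`--config`) supplies defaults
that flags override.

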