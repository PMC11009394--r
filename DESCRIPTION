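Package: podoquant
Title: Quantitative Image Analysis of Podocyte Adhesion, Morphology and
    Filtration Slits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-analysis and statistics pipelines for podocyte cell
    biology: gradient-gated local-threshold segmentation and morphometry of
    focal contacts (size, shape, intensity and within-cell position),
    filtration-slit-density measurement from slit-diaphragm stainings
    (skeleton length per capillary area), seeded cell segmentation with
    spreading, filopodia and migration quantification, nuclei counting and
    adhesion-loss estimation, stretch-membrane strain geometry,
    efficiency-corrected qPCR ratios, group comparisons with
    Benjamini-Hochberg control, and volcano-style fold-change/p-value
    filtering of differential-abundance tables. Includes seeded synthetic
    scene generators with exact ground truth for benchmarking every
    pipeline, plus TIFF/CSV/YAML input-output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'ImageScene-methods.R'
    'utils-internal.R'
    'skeleton.R'
    'io.R'
    'synthFa.R'
    'synthSlit.R'
    'synthCells.R'
    'synthProteome.R'
    'faMorphometry.R'
    'cellDynamics.R'
    'slitDensity.R'
    'statsReporting.R'
    'cli.R'
    'podoquant-package.R'
RoxygenNote: 7.3.3
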