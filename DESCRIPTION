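Package: ubimod
Title: Chemical Shift Perturbation Mapping, Global Binding-Isotherm Fitting
    and Interactome Statistics for Ubiquitin Variants
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of site-specifically modified ubiquitin
    variants. Reads assigned two-dimensional 1H-15N HSQC peak lists and
    computes weighted chemical shift perturbations with pooled
    mean / mean-plus-one-standard-deviation significance cutoffs, sequence
    clusters and hydrophobic-patch overlap; assembles HSQC titration series
    and extracts a shared dissociation constant by globally fitting the exact
    1:1 binding quadratic across residues; re-implements a label-free
    affinity-enrichment proteomics workflow (contaminant filtering, log2
    transformation, valid-value filtering, downshifted-normal imputation,
    S0-moderated ANOVA with permutation-based FDR, z-scoring, median bait
    profiles, correlation clustering); and derives residue-residue mean
    minimum-distance matrices from multi-model PDB coordinate ensembles.
    Seeded synthetic-data generators with known ground truth make every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, StructuralPrediction, Software
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'lfq-experiment.R'
    'aems-stats.R'
    'peak-io.R'
    'csp-core.R'
    'titration.R'
    'struct-dist.R'
    'synthetic-data.R'
    'pipeline.R'
    'ubimod-package.R'
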