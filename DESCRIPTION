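Package: pairclass
Title: Paired-Condition Classification of Resting-State fMRI ALFF Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Within-group (paired-condition) classification of resting-state
    fMRI. Computes amplitude of low-frequency fluctuation (ALFF) maps in
    conventional and slow-band frequency ranges from 4D NIfTI volumes,
    selects features with voxel-wise paired t-tests and Monte-Carlo
    cluster-extent correction, builds signed within-subject difference-map
    samples (the PAIR scheme) or condition-stacked samples (the UNPAIR
    baseline), and classifies them with a linear soft-margin support vector
    machine with squared hinge loss. Includes leave-one-out and
    cross-dataset validation, feature-weight analysis against cluster
    t-values, and a synthetic paired-fMRI data generator with planted
    band-limited effects so the whole pipeline is testable without any
    external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'alff.R'
    'masks.R'
    'paired-stats.R'
    'features.R'
    'classification.R'
    'nifti.R'
    'pairclass-package.R'
    'smoothing.R'
    'synthetic.R'
    'pipeline.R'
    'reference-tables.R'
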