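Package: rsfcperm
Title: Permutation Inference for Resting-State Functional Connectivity in
    Minor Cerebrovascular Event Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A lesion-aware analysis pipeline for resting-state functional
    connectivity (rsFC) studies of minor stroke and transient ischaemic
    attack (TIA) cohorts. Provides BOLD nuisance cleaning (ordinary
    least-squares confound regression with a discrete cosine high-pass
    basis, z-scoring, Gaussian smoothing, probabilistic-atlas
    parcellation), lesion-artifact component flagging via the Jaccard
    index, partial-correlation network estimation over an 11-node
    default-mode / frontoparietal parcellation, Westfall-Young maxT
    permutation tests of group differences in edge strength, robust
    (Huber) confound residualisation, Manly-permutation tests of
    connectivity-by-group interactions on cognition, and cohort summary
    statistics. A synthetic-cohort generator with known ground truth makes
    every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
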