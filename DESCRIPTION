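Package: lnmapper
Title: Literature-Based Lesion Network Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lesion network mapping (LNM) from binary lesion masks and a
    normative resting-state functional connectome: per-lesion seed
    correlation T-maps, binarize-and-overlap network maps, sign-flip and
    two-sample permutation inference with max-statistic family-wise error
    control, leave-k-out stability, winner-takes-all thalamic
    parcellation with repeated-measures post-hoc tests, and tabulation of
    MRI classification system (MRICS) lesion-pattern findings.  Includes
    a synthetic-data module that simulates connectomes with planted
    network structure, lesion cohorts, and grey-matter-restricted sphere
    control cohorts so every pipeline stage can be exercised and
    validated without access to patient data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
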