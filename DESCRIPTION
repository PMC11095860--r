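Package: ARpipe
Title: Paired-Biopsy Profiling of Acquired Resistance to Immune Checkpoint Blockade
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for matched pre-/post-therapy tumor biopsy
    cohorts profiled for acquired resistance to PD-(L)1 blockade. Implements
    a cohort-frequency tumor similarity score for shared-lineage assessment,
    purity-corrected absolute copy number from segmented log2 ratios with an
    arm-level aneuploidy score, acquired mutation/copy-number alteration
    calling with biallelic-inactivation detection, spatial single-cell
    PD-1/PD-L1 engagement and nearest-neighbor distance metrics from
    multiplexed immunofluorescence cell tables, immunohistochemistry H-score
    statistics, exact paired nonparametric tests, and a seeded synthetic
    paired-cohort generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
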