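Package: clonalpair
Title: Clonality Concordance Analysis of Paired Primary and Metastatic Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies primary carcinoma / metastasis pairs as clonally
    related or genetically distinct from somatic copy-number alteration (SCNA)
    profiles and somatic mutation lists. Provides SEG/MAF-like table readers,
    per-sample SCNA burden summaries over five event categories, binned
    copy-number matrices, deterministic agglomerative hierarchical clustering
    with a dendrogram pair-adjacency criterion, shared-mutation (Jaccard)
    statistics and driver-gene concordance between paired samples,
    hypermutation calling with mismatch-repair and polymerase gene-panel
    screens, t-test based association of hypermutation with loss of
    heterozygosity burden, a rule-based clonality classifier, and a synthetic
    cohort generator with known truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
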