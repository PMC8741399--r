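Package: varfuse
Title: Exact-Match Sequence Indexing and Bayesian Fusion of Variant Call Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Self-contained toolkit for ensemble tumour variant detection at
    desk scale. Implements the classical exact-match index structures used by
    short-read aligners (Burrows-Wheeler transform, suffix array, suffix tree,
    FM-index backward search, and base-4 k-mer hash seeding), consensus voting
    over alignment sets produced by multiple aligners, Bayesian evidence fusion
    of variant call sets from multiple callers with GATK-style hard filtering,
    sparse incidence-matrix statistics (greedy L0 recovery, spark, restricted
    isometry bounds, between/within-class scatter traces), and a simulation
    harness that implants SNP and short indel truth sets into synthetic
    references and measures precision and recall of individual and fused
    callers across sequencing depths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Matrix,
    Rsamtools,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
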