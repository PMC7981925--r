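Package: svexpr
Title: Integrating Somatic Structural Variant Breakpoints with Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates somatic structural variant (SV) breakpoints with
    gene expression across a cancer cohort. Builds gene-by-sample breakpoint
    matrices over configurable region windows (optionally distance-weighted
    within 1 Mb), fits per-gene linear models of expression against breakpoint
    pattern correcting for cancer type and gene-level copy number, controls
    the false discovery rate with Storey-Tibshirani q-values, and annotates
    candidate mechanisms: enhancer translocation (hijacking), disruption of
    topologically associated domains (TADs), and corroboration of RNA-seq
    gene-fusion candidates by within-gene breakpoints. A seed-controlled
    synthetic-cohort simulator emulates all inputs so every stage is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
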