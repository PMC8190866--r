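Package: eretarget
Title: Estrogen Response Element Scanning and ERalpha Direct-Target Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative toolkit for calling genes directly targeted by the
    estrogen receptor alpha (ERalpha) from ChIP-seq binding sites and
    RNA-seq expression contrasts. Implements estrogen response element (ERE)
    identification on binding sites by count-matrix log-odds scanning with
    exact score-distribution p-values and a consensus mismatch co-filter,
    peak-to-TSS genomic localization, differential-expression thresholding
    with the <50 kb upstream direct-target rule, a six-criterion lncRNA
    identification cascade, miRNA-mRNA consensus target networks,
    hypergeometric over-representation with Benjamini-Hochberg correction,
    and qPCR 2^-ddCt / ChIP-qPCR fold-enrichment arithmetic. A synthetic-data
    generator with serialized ground truth exercises the full pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
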