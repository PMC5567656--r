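Package: srnannot
Title: Annotation of Small Non-Coding RNA Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Complete annotation of small RNA sequencing libraries against
    user-supplied local reference collections. Provides automated 3' adapter
    motif inference and trimming, low-complexity read filtering, tiered miRNA
    annotation with 3' tailing and internal modification profiling, fractional
    apportioning of multi-class ncRNA/mRNA read counts, classification of
    tRNA-derived fragments (tRFs and tRNA halves), piRNA candidate calling
    with ping-pong signature Z-scores, and detection of phased siRNAs
    (phasiRNAs) in genome map files via a binomial sliding-window statistic.
    Includes seeded synthetic data generators that emulate all supported
    input types for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
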