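Package: apascreen
Title: Alternative Polyadenylation Landscape Analysis and Regulator Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying alternative polyadenylation (APA) from
    3'UTR read coverage and for screening APA regulators and their targets
    in tumor cohorts. Implements a two-isoform linear-regression estimator
    of the Percentage of Distal polyA site Usage Index (PDUI) with
    breakpoint search, PDUI-based hierarchical clustering of cohort
    samples, a regulator screen combining differential expression,
    gene-set intersection, and expression-versus-APA-burden correlation,
    canonical/non-canonical polyadenylation-signal (PAS) classification of
    3'UTRs, and a three-criterion APA target funnel. A synthetic-data
    module generates coverage tracks, cohort matrices, and 3'UTR sequences
    with planted ground truth so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    fgsea,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    rtracklayer,
    GenomicRanges,
    IRanges
Config/testthat/edition: 3
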