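Package: trimethnet
Title: DNA Methylation-miRNA-mRNA Regulatory Network Integration for
    Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds three-layer epigenetic regulatory networks from
    case-control omics profiles: binomial calling of methylated CpG
    sites from bisulfite counts, sliding-window detection of
    differentially methylated regions, RPM/RPKM normalization and
    differential screening of miRNA and mRNA count matrices,
    strand-aware promoter assignment and seed-match target prediction,
    and correlation-based retention of DMR-miRNA-mRNA regulatory
    triplets.  Includes a seeded synthetic cohort generator with
    planted regulatory triplets (beta-binomial bisulfite counts,
    negative-binomial expression) so the whole chain is testable
    without external data, plus summary-statistics t-tests,
    trait-correlation tables and the 2^-ddCt transform for the
    clinical layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
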