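Package: meripr
Title: Window-Based m6A-Seq Peak Calling, Target Triage and Decay Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for MeRIP/m6A-seq experiments: strand-aware
    projection of aligned fragments from genome to isoform coordinates,
    sliding-window IP-over-input peak calling with a Fisher exact test and
    an (a x d)/(b x c) enrichment score, merging of positive windows into
    peaks, condition-unique peak comparison, metagene 5'UTR/CDS/3'UTR peak
    profiles, multi-dataset differential-expression triage with fold-change
    and p-value cutoffs, and small quantitative models (exponential-decay
    half-life fits, delta-delta-Cq relative expression, caliper tumor
    volume, Spearman rank correlation). Includes a seeded synthetic-data
    generator with negative-binomial background coverage and planted
    methylation peaks so the whole pipeline can be exercised without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
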