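Package: genomescars
Title: Copy-Number and Rearrangement Signatures, Chromothripsis, and
    Genome-Duplication Timing from Somatic Whole-Genome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of somatic whole-genome sequencing in
    karyotypically complex tumours such as undifferentiated sarcomas.
    Classifies allele-specific copy-number segments into 40 mutually
    exclusive categories and structural rearrangements into
    clustered/unclustered type-size categories, extracts mutational-process
    signatures by consensus non-negative matrix factorization with
    rank-selection diagnostics and constrained exposure refitting, detects
    chromothripsis with three randomness tests in sliding genomic windows,
    assesses recurrently rearranged megabase bins against a Monte Carlo
    breakpoint null model with bespoke q-values, applies rule-based driver
    triage to somatic and germline variants, and times whole-genome
    duplications and driver mutations from SNV multiplicities with
    bootstrap confidence intervals. A synthetic-cohort generator with
    known signature mixtures, clustered rearrangement fractions and
    duplication timings supports end-to-end testing without access to
    controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    cluster,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
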