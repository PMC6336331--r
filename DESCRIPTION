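Package: sigcohort
Title: Mutational Signatures, Somatic Filtering and IHC Subtype Analyses for
    Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis toolkit for targeted and exome sequencing of
    tumor cohorts: immunohistochemistry marker-positivity calling and breast
    cancer subtype assignment with exact contingency-table tests;
    duplicate-concordance somatic mutation filtering for FFPE samples;
    96-trinucleotide-channel mutation catalogs and strand-symmetric pair
    spectra; de novo mutational signature extraction by non-negative matrix
    factorization with cophenetic-coefficient rank selection, reference
    matching by cosine similarity and non-negative least-squares exposure
    estimation; permutation Kruskal-Wallis association testing of signature
    contributions with clinical covariates (plain, stratified and
    Freedman-Lane adjusted variants); local gene-set over-representation
    analysis; and seeded synthetic-cohort generators with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
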