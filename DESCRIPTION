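Package: apobecscan
Title: APOBEC Mutagenesis Enrichment Scoring and Cohort Statistics for
    Tumor Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies APOBEC-driven mutagenesis in tumor cohorts from
    somatic variant calls and a reference genome: pyrimidine-normalized
    96-channel substitution catalogs, the APOBEC mutagenesis enrichment
    score (AMS) over 41-nucleotide context windows, YTCA/RTCA
    tetranucleotide motif attribution separating APOBEC3A- from
    APOBEC3B-like activity, nonnegative least-squares refitting of
    signature activities against a reference catalog, survival
    dichotomization at the minimum log-rank cutpoint with Cox adjustment,
    two-stage Fisher mutation-pathway enrichment, bulk-expression immune
    scores (cytolytic score, score-correlated gene ranking, gene-set
    means), single-cell QC and Ro/e cell-type enrichment, and seeded
    generators of synthetic cohorts with known truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    methods,
    pracma,
    stats,
    survival,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
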