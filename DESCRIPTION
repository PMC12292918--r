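Package: repqtl
Title: Genetic Determinants of the T Cell Receptor Repertoire
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-trait analysis of CD8+ T cell receptor (TCR)
    repertoires against germline genotype. Builds V-gene and CDR3 7-mer
    usage phenotypes from clone tables (unique-clone counting, TMM
    normalisation, batch correction, rank-based inverse normal
    transformation), runs additive linear association scans against SNP
    dosages, classical HLA alleles and HLA amino-acid positions (including
    multi-residue omnibus tests and conditional analysis), derives
    family-wise significance thresholds by phenotype permutation, tracks
    clonal persistence across treatment timepoints with HLA-matched clone
    scoring, computes single-cell tumour reactivity scores, and compares
    overall survival between carriers and non-carriers of HLA-matched
    clones. A seeded synthetic-cohort generator with planted cis, trans and
    motif effects supports calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    edgeR,
    limma,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
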