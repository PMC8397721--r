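Package: clonemet
Title: Clonal Evolution and Immune Escape Analysis of Paired Primary-Metastasis Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired primary tumor and metastasis whole-exome
    cohorts: cancer cell fraction (CCF) estimation from read counts, purity and
    allele-specific copy number with a grid posterior and credible interval;
    clonal/subclonal classification; primary-to-metastasis clonal evolution
    pattern taxonomy (C-C, S-C, 0-C, ...) for SNVs and arm-level copy-number
    events; per-patient maximum-parsimony phylogenies from binary
    presence/absence matrices with mutation-count branch lengths; HLA loss of
    heterozygosity calling from allele-specific bin coverage; neoantigen depth
    and expression filtering; HLA-corrected tumor mutational burden; and a
    synthetic paired-cohort simulator with known clone structure for
    ground-truth validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
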