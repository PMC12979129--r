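Package: zincsig
Title: Consensus Zinc Signature Derivation and Tissue Zinc Scoring from
    Transcriptomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Derives a consensus zinc-stimulated gene signature from
    heterogeneous two-group expression datasets (microarray intensities or
    RNA-seq counts) by per-dataset moderated-t differential expression and
    vote counting, filters stress-response transcripts, and validates the
    signature against zinc-depletion experiments.  Scores tissue cohorts for
    inferred zinc status as the mean normalized log expression of the
    signature genes, and runs the downstream association analyses: fold
    change versus controls, quartile stratification and rank-sum comparison,
    clinical-covariate correlation, batch merging, genome-wide score-gene
    correlation, cross-dataset top-gene consensus, and pre-ranked gene set
    enrichment with a permutation null.  Includes a synthetic-data generator
    reproducing the statistical structure of multi-dataset zinc treatment,
    depletion, and disease-cohort studies for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    withr
Config/testthat/edition: 3
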