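Package: panethnet
Title: Integrative Proteomic Analysis of Autophagy-Impaired Paneth Cell Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline linking differential protein abundance
    in autophagy-impaired (Atg16l1-deficient) Paneth-cell-enriched intestinal
    organoids to selective-autophagy targeting and to up- or down-modulation of
    cellular processes. Stages cover differential-abundance filtering of
    label-free proteomic intensity tables (one-factor ANOVA, fold-change and
    peptide-count gates), mouse-to-human orthologue mapping, prediction of
    p62/LC3/ATG16L1 targets by experimental interactor lists, LIR-motif
    scanning and domain-domain interaction inference, signed aggregation of
    protein-to-process trends, a proteome-transcriptome concordance check that
    attributes abundance changes to autophagy-mediated turnover versus
    transcription, hypergeometric marker-gene enrichment, and a synthetic-data
    generator with planted ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
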