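Package: sarcomark
Title: Multi-Omics Biomarker Nomination and IHC Diagnostic Validation for Fusion-Driven Sarcoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline that nominates single-protein diagnostic
    biomarkers for a fusion-driven sarcoma (desmoplastic small round cell
    tumor, DSRCT) by intersecting three omics gates: one-vs-rest differential
    gene expression across tumor entities, knockdown-proteomics concordance
    across cell lines, and fusion-protein ChIP peak-to-gene assignment.
    Downstream stages build anchor-gene correlation signatures and
    knockdown-derived signatures, score bulk samples and single cells by
    single-sample GSEA, test enrichment by preranked GSEA with a permutation
    null, call super-enhancers from ranked H3K27ac signal by the tangent
    cutoff, quantify entity-specific CpG hypomethylation, and evaluate an
    immunoreactive-score (IRS) diagnostic rule via cutoff-indexed
    sensitivity/specificity curves. A synthetic multi-omics generator with
    planted ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    jsonlite
Config/testthat/edition: 3
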