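#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic multi-omics study and write it out.
#
# The bundle mirrors the study design the pipeline was built for: a
# multi-entity bulk expression cohort in which one entity (DSRCT) drives two
# planted biomarker genes, knockdown proteomics for two fusion-depleted cell
# lines, fusion-binding peaks, a heavy-tailed H3K27ac enhancer landscape, a
# methylation cohort with anchor-locus hypomethylation, tumor/normal single
# cells, and an IHC cohort scored by IRS.

library(sarcomark)

bundle <- generate_multiomics(seed = 42)
write_bundle(bundle, "scratch/synthetic_bundle")

tr <- bundle$truth
cat("Planted biomarkers: ", paste(tr$planted_biomarkers, collapse = ", "),
    " (anchor ", tr$anchor_gene, ")\n", sep = "")
cat("Coexpression module:", length(tr$coexpression_module), "genes\n")
cat("Knockdown-responsive proteins:", length(tr$dep_planted), "\n")
cat("Planted super-enhancer regions:", length(tr$se_regions), "\n")
cat("Hypomethylated CpGs:", length(tr$hypomethylated_cpgs), "\n")
cat("Bulk cohort:", ncol(bundle$expression), "samples;",
    nrow(bundle$expression), "genes\n")

dir.create("results", showWarnings = FALSE)
write_tsv_table(data.frame(
  component = c("planted_biomarkers", "coexpression_module", "dep_planted",
                "se_regions", "hypomethylated_cpgs"),
  n = c(length(tr$planted_biomarkers), length(tr$coexpression_module),
        length(tr$dep_planted), length(tr$se_regions),
        length(tr$hypomethylated_cpgs)),
  members = c(paste(tr$planted_biomarkers, collapse = ";"),
              paste(tr$coexpression_module, collapse = ";"),
              paste(tr$dep_planted, collapse = ";"),
              paste(tr$se_regions, collapse = ";"),
              paste(tr$hypomethylated_cpgs, collapse = ";"))),
  "results/01_truth_summary.tsv")
cat("Bundle written to scratch/synthetic_bundle; truth summary to results/.\n")
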