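#' Run the full biomarker-nomination pipeline on a bundle
#'
#' Executes the three omics gates (one-vs-rest DEG, knockdown-proteomics
#' concordance, peak-to-gene assignment), intersects them, and prioritizes
#' the candidates by target-entity expression. Every stage appends one
#' record to the run log, so two runs with the same inputs and seed produce
#' identical counts.
#'
#' @param bundle A `synthetic_bundle` (or any list with the same fields).
#' @param config A [pipeline_config()].
#' @return List: deg, dep, assignment, candidates, report, prioritized, log.
#' @export
run_pipeline <- function(bundle, config = pipeline_config()) {
  th <- config$thresholds
  log <- run_log(seed = config$random_seed)
  target <- bundle$truth$target_entity

  deg <- deg_one_vs_rest(bundle$expression, target,
                         lfc_gate = th$deg_lfc, padj_gate = th$deg_padj)
  log_stage(log, "deg", c(tested = nrow(deg$table),
                          passing = length(deg$passing)))

  dep <- dep_knockdown_concordance(bundle$kd_tables,
                                   lfc_gate = th$dep_lfc,
                                   padj_gate = th$dep_padj)
  log_stage(log, "dep", c(tested = nrow(dep$tables[[1]]),
                          concordant = length(dep$concordant)))

  asg <- assign_peaks_to_genes(bundle$peaks, bundle$gene_annotation,
                               config$peak_assignment$max_tss_distance)
  log_stage(log, "annotate_peaks", c(peaks = nrow(bundle$peaks),
                                     target_genes = length(asg$target_genes)))

  candidates <- intersect_candidates(deg$passing, asg$target_genes,
                                     dep$concordant, bundle$protein_gene_map)
  log_stage(log, "nominate", c(candidates = length(candidates)))

  report <- if (length(candidates) > 0) {
    candidate_report(candidates, deg$table, dep$tables, asg$assignments)
  }
  prioritized <- if (length(candidates) > 0) {
    prioritize(candidates, bundle$expression, target)
  }
  list(deg = deg, dep = dep, assignment = asg, candidates = candidates,
       report = report, prioritized = prioritized, log = log)
}

#' Write a synthetic bundle to plain-text files
#'
#' Serializes every component in the format its pipeline stage reads:
#' expression + labels TSV, per-line knockdown TSVs, peaks BED, H3K27ac
#' region TSV, beta TSV + CpG annotation, single-cell counts + cell labels,
#' IHC cohort TSV, and the planted truth as YAML.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_expression_matrix(bundle$expression, fp("expression.tsv"),
                          fp("labels.tsv"))
  for (line in names(bundle$kd_tables)) {
    kt <- bundle$kd_tables[[line]]
    df <- data.frame(protein = rownames(kt$control), kt$control, kt$knockdown,
                     check.names = FALSE)
    write_tsv_table(df, fp(sprintf("kd_%s.tsv", line)))
  }
  write_bed(bundle$peaks, fp("peaks.bed"))
  write_tsv_table(bundle$h3k27ac_regions, fp("h3k27ac.tsv"))
  write_tsv_table(bundle$gene_annotation, fp("gene_annotation.tsv"))
  beta_df <- data.frame(cpg = rownames(bundle$methylation$beta),
                        bundle$methylation$beta, check.names = FALSE)
  write_tsv_table(beta_df, fp("beta.tsv"))
  write_tsv_table(bundle$methylation$cpg_annotation, fp("cpg_annotation.tsv"))
  write_tsv_table(data.frame(sample = names(bundle$methylation$entity),
                             entity = unname(bundle$methylation$entity)),
                  fp("meth_labels.tsv"))
  sc <- data.frame(gene = rownames(bundle$single_cell$counts),
                   bundle$single_cell$counts, check.names = FALSE)
  write_tsv_table(sc, fp("sc_counts.tsv"))
  write_tsv_table(data.frame(cell = names(bundle$single_cell$cell_labels),
                             label = unname(bundle$single_cell$cell_labels)),
                  fp("cell_labels.tsv"))
  write_tsv_table(bundle$irs_cohort, fp("irs.tsv"))
  yaml::write_yaml(bundle$truth, fp("truth.yaml"))
  invisible(dir)
}
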