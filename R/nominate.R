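#' Triple-intersection biomarker nomination
#'
#' Candidates are the genes passing all three omics gates: significantly
#' overexpressed in the target entity (DEG), concordantly regulated upon
#' fusion knockdown in every cell line (DEP, mapped protein -> gene), and
#' carrying an assigned fusion-binding peak (ChIP). Proteins without a gene
#' mapping are dropped with a warning.
#'
#' @param deg_genes Character vector: DEG-gate survivors.
#' @param target_genes Character vector: genes with an assigned peak.
#' @param dep_proteins Character vector: concordant proteins.
#' @param protein_gene_map Named character vector protein -> gene. Defaults
#'   to identity.
#' @return Character vector of candidate gene IDs in lexicographic order.
#' @export
intersect_candidates <- function(deg_genes, target_genes, dep_proteins,
                                 protein_gene_map = NULL) {
  if (is.null(protein_gene_map)) {
    protein_gene_map <- stats::setNames(dep_proteins, dep_proteins)
  }
  unmapped <- setdiff(dep_proteins, names(protein_gene_map))
  if (length(unmapped) > 0) {
    warning("dropping unmappable protein(s): ", paste(unmapped, collapse = ", "))
  }
  dep_genes <- unname(protein_gene_map[intersect(dep_proteins,
                                                 names(protein_gene_map))])
  sort(intersect(intersect(unique(deg_genes), unique(target_genes)),
                 unique(dep_genes)))
}

#' Candidate provenance report
#'
#' Collects, per candidate, the evidence behind each gate: DEG log2fc/padj,
#' per-line DEP log2fc/padj, and the nearest assigned peak distance.
#'
#' @param candidates Character vector from [intersect_candidates()].
#' @param deg_table DEG data.frame (feature, log2fc, padj, ...).
#' @param dep_tables Named list of per-line DEP data.frames.
#' @param assignments Peak assignment data.frame (gene_id, peak, distance).
#' @return data.frame, one row per candidate.
#' @export
candidate_report <- function(candidates, deg_table, dep_tables, assignments) {
  rows <- lapply(candidates, function(g) {
    deg <- deg_table[deg_table$feature == g, ]
    row <- data.frame(candidate = g, deg_log2fc = deg$log2fc,
                      deg_padj = deg$padj, stringsAsFactors = FALSE)
    for (ln in names(dep_tables)) {
      dt <- dep_tables[[ln]][dep_tables[[ln]]$feature == g, ]
      row[[paste0("dep_log2fc_", ln)]] <- dt$log2fc
      row[[paste0("dep_padj_", ln)]] <- dt$padj
    }
    hits <- assignments[assignments$gene_id == g, ]
    row$peak_distance <- min(hits$distance)
    row
  })
  do.call(rbind, rows)
}

#' Prioritize candidates by target-entity expression
#'
#' Candidates are ranked by median expression within the target entity,
#' descending (ties broken lexicographically); for each adjacent pair in the
#' ranking a two-sided rank-sum p-value on the per-sample expression values
#' is reported — the test used to prefer one biomarker over the next.
#'
#' @param candidates Character vector (>= 1, all present in `expr`).
#' @param expr An `expression_matrix`.
#' @param target_entity Entity whose samples are compared.
#' @return data.frame candidate, median_expression, rank, pairwise_p (p vs
#'   the next-ranked candidate; NA for the last row).
#' @export
prioritize <- function(candidates, expr, target_entity) {
  stopifnot(length(candidates) >= 1)
  absent <- setdiff(candidates, rownames(expr))
  if (length(absent) > 0) {
    stop("candidate(s) absent from matrix: ", paste(absent, collapse = ", "))
  }
  cols <- which(entity_labels(expr) == target_entity)
  stopifnot(length(cols) > 0)
  m <- unclass(expr)[candidates, cols, drop = FALSE]
  med <- apply(m, 1, stats::median)
  ord <- order(-med, candidates)
  ranked <- candidates[ord]
  pw <- rep(NA_real_, length(ranked))
  if (length(ranked) > 1) {
    for (i in seq_len(length(ranked) - 1)) {
      pw[i] <- rank_sum_test(m[ranked[i], ], m[ranked[i + 1], ])$p_value
    }
  }
  data.frame(candidate = ranked, median_expression = med[ord],
             rank = seq_along(ranked), pairwise_p = pw,
             row.names = NULL, stringsAsFactors = FALSE)
}
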