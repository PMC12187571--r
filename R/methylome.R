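#' Select CpGs associated with a gene
#'
#' CpGs whose position falls in `[gene start - flank, gene end + flank)`
#' (0-based), returned in position order. The default 1,500 bp flank keeps
#' promoter-region probes of either orientation.
#'
#' @param cpg_annotation data.frame with cpg_id, chrom, position.
#' @param gene One-row data.frame (or list) with chrom, start, end.
#' @param flank_bp Flank in bp (>= 0; default 1500).
#' @return Character vector of CpG IDs ordered by position; errors when
#'   empty, advising a larger flank.
#' @export
select_gene_cpgs <- function(cpg_annotation, gene, flank_bp = 1500) {
  stopifnot(flank_bp >= 0)
  hit <- cpg_annotation$chrom == gene$chrom &
    cpg_annotation$position >= gene$start - flank_bp &
    cpg_annotation$position < gene$end + flank_bp
  sel <- cpg_annotation[hit, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop("no CpGs selected around [", gene$start, ", ", gene$end,
         "); try a larger flank")
  }
  sel$cpg_id[order(sel$position)]
}

#' Low-dimensional separation and hypomethylation contrast
#'
#' Projects the beta submatrix onto its first two principal components
#' (samples as points), scores target-vs-rest separation by the mean
#' silhouette width on those coordinates, and tests the hypomethylation
#' contrast by a two-sided rank-sum test on per-sample mean beta.
#'
#' @param beta Numeric matrix, CpGs x samples, values in [0, 1] (>= 2 CpGs).
#' @param entity Named or positional character vector of per-sample entity
#'   labels.
#' @param target_entity Label of the target group (both groups >= 3).
#' @return List: `embedding` (samples x 2), `silhouette` (mean width, in
#'   [-1, 1]), `p_value`, `direction` ("target_lower" / "target_higher" /
#'   "none"), `mean_beta_target`, `mean_beta_rest`.
#' @export
methylation_separation <- function(beta, entity, target_entity) {
  stopifnot(nrow(beta) >= 2)
  is_tgt <- entity == target_entity
  if (sum(is_tgt) < 3 || sum(!is_tgt) < 3) {
    stop("both groups need >= 3 samples")
  }
  if (all(apply(beta, 1, stats::sd) == 0)) stop("constant beta submatrix")
  pc <- stats::prcomp(t(beta), center = TRUE, scale. = FALSE)
  emb <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  if (ncol(emb) == 1) emb <- cbind(emb, 0)
  sil <- cluster::silhouette(ifelse(is_tgt, 1L, 2L), stats::dist(emb))
  mean_beta <- colMeans(beta)
  ht <- rank_sum_test(mean_beta[is_tgt], mean_beta[!is_tgt])
  mt <- mean(mean_beta[is_tgt]); mr <- mean(mean_beta[!is_tgt])
  list(embedding = emb,
       silhouette = mean(sil[, "sil_width"]),
       p_value = ht$p_value,
       direction = if (mt < mr) "target_lower"
                   else if (mt > mr) "target_higher" else "none",
       mean_beta_target = mt, mean_beta_rest = mr)
}
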