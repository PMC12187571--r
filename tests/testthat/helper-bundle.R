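# Shared fixtures, generated once per test run. The default bundle mirrors
# the generator's stated study conditions; the cohort32 bundle uses the
# 32-target-sample cohort size the signature analyses assume.
shared_bundle <- generate_multiomics(seed = 42)
shared_result <- run_pipeline(shared_bundle)
shared_bundle32 <- generate_multiomics(truth_params(n_target_samples = 32),
                                       seed = 42)

# Small labeled expression matrix built by hand.
tiny_expr <- function(values, entities) {
  n <- length(entities)
  m <- matrix(values, ncol = n,
              dimnames = list(paste0("g", seq_len(length(values) / n)),
                              paste0("s", seq_len(n))))
  expression_matrix(m, stats::setNames(entities, colnames(m)))
}

# Brute-force BH step-up: padj_(i) = min_{j>=i} m p_(j) / j, original order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  stepup <- numeric(m)
  running <- Inf
  for (j in rev(seq_len(m))) {
    running <- min(running, m * p[ord[j]] / j)
    stepup[ord[j]] <- min(1, running)
  }
  stepup
}

# Brute-force ssGSEA: explicit double loop over positions and members.
ssgsea_oracle <- function(values, gene_set, alpha) {
  genes <- names(values)
  ord <- order(-values, genes)
  genes <- genes[ord]
  rnk <- rank(values)[ord]
  N <- length(genes)
  inset <- genes %in% gene_set
  wsum <- sum(rnk[inset]^alpha)
  es <- 0
  for (i in seq_len(N)) {
    p_in <- sum(ifelse(inset[seq_len(i)], rnk[seq_len(i)]^alpha, 0)) / wsum
    p_out <- sum(!inset[seq_len(i)]) / (N - sum(inset))
    es <- es + (p_in - p_out)
  }
  es
}

# Brute-force preranked-GSEA enrichment score: full running sum over all
# positions, signed maximum deviation.
gsea_es_oracle <- function(stats_sorted_desc, member_positions, weight_p) {
  N <- length(stats_sorted_desc)
  inset <- seq_len(N) %in% member_positions
  w <- abs(stats_sorted_desc)^weight_p
  w[!inset] <- 0
  w <- w / sum(w)
  steps <- ifelse(inset, w, -1 / (N - sum(inset)))
  run <- cumsum(steps)
  if (max(run) >= -min(run)) max(run) else min(run)
}
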