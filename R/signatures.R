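#' Anchor-gene correlation signature
#'
#' Builds a gene set from the genes most correlated (Pearson) with an anchor
#' gene across the target entity's samples — the construction behind the
#' CACNA2D2-style signature: genes that move with the anchor inside the
#' entity of interest.
#'
#' @param expr An `expression_matrix`.
#' @param anchor_gene Gene ID present in the matrix with non-zero variance
#'   across target samples.
#' @param target_entity Entity whose samples (>= 3) the correlation is
#'   computed within.
#' @param top_n Number of top-correlated genes to keep (default 100).
#' @param min_r Optional minimum correlation; when given, members are the
#'   top `top_n` intersected with `{r >= min_r}`.
#' @return Character vector of member gene IDs, ordered by decreasing r,
#'   anchor excluded; the `r` attribute carries the correlations.
#' @export
anchor_correlation_signature <- function(expr, anchor_gene, target_entity,
                                         top_n = 100, min_r = NULL) {
  if (!anchor_gene %in% rownames(expr)) stop("anchor gene absent: ", anchor_gene)
  cols <- which(entity_labels(expr) == target_entity)
  if (length(cols) < 3) stop("need >= 3 target-entity samples")
  m <- unclass(expr)[, cols, drop = FALSE]
  anchor <- m[anchor_gene, ]
  if (stats::sd(anchor) == 0) stop("zero-variance anchor")
  r <- as.vector(stats::cor(t(m), anchor))
  names(r) <- rownames(m)
  r <- r[names(r) != anchor_gene]
  r[is.na(r)] <- 0                     # zero-variance genes cannot correlate
  ord <- order(-r, names(r))
  members <- names(r)[ord][seq_len(min(top_n, length(r)))]
  if (!is.null(min_r)) {
    stopifnot(min_r > 0, min_r < 1)
    members <- members[r[members] >= min_r]
  }
  attr(members, "r") <- r[members]
  members
}

#' Knockdown-derived fusion signature
#'
#' Combines differential tables from several knockdown experiments into a
#' direction-split signature. A gene enters the fusion-activated set when it
#' is significantly DOWN upon knockdown (padj < `padj_gate`, log2fc < 0) in
#' at least `min_support` tables; the fusion-repressed set is symmetric
#' (significantly up).
#'
#' @param diff_tables List (>= 2) of data.frames with feature, log2fc, padj
#'   over a shared feature universe.
#' @param padj_gate Significance gate (default 0.01).
#' @param min_support Minimum number of supporting tables (default: all).
#' @param both Return both directions (default FALSE: activated set only).
#' @return Character vector of fusion-activated genes, or when `both = TRUE`
#'   a list with `activated` and `repressed`.
#' @export
kd_combined_signature <- function(diff_tables, padj_gate = 0.01,
                                  min_support = length(diff_tables),
                                  both = FALSE) {
  stopifnot(length(diff_tables) >= 2)
  if (min_support < 1) stop("min_support must be >= 1")
  if (min_support > length(diff_tables)) stop("min_support exceeds table count")
  features <- diff_tables[[1]]$feature
  stopifnot(all(vapply(diff_tables, function(t) identical(t$feature, features),
                       TRUE)))
  down <- rowSums(vapply(diff_tables, function(t) {
    t$padj < padj_gate & t$log2fc < 0
  }, logical(length(features))))
  up <- rowSums(vapply(diff_tables, function(t) {
    t$padj < padj_gate & t$log2fc > 0
  }, logical(length(features))))
  activated <- sort(features[down >= min_support])
  if (!both) return(activated)
  list(activated = activated, repressed = sort(features[up >= min_support]))
}

#' Single-sample GSEA score
#'
#' Ranks one sample's genes by expression (descending, average ranks for
#' ties) and accumulates the difference between the weighted in-set and the
#' unweighted out-of-set empirical distribution functions:
#' `ES = sum_i [P_in(i) - P_out(i)]` over all N positions, where a member at
#' rank position i contributes weight `w = r^alpha` (r the gene's ascending
#' rank, so the highest-expressed gene carries the largest weight) and
#' `P_out` steps by `1/(N - |S|)` at non-members. With `alpha = 0` the score
#' depends on ranks only, hence is invariant under strictly monotone
#' transforms of the values.
#'
#' @param sample_values Named numeric vector: gene -> expression.
#' @param gene_set Character vector of member genes; the overlap with the
#'   universe must be non-empty and proper.
#' @param alpha Rank-weight exponent (>= 0; default 0.25).
#' @return Numeric enrichment score (dimensionless, in [-N/ (N-|S|) .. N/|S|]
#'   scale terms; 0 under exchangeability).
#' @export
ssgsea_score <- function(sample_values, gene_set, alpha = 0.25) {
  stopifnot(alpha >= 0)
  genes <- names(sample_values)
  inset <- genes %in% gene_set
  n_in <- sum(inset)
  N <- length(genes)
  if (n_in == 0) stop("gene set does not overlap the universe")
  if (n_in == N) stop("gene set covers the whole universe")
  ord <- order(-sample_values, genes)            # descending; ties by name
  inset <- inset[ord]
  rnk <- rank(sample_values)[ord]                # ascending midranks: top gene ~ N
  w <- ifelse(inset, rnk^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!inset) / (N - n_in)
  sum(p_in - p_out)
}

#' ssGSEA score matrix
#'
#' Scores every sample (column) of an expression matrix against every gene
#' set. With `normalize = TRUE` all scores are divided by the global
#' max - min of the raw score matrix, putting heterogeneous signatures on a
#' shared scale.
#'
#' @param expr Numeric matrix (genes x samples) or `expression_matrix`.
#' @param gene_sets Named list of character vectors.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize Divide by the global score range (default FALSE).
#' @return Numeric matrix, signatures x samples.
#' @export
ssgsea_matrix <- function(expr, gene_sets, alpha = 0.25, normalize = FALSE) {
  m <- unclass(expr)
  scores <- matrix(NA_real_, length(gene_sets), ncol(m),
                   dimnames = list(names(gene_sets), colnames(m)))
  for (j in seq_len(ncol(m))) {
    vals <- stats::setNames(m[, j], rownames(m))
    for (s in seq_along(gene_sets)) {
      scores[s, j] <- tryCatch(
        ssgsea_score(vals, gene_sets[[s]], alpha),
        error = function(e) stop("sample ", colnames(m)[j], ": ",
                                 conditionMessage(e)))
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

# Running-sum ES for a preranked list, given member positions in the
# descending-sorted statistics. O(|S|): between members the sum falls
# linearly, so extrema occur right after a member or just before the next.
.gsea_es <- function(abs_sorted_stats, positions, N, weight_p) {
  pos <- sort(positions)
  k <- length(pos)
  w <- abs_sorted_stats[pos]^weight_p
  tot <- sum(w)
  w <- if (tot > 0) w / tot else rep(1 / k, k)
  dec <- 1 / (N - k)
  cum_w <- cumsum(w)
  after <- cum_w - dec * (pos - seq_len(k))          # just after each member
  before <- c(0, cum_w[-k]) - dec * (pos - seq_len(k)) # just before each member
  top <- max(after)
  bottom <- min(before)
  if (top >= -bottom) top else bottom
}

#' Preranked GSEA with a permutation null
#'
#' Classical running-sum enrichment on a ranked gene list: members increment
#' by `|stat|^weight_p` (normalized to total 1), non-members decrement by
#' `1/(N - |S|)`; ES is the signed maximum deviation of the running sum. The
#' null is built from `n_permutations` random gene sets of the same size
#' (seeded); `NES = ES / mean(|null ES| of matching sign)` and
#' `p = (1 + #{same-sign null with |ES_null| >= |ES|}) / (1 + #same-sign)`.
#'
#' @param ranked_stats Named numeric vector gene -> ranking statistic (all
#'   finite).
#' @param gene_set Character vector; overlap with the universe must be >= 1
#'   and proper.
#' @param n_permutations Number of permutations (default 1000; < 100 warns).
#' @param seed Integer seed for the permutation draws.
#' @param weight_p Weighting exponent on |stat| (default 1).
#' @return List: es, nes, pvalue, n_permutations, seed, n_leading (members),
#'   degenerate_null (TRUE when no null ES matched the observed sign; the
#'   p-value is then the resolution floor `1/(n_permutations+1)`).
#' @export
preranked_gsea <- function(ranked_stats, gene_set, n_permutations = 1000,
                           seed = 1, weight_p = 1) {
  if (any(!is.finite(ranked_stats))) stop("ranking statistics must be finite")
  if (n_permutations < 100) {
    warning("fewer than 100 permutations: p-value resolution is poor")
  }
  genes <- names(ranked_stats)
  N <- length(genes)
  ord <- order(-ranked_stats, genes)
  sorted_abs <- abs(ranked_stats[ord])
  members <- which(genes[ord] %in% gene_set)
  k <- length(members)
  if (k < 1 || k >= N) stop("gene set overlap must satisfy 1 <= |overlap| < N")
  es <- .gsea_es(sorted_abs, members, N, weight_p)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  null_es <- vapply(seq_len(n_permutations), function(i) {
    .gsea_es(sorted_abs, sample.int(N, k), N, weight_p)
  }, 0)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  same <- null_es[sign(null_es) == sign(es)]
  degenerate <- length(same) == 0
  if (degenerate) {
    nes <- NA_real_
    p <- 1 / (n_permutations + 1)
  } else {
    nes <- es / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  }
  list(es = es, nes = nes, pvalue = p, n_permutations = n_permutations,
       seed = seed, n_leading = k, degenerate_null = degenerate)
}

#' Pearson correlation between signature score profiles
#'
#' @param scores Matrix signatures x samples (>= 3 samples).
#' @return Symmetric correlation matrix with unit diagonal; rows with zero
#'   variance yield NA entries with a warning.
#' @export
score_correlation <- function(scores) {
  stopifnot(ncol(scores) >= 3)
  sds <- apply(scores, 1, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance signature row(s): ",
            paste(rownames(scores)[sds == 0], collapse = ", "))
  }
  suppressWarnings(stats::cor(t(scores)))
}

#' Score single cells against gene signatures
#'
#' Applies ssGSEA per cell to log1p-transformed counts after dropping cells
#' with fewer than `min_genes` detected genes (a minimal quality gate).
#'
#' @param counts Numeric matrix genes x cells (raw counts).
#' @param gene_sets Named list of character vectors.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param min_genes Minimum detected genes per kept cell (default 200).
#' @return Matrix signatures x kept cells.
#' @export
sc_signature_scores <- function(counts, gene_sets, alpha = 0.25,
                                min_genes = 200) {
  detected <- colSums(counts > 0)
  keep <- detected >= min_genes
  if (!any(keep)) stop("no cell passes the detected-gene threshold")
  ssgsea_matrix(log1p(counts[, keep, drop = FALSE]), gene_sets, alpha)
}
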