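#' Two-sided Mann-Whitney rank-sum test
#'
#' The per-gene test of the one-vs-rest differential-expression gate.
#' Ties are handled by midranks. When both groups have at most
#' `exact_max` observations the two-sided p-value is computed by exact
#' enumeration of all label assignments (so it is valid under ties, where
#' the classical exact tables are not); otherwise the normal approximation
#' with the variance tie correction is used. The two-sided exact p is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))` over the permutation
#' distribution of U.
#'
#' @param group_a,group_b Numeric vectors, both non-empty.
#' @param exact_max Largest per-group size at which full enumeration is used
#'   (default 8).
#' @return List with `statistic` (U of `group_a`: number of (a, b) pairs with
#'   a > b, ties counting 1/2) and `p_value`.
#' @export
rank_sum_test <- function(group_a, group_b, exact_max = 8L) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("rank_sum_test: both groups must be non-empty")
  }
  n1 <- length(group_a); n2 <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)                       # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    null_u <- .enumerate_u(r, n1)
    p <- min(1, 2 * min(mean(null_u <= u + 1e-9), mean(null_u >= u - 1e-9)))
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(statistic = u, p_value = 1))
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = u, p_value = p)
}

# U statistics over all choose(N, n1) assignments of pooled ranks to group a
.enumerate_u <- function(ranks, n1) {
  idx <- utils::combn(length(ranks), n1)
  colSums(matrix(ranks[idx], nrow = n1)) - n1 * (n1 + 1) / 2
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR control: `padj_(i) = min_{j >= i} m * p_(j) / j`, capped at 1,
#' returned in the original order. Input p-values must lie in (0, 1].
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted p-values, same order and length.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("benjamini_hochberg: p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' One-vs-rest differential expression across tumor entities
#'
#' For each gene: log2 fold change = mean(target samples) - mean(all other
#' samples pooled); p-value from the two-sided rank-sum test; adjustment by
#' Benjamini-Hochberg across all genes. A gene passes the gate when
#' `log2fc > lfc_gate` and `padj < padj_gate`. With `per_entity = TRUE` the
#' fold-change gate must additionally hold against every non-target entity
#' separately (strict reading of "overexpressed compared to all other
#' entities").
#'
#' @param expr An `expression_matrix`.
#' @param target_entity Entity label of the positive class (>= 3 samples).
#' @param lfc_gate,padj_gate Gates (defaults 2.5, 0.01).
#' @param per_entity Require the fold-change gate per entity (default FALSE:
#'   pooled rest).
#' @return List with `table` (data.frame feature, log2fc, pvalue, padj,
#'   direction, pass) and `passing` (character vector of gene IDs).
#' @export
deg_one_vs_rest <- function(expr, target_entity, lfc_gate = 2.5,
                            padj_gate = 0.01, per_entity = FALSE) {
  labels <- entity_labels(expr)
  if (!target_entity %in% labels) {
    stop("unknown entity: ", target_entity)
  }
  tgt <- which(labels == target_entity)
  rest <- which(labels != target_entity)
  if (length(tgt) < 3) stop("target entity must have >= 3 samples")
  if (length(rest) < 1) stop("no non-target samples")
  m <- unclass(expr)
  lfc <- rowMeans(m[, tgt, drop = FALSE]) - rowMeans(m[, rest, drop = FALSE])
  pv <- vapply(seq_len(nrow(m)), function(i) {
    rank_sum_test(m[i, tgt], m[i, rest])$p_value
  }, 0)
  pv <- pmax(pv, .Machine$double.xmin)    # rank-sum p can be 0 only numerically
  padj <- benjamini_hochberg(pv)
  pass_lfc <- lfc > lfc_gate
  if (per_entity) {
    for (ent in setdiff(unique(labels), target_entity)) {
      cols <- which(labels == ent)
      lfc_e <- rowMeans(m[, tgt, drop = FALSE]) - rowMeans(m[, cols, drop = FALSE])
      pass_lfc <- pass_lfc & (lfc_e > lfc_gate)
    }
  }
  pass <- pass_lfc & (padj < padj_gate)
  tab <- data.frame(feature = rownames(m), log2fc = lfc, pvalue = pv,
                    padj = padj,
                    direction = ifelse(lfc >= 0, "up", "down"),
                    pass = pass, row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, passing = tab$feature[tab$pass])
}

#' Per-cell-line knockdown differential protein table
#'
#' Welch t-test per protein (knockdown vs control replicates; rank-based
#' tests are unreliable at n = 4), log2fc = mean(KD) - mean(control), BH
#' adjustment within the line.
#'
#' @param control,knockdown Numeric matrices (proteins x replicates, log2
#'   abundance), same rownames, >= 3 replicates each.
#' @return data.frame feature, log2fc, pvalue, padj, direction.
#' @export
kd_diff_table <- function(control, knockdown) {
  if (ncol(control) < 3 || ncol(knockdown) < 3) {
    stop("knockdown differential testing requires >= 3 replicates per arm")
  }
  stopifnot(identical(rownames(control), rownames(knockdown)))
  lfc <- rowMeans(knockdown) - rowMeans(control)
  pv <- vapply(seq_len(nrow(control)), function(i) {
    stats::t.test(knockdown[i, ], control[i, ])$p.value
  }, 0)
  pv <- pmin(pmax(pv, .Machine$double.xmin), 1)
  data.frame(feature = rownames(control), log2fc = lfc, pvalue = pv,
             padj = benjamini_hochberg(pv),
             direction = ifelse(lfc >= 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Knockdown-proteomics concordance across cell lines
#'
#' A protein is concordantly regulated when, in EVERY cell line,
#' `|log2fc| > lfc_gate` and `padj < padj_gate`, with the same sign of
#' log2fc across lines.
#'
#' @param kd_tables Named list, one element per cell line, each a list with
#'   matrices `control` and `knockdown` (proteins x replicates) — or an
#'   already-computed data.frame as returned by [kd_diff_table()].
#' @param lfc_gate,padj_gate Gates (defaults 1.0, 0.01).
#' @return List with `tables` (per-line diff tables), `concordant`
#'   (character vector of protein IDs) and `direction` (named sign vector).
#' @export
dep_knockdown_concordance <- function(kd_tables, lfc_gate = 1.0,
                                      padj_gate = 0.01) {
  if (length(kd_tables) < 2) stop("need >= 2 cell lines")
  tabs <- lapply(kd_tables, function(x) {
    if (is.data.frame(x)) x else kd_diff_table(x$control, x$knockdown)
  })
  features <- tabs[[1]]$feature
  stopifnot(all(vapply(tabs, function(t) identical(t$feature, features), TRUE)))
  pass <- Reduce(`&`, lapply(tabs, function(t) {
    abs(t$log2fc) > lfc_gate & t$padj < padj_gate
  }))
  signs <- vapply(tabs, function(t) sign(t$log2fc), numeric(length(features)))
  same_sign <- apply(signs, 1, function(s) all(s == s[1]) && s[1] != 0)
  conc <- features[pass & same_sign]
  list(tables = tabs, concordant = conc,
       direction = stats::setNames(signs[match(conc, features), 1], conc))
}
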