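test_that("ssGSEA singleton worked examples give ES = +/-2 exactly", {
  v <- c(a = 4, b = 3, c = 2, d = 1)
  expect_equal(ssgsea_score(v, "a", alpha = 0), 2)
  expect_equal(ssgsea_score(v, "d", alpha = 0), -2)
  expect_error(ssgsea_score(v, c("x", "y")), "overlap")
  expect_error(ssgsea_score(v, names(v)), "whole universe")
})

test_that("ssGSEA matches the brute-force double-loop oracle", {
  set.seed(77)
  worst <- 0
  for (i in 1:200) {
    N <- sample(5:50, 1)
    v <- stats::setNames(rnorm(N), paste0("g", seq_len(N)))
    if (i %% 4 == 0) v <- round(v, 1)     # ties
    k <- sample(seq_len(N - 1), 1)
    s <- sample(names(v), k)
    alpha <- sample(c(0, 0.25, 1), 1)
    worst <- max(worst, abs(ssgsea_score(v, s, alpha) - ssgsea_oracle(v, s, alpha)))
  }
  expect_lt(worst, 1e-9)
})

test_that("ssGSEA with alpha = 0 depends on ranks only", {
  set.seed(13)
  v <- stats::setNames(rnorm(30), paste0("g", 1:30))
  s <- sample(names(v), 7)
  base <- ssgsea_score(v, s, alpha = 0)
  expect_equal(ssgsea_score(exp(v), s, alpha = 0), base)
  expect_equal(ssgsea_score(rank(v), s, alpha = 0), base)
  # symmetry null: random half-sets average out near zero
  es <- replicate(300, ssgsea_score(stats::setNames(rnorm(20), paste0("g", 1:20)),
                                    paste0("g", sample(20, 10)), alpha = 0))
  expect_lt(abs(mean(es)), 0.2)
})

test_that("ssGSEA matrix is consistent with single scores and normalizes by range", {
  m <- matrix(c(4, 3, 2, 1), 4, 1, dimnames = list(letters[1:4], "s1"))
  sm <- ssgsea_matrix(m, list(top = "a"), alpha = 0)
  expect_equal(dim(sm), c(1L, 1L))
  expect_equal(sm[1, 1], 2)

  set.seed(3)
  mm <- matrix(rnorm(40 * 6), 40, 6,
               dimnames = list(paste0("g", 1:40), paste0("s", 1:6)))
  sets <- list(A = paste0("g", 1:5), B = paste0("g", 30:40))
  raw <- ssgsea_matrix(mm, sets)
  nrm <- ssgsea_matrix(mm, sets, normalize = TRUE)
  expect_equal(nrm, raw / (max(raw) - min(raw)))
})

test_that("anchor correlation signature recovers the planted module", {
  b <- shared_bundle32
  sig <- anchor_correlation_signature(b$expression, b$truth$anchor_gene,
                                      "DSRCT", top_n = 100)
  expect_gte(mean(b$truth$coexpression_module %in% sig), 0.95)
  expect_false(b$truth$anchor_gene %in% sig)

  # a gene identical to the anchor ranks first with r = 1
  m <- unclass(b$expression)[1:50, ]
  m <- rbind(m, clone = m[b$truth$anchor_gene, ])
  x <- expression_matrix(m, entity_labels(b$expression))
  s2 <- anchor_correlation_signature(x, b$truth$anchor_gene, "DSRCT", top_n = 5)
  expect_equal(s2[1], "clone")
  expect_equal(unname(attr(s2, "r")["clone"]), 1)

  # independent genes are excluded by a min_r gate
  s3 <- anchor_correlation_signature(b$expression, b$truth$anchor_gene,
                                     "DSRCT", top_n = 100, min_r = 0.6)
  expect_true(all(s3 %in% c(b$truth$coexpression_module,
                            b$truth$planted_biomarkers)))

  expect_error(anchor_correlation_signature(b$expression, "nope", "DSRCT"),
               "absent")
  flat <- unclass(b$expression)[1:10, ]
  flat["G0001", ] <- 5
  xf <- expression_matrix(flat, entity_labels(b$expression))
  expect_error(anchor_correlation_signature(xf, "G0001", "DSRCT"),
               "zero-variance")
})

test_that("knockdown signature applies the support and direction rules", {
  mk <- function(lfc, padj) data.frame(feature = c("a", "b", "c"),
                                       log2fc = lfc, padj = padj)
  tabs <- list(mk(c(-2, -2, 2), c(1e-5, 1e-5, 1e-5)),
               mk(c(-2, -2, 2), c(1e-5, 0.5, 1e-5)),
               mk(c(-2, -2, 2), c(1e-5, 1e-5, 1e-5)))
  # gene a down in 3/3 -> member; b down in 2/3 at min_support 3 -> excluded
  expect_equal(kd_combined_signature(tabs), "a")
  expect_equal(kd_combined_signature(tabs, min_support = 2), c("a", "b"))
  both <- kd_combined_signature(tabs, both = TRUE)
  expect_equal(both$activated, "a")
  expect_equal(both$repressed, "c")
  expect_error(kd_combined_signature(tabs, min_support = 0), ">= 1")

  dep <- dep_knockdown_concordance(shared_bundle$kd_tables)
  sig <- kd_combined_signature(dep$tables)
  expect_true(all(shared_bundle$truth$dep_planted %in% sig))
})

test_that("target-entity samples outscore mimics on the planted-module set", {
  b <- shared_bundle32
  sets <- list(module = c(b$truth$anchor_gene, b$truth$coexpression_module))
  sm <- ssgsea_matrix(b$expression, sets, alpha = 0.25)
  lab <- entity_labels(b$expression)
  p <- rank_sum_test(sm[1, lab == "DSRCT"], sm[1, lab != "DSRCT"])$p_value
  expect_lt(p, 0.001)
})

test_that("preranked GSEA running-sum ES matches oracles and conventions", {
  # worked example: top-5 member set with all non-member stats 0 -> ES = +1
  stats_ <- stats::setNames(c(5:1, rep(0, 95)), paste0("g", 1:100))
  res <- preranked_gsea(stats_, paste0("g", 1:5), n_permutations = 100,
                        seed = 1)
  expect_equal(res$es, 1)
  expect_gt(res$nes, 0)

  # antisymmetry: negating every statistic negates ES
  set.seed(21)
  v <- stats::setNames(rnorm(60), paste0("g", 1:60))
  s <- sample(names(v), 12)
  a <- preranked_gsea(v, s, 200, seed = 3)
  bnegated <- preranked_gsea(-v, s, 200, seed = 3)
  expect_equal(bnegated$es, -a$es, tolerance = 1e-12)
  expect_equal(sign(a$nes), sign(a$es))

  # seed-fixed bit reproducibility
  expect_identical(preranked_gsea(v, s, 200, seed = 9),
                   preranked_gsea(v, s, 200, seed = 9))

  # fast ES equals the brute-force running-sum oracle
  set.seed(37)
  for (i in 1:100) {
    N <- sample(10:80, 1)
    st <- sort(rnorm(N), decreasing = TRUE)
    k <- sample(2:(N - 2), 1)
    pos <- sort(sample(N, k))
    wp <- sample(c(0.5, 1, 1.5), 1)
    expect_equal(sarcomark:::.gsea_es(abs(st), pos, N, wp),
                 gsea_es_oracle(st, pos, wp), tolerance = 1e-12)
  }

  # fgsea computes the same enrichment statistic (independent cross-check)
  if (requireNamespace("fgsea", quietly = TRUE)) {
    for (i in 1:20) {
      N <- 50
      v2 <- stats::setNames(rnorm(N), paste0("g", 1:N))
      s2 <- sample(names(v2), 8)
      ours <- preranked_gsea(v2, s2, 100, seed = 1)$es
      ref <- fgsea::calcGseaStat(sort(v2, decreasing = TRUE),
                                 which(names(sort(v2, decreasing = TRUE)) %in% s2),
                                 gseaParam = 1)
      expect_equal(ours, ref, tolerance = 1e-9)
    }
  }

  expect_warning(preranked_gsea(v, s, n_permutations = 50, seed = 1),
                 "fewer than 100")
  expect_error(preranked_gsea(c(a = Inf, b = 1), "a", 100, 1), "finite")
})

test_that("signature score correlation is a proper correlation matrix", {
  set.seed(4)
  sm <- matrix(rnorm(3 * 10), 3, 10,
               dimnames = list(c("x", "y", "z"), paste0("s", 1:10)))
  sm["y", ] <- sm["x", ]                 # same signature under two names
  cc <- score_correlation(sm)
  expect_equal(cc["x", "y"], 1)
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 3))
  expect_true(all(abs(cc) <= 1 + 1e-12))

  smz <- sm; smz["z", ] <- 0
  expect_warning(ccz <- score_correlation(smz), "zero-variance")
  expect_true(is.na(ccz["z", "x"]))
})

test_that("anchor and knockdown signature scores correlate in the planted regime", {
  b <- shared_bundle32
  anchor_sig <- anchor_correlation_signature(b$expression,
                                             b$truth$anchor_gene, "DSRCT",
                                             top_n = 100)
  dep <- dep_knockdown_concordance(b$kd_tables)
  kd_sig <- kd_combined_signature(dep$tables)
  sm <- ssgsea_matrix(b$expression,
                      list(anchor = as.character(anchor_sig), kd = kd_sig))
  cc <- score_correlation(sm)
  expect_gt(cc["anchor", "kd"], 0.6)
})

test_that("tumor cells outscore normal cells on the planted program", {
  b <- shared_bundle
  sets <- list(program = c(b$truth$anchor_gene, b$truth$coexpression_module))
  scs <- sc_signature_scores(b$single_cell$counts, sets, min_genes = 200)
  lab <- b$single_cell$cell_labels[colnames(scs)]
  expect_gte(sum(lab == "tumor"), 100)
  p <- rank_sum_test(scs[1, lab == "tumor"], scs[1, lab == "normal"])$p_value
  expect_lt(p, 1e-6)
})
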