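test_that("rank-sum exact mode matches hand-derived two-sided p-values", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  expect_equal(rank_sum_test(c(1, 2), c(3))$p_value, 2 / 3)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(rank_sum_test(numeric(), 1:3), "non-empty")
})

test_that("rank-sum exact mode agrees with full enumeration for small groups", {
  set.seed(31)
  for (rep in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    # mix of continuous and tied data
    pool <- if (rep %% 2 == 0) sample(1:4, n1 + n2, replace = TRUE)
            else rnorm(n1 + n2)
    a <- pool[seq_len(n1)]; b <- pool[-seq_len(n1)]
    got <- rank_sum_test(a, b)
    # independent enumeration over all label assignments
    r <- rank(c(a, b))
    idx <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    p_exp <- min(1, 2 * min(mean(u_all <= u_obs + 1e-9),
                            mean(u_all >= u_obs - 1e-9)))
    expect_equal(got$p_value, p_exp)
    expect_equal(got$statistic, u_obs)
  }
})

test_that("rank-sum normal approximation tracks wilcox.test with ties corrected", {
  set.seed(5)
  a <- rnorm(15); b <- rnorm(20, 0.5)
  got <- rank_sum_test(a, b)
  ref <- stats::wilcox.test(a, b, correct = FALSE, exact = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up oracle and worked examples", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\(0, 1\\]")

  set.seed(17)
  for (i in 1:500) {
    p <- runif(sample(1:50, 1))
    expect_lt(max(abs(benjamini_hochberg(p) - bh_oracle(p))), 1e-12)
  }
})

test_that("one-vs-rest DEG recovers planted genes and obeys invariances", {
  res <- shared_result$deg
  expect_true(all(shared_bundle$truth$planted_biomarkers %in% res$passing))
  expect_true(all(res$table$padj >= res$table$pvalue - 1e-12))
  expect_identical(res$table$direction, ifelse(res$table$log2fc >= 0, "up", "down"))

  expect_error(deg_one_vs_rest(shared_bundle$expression, "no_such_entity"),
               "unknown entity")

  # infinite gate -> nothing passes
  none <- deg_one_vs_rest(shared_bundle$expression, "DSRCT", lfc_gate = Inf)
  expect_length(none$passing, 0)

  # invariance: column order and global constants leave lfc and p unchanged
  x <- tiny_expr(rnorm(60), rep(c("T", "A", "B"), each = 4))
  base <- deg_one_vs_rest(x, "T", lfc_gate = 0.5, padj_gate = 0.5)
  perm <- sample(ncol(x))
  x_perm <- expression_matrix(unclass(x)[, perm],
                              entity_labels(x)[perm])
  x_shift <- expression_matrix(unclass(x)[, ] + 7, entity_labels(x))
  for (other in list(deg_one_vs_rest(x_perm, "T", 0.5, 0.5),
                     deg_one_vs_rest(x_shift, "T", 0.5, 0.5))) {
    expect_equal(other$table$log2fc, base$table$log2fc)
    expect_equal(other$table$pvalue, base$table$pvalue)
  }
})

test_that("DEG under a null matrix passes nothing at padj < 0.01", {
  set.seed(23)
  x <- tiny_expr(rnorm(200 * 12, 6), rep(c("T", "R"), each = 6))
  res <- deg_one_vs_rest(x, "T", lfc_gate = 0, padj_gate = 0.01)
  expect_length(res$passing, 0)
})

test_that("knockdown concordance requires the gate in every line with one sign", {
  res <- shared_result$dep
  expect_true(all(shared_bundle$truth$dep_planted %in% res$concordant))
  expect_true(all(res$direction == -1))

  # discordant signs are excluded even when both lines are significant
  set.seed(41)
  mk <- function(eff) {
    base <- rnorm(50, 6)
    list(control = matrix(base + rnorm(200, 0, 0.1), 50,
                          dimnames = list(paste0("p", 1:50), NULL)),
         knockdown = matrix(base + eff + rnorm(200, 0, 0.1), 50,
                            dimnames = list(paste0("p", 1:50), NULL)))
  }
  eff_up <- eff_down <- rep(0, 50)
  eff_up[1] <- 2; eff_down[1] <- -2
  disc <- dep_knockdown_concordance(list(a = mk(eff_up), b = mk(eff_down)))
  expect_false("p1" %in% disc$concordant)
  conc <- dep_knockdown_concordance(list(a = mk(eff_down), b = mk(eff_down)))
  expect_true("p1" %in% conc$concordant)

  expect_error(dep_knockdown_concordance(list(a = mk(eff_up))), ">= 2")
  few <- mk(eff_up)
  few$control <- few$control[, 1:2]
  expect_error(dep_knockdown_concordance(list(a = few, b = mk(eff_up))),
               ">= 3 replicates")
})

test_that("null knockdown effect yields an empty concordant set", {
  p0 <- truth_params()
  p0$dep_effect <- 1e-9   # effectively no planted effect
  b0 <- generate_multiomics(p0, seed = 3)
  res <- dep_knockdown_concordance(b0$kd_tables)
  expect_length(res$concordant, 0)
})
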