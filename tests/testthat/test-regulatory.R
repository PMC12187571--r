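test_that("peak-to-gene assignment uses edge-to-TSS distance with a window", {
  genes <- data.frame(gene_id = c("gIn", "gNear", "gFar"),
                      chrom = "chr1", strand = "+",
                      start = c(1500, 50000, 200000),
                      end = c(21500, 70000, 220000),
                      tss = c(1500, 50000, 200000))
  peaks <- data.frame(chrom = "chr1", start = c(1000, 0), end = c(2000, 100),
                      name = c("pA", "pB"), score = 1)
  res <- assign_peaks_to_genes(peaks, genes, max_tss_distance = 100000)
  asg <- res$assignments
  # TSS inside the peak: distance 0
  expect_equal(asg$distance[asg$gene_id == "gIn" & asg$peak == "pA"], 0)
  # TSS 50,000 vs peak [0,100): edge distance 49,900
  expect_equal(asg$distance[asg$gene_id == "gNear" & asg$peak == "pB"], 49900)
  # TSS at 200,000 is beyond the 100 kb window of both peaks
  expect_false("gFar" %in% res$target_genes)

  # invariant to peak order
  res2 <- assign_peaks_to_genes(peaks[2:1, ], genes, 100000)
  expect_equal(res2$assignments, res$assignments)
  expect_equal(res2$target_genes, res$target_genes)

  # minus-strand TSS is the annotation end
  gm <- data.frame(gene_id = "gM", chrom = "chr1", strand = "-",
                   start = 0, end = 1500)
  rm_ <- assign_peaks_to_genes(peaks[1, ], gm, 100)
  expect_equal(rm_$assignments$distance, 0)

  expect_warning(
    skipped <- assign_peaks_to_genes(
      data.frame(chrom = "chrX", start = 0, end = 10, name = "p", score = 0),
      genes, 100),
    "chrX")
  expect_length(skipped$target_genes, 0)
})

test_that("stitching merges transitively within the gap and is idempotent", {
  peaks <- data.frame(chrom = "chr1",
                      start = c(0, 5000, 30000),
                      end = c(1000, 6000, 31000),
                      name = paste0("p", 1:3), score = c(2, 3, 5))
  st <- stitch_peaks(peaks, 12500)
  expect_equal(nrow(st), 2)
  expect_equal(st$start, c(0, 30000))
  expect_equal(st$end, c(6000, 31000))
  expect_equal(st$component_peak_count, c(2L, 1L))
  expect_equal(st$total_signal, c(5, 5))

  # distance 0 leaves disjoint peaks alone; overlapping peaks always merge
  expect_equal(nrow(stitch_peaks(peaks, 0)), 3)
  ovl <- data.frame(chrom = "chr1", start = c(0, 500), end = c(1000, 1500),
                    name = c("a", "b"), score = 1)
  expect_equal(nrow(stitch_peaks(ovl, 0)), 1)

  # idempotence: stitching the stitched output changes nothing
  st_in <- data.frame(chrom = st$chrom, start = st$start, end = st$end,
                      name = paste0("r", seq_len(nrow(st))),
                      score = st$total_signal)
  st2 <- stitch_peaks(st_in, 12500)
  expect_equal(st2[, c("chrom", "start", "end", "total_signal")],
               st[, c("chrom", "start", "end", "total_signal")])

  # total signal dominates any component score
  set.seed(8)
  n <- 300
  rstart <- sample(0:5e5, n)
  rnd <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                    start = rstart, end = rstart + sample(500:2000, n, TRUE),
                    name = paste0("p", 1:n), score = runif(n, 0, 10))
  str_ <- stitch_peaks(rnd, 12500)
  expect_true(all(str_$total_signal >=
                    vapply(seq_len(nrow(str_)), function(i) {
                      sel <- rnd$chrom == str_$chrom[i] &
                        rnd$start >= str_$start[i] & rnd$end <= str_$end[i]
                      max(rnd$score[sel])
                    }, 0) - 1e-12))
  # disjoint per chromosome
  for (ch in unique(str_$chrom)) {
    s <- str_[str_$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
})

test_that("super-enhancer cutoff is the scaled-rank tangent point", {
  st <- data.frame(total_signal = c(1, 1, 1, 1, 1, 1, 1, 1, 10, 20))
  res <- call_super_enhancers(st)
  expect_equal(attr(res, "cutoff_index"), 8)
  expect_equal(attr(res, "cutoff_signal"), 1)
  expect_equal(attr(res, "n_super"), 2)
  expect_false(attr(res, "weak_elbow"))

  lin <- call_super_enhancers(data.frame(total_signal = 1:10))
  expect_true(attr(lin, "weak_elbow"))

  two <- call_super_enhancers(data.frame(total_signal = c(1, 100)))
  expect_equal(attr(two, "cutoff_index"), 1)
  expect_equal(attr(two, "n_super"), 1)

  expect_error(call_super_enhancers(data.frame(total_signal = rep(3, 5))),
               "degenerate")
})

test_that("super-enhancer calling equals the exhaustive argmax oracle and is monotone", {
  set.seed(59)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    s <- rgamma(n, shape = 1, scale = sample(c(1, 5), 1))
    if (i %% 3 == 0) s <- round(s)          # force ties
    if (length(unique(s)) == 1) s <- s + seq_len(n) * 0.01
    res <- call_super_enhancers(data.frame(id = seq_len(n), total_signal = s))
    # exhaustive oracle over all candidate indices, ties toward larger i
    ss <- sort(s)
    gap <- seq_len(n) / n - ss / max(ss)
    istar <- max(which(gap == max(gap)))
    expect_equal(attr(res, "cutoff_index"), istar)
    expect_equal(sum(res$is_super), sum(s > ss[istar]))

    # monotonicity: raising one region's signal never demotes it
    pick <- sample(n, 1)
    s2 <- s
    s2[pick] <- s2[pick] + max(s) * runif(1, 0.1, 2)
    res2 <- call_super_enhancers(data.frame(id = seq_len(n), total_signal = s2))
    was_super <- res$is_super[match(pick, res$id)]
    now_super <- res2$is_super[match(pick, res2$id)]
    if (was_super) expect_true(now_super)
  }
})
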