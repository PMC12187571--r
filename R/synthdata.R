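# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

#' Default synthetic-truth parameters
#'
#' The study conditions of the synthetic multi-omics bundle: a scaled-down
#' mirror of a multi-entity tumor cohort in which one entity (the target)
#' overexpresses a small set of planted biomarker genes driven by a fusion
#' protein. Effects are on the log2 scale.
#'
#' @param n_entities Number of tumor entities (default 8; entity 1 is the
#'   target).
#' @param samples_per_entity Bulk samples per non-target entity (default 10).
#' @param n_target_samples Bulk samples of the target entity (default
#'   `samples_per_entity`; the signature analyses use 32, the size of the
#'   target-patient cohort they emulate).
#' @param n_genes Gene universe size (default 2000).
#' @param expression_effect Log2 shift of planted biomarkers in the target
#'   entity (default +4).
#' @param dep_effect Log2 drop of planted proteins upon fusion knockdown
#'   (default 2, applied as -2).
#' @param module_size Size of the anchor-correlated coexpression module
#'   (default 30).
#' @param module_noise_sd SD of module-gene noise around the anchor
#'   (default 0.5).
#' @param kd_replicates Replicates per arm per cell line (default 4).
#' @param kd_background_sd SD of background (non-planted) knockdown effects
#'   (default 0.3).
#' @param kd_replicate_sd Replicate-level abundance noise SD (default 0.15,
#'   typical measurement noise for well-quantified proteins).
#' @param n_proteins Protein universe: the first `n_proteins` genes
#'   (default 1500).
#' @param n_background_peaks Fusion-binding peaks placed near random
#'   non-module genes (default 200).
#' @param n_enhancer_regions Stitched H3K27ac regions (default 500).
#' @param n_planted_se Regions given a super-enhancer-scale signal
#'   (default 12).
#' @param n_cpgs CpG universe (default 400).
#' @param n_hypo_cpgs Planted hypomethylated CpGs inside the anchor gene
#'   body (default 12).
#' @param meth_shift Beta-value drop of hypomethylated CpGs in target
#'   samples (default 0.3).
#' @param n_meth_target,n_meth_mimic Methylation cohort sizes (defaults 24
#'   and 192 over 13 mimic entities).
#' @param n_tumor_cells,n_normal_cells Single-cell cohort (defaults 200 each).
#' @param sc_dispersion Negative-binomial dispersion (default 0.5).
#' @param irs_contamination Fraction of mimic IHC samples with weak staining
#'   (default 0.02, mirroring the ~98%-specificity regime).
#' @return Named list of parameters.
#' @export
truth_params <- function(n_entities = 8, samples_per_entity = 10,
                         n_target_samples = samples_per_entity,
                         n_genes = 2000,
                         expression_effect = 4, dep_effect = 2,
                         module_size = 30, module_noise_sd = 0.5,
                         kd_replicates = 4, kd_background_sd = 0.3,
                         kd_replicate_sd = 0.15, n_proteins = 1500,
                         n_background_peaks = 200,
                         n_enhancer_regions = 500, n_planted_se = 12,
                         n_cpgs = 400, n_hypo_cpgs = 12, meth_shift = 0.3,
                         n_meth_target = 24, n_meth_mimic = 192,
                         n_tumor_cells = 200, n_normal_cells = 200,
                         sc_dispersion = 0.5,
                         irs_contamination = 0.02) {
  as.list(environment())
}

# Deterministic gene annotation: 0-based half-open bodies, 200 kb TSS
# spacing, alternating strand; minus-strand TSS = body end.
.gene_annotation <- function(n_genes) {
  per_chr <- 250
  idx <- seq_len(n_genes) - 1
  start <- (idx %% per_chr) * 200000 + 10000
  strand <- ifelse(idx %% 2 == 0, "+", "-")
  data.frame(
    gene_id = sprintf("G%04d", seq_len(n_genes)),
    chrom = paste0("chr", idx %/% per_chr + 1),
    strand = strand, start = start, end = start + 20000,
    tss = ifelse(strand == "-", start + 20000, start),
    stringsAsFactors = FALSE)
}

#' Generate the synthetic multi-omics bundle
#'
#' Produces every input the pipeline consumes, with planted ground truth
#' recorded in `$truth`: a labeled bulk expression cohort whose target
#' entity overexpresses the planted biomarkers; replicate-level knockdown
#' proteomics for two cell lines in which the planted program drops
#' concordantly; a fusion-binding peak set in which exactly the planted
#' biomarkers carry a dedicated peak near their TSS (background peaks avoid
#' the coexpression module's loci, since indirect targets are not bound);
#' a heavy-tailed per-region H3K27ac signal; a beta-value matrix with
#' hypomethylated CpGs in the anchor gene body; single-cell counts with the
#' planted program elevated in tumor cells; and an IHC cohort whose target
#' samples score IRS in [6, 12]. Fully determined by `seed`.
#'
#' @param params Parameter list from [truth_params()].
#' @param seed Integer seed.
#' @return List of class `synthetic_bundle`: expression, gene_annotation,
#'   kd_tables, protein_gene_map, peaks, h3k27ac_regions, methylation,
#'   single_cell, irs_cohort, truth, params.
#' @export
generate_multiomics <- function(params = truth_params(), seed = 42) {
  p <- params
  if (p$expression_effect <= 0 || p$dep_effect <= 0) {
    stop("effect sizes must be > 0")
  }
  if (p$samples_per_entity < 3 || p$n_target_samples < 3) {
    stop("need >= 3 samples per entity")
  }
  with_seed(seed, {
    genes <- .gene_annotation(p$n_genes)
    gene_ids <- genes$gene_id
    biomarkers <- c("G0001", "G0010")
    anchor <- biomarkers[1]
    module <- sprintf("G%04d", 1200 + seq_len(p$module_size))
    entities <- c("DSRCT", sprintf("mimic_%02d", seq_len(p$n_entities - 1)))
    n_per <- c(p$n_target_samples, rep(p$samples_per_entity, p$n_entities - 1))
    entity <- rep(entities, n_per)
    n_samp <- length(entity)
    sample_ids <- sprintf("S%03d", seq_len(n_samp))

    # bulk expression: background N(6,1); planted biomarkers +effect in target
    m <- matrix(stats::rnorm(p$n_genes * n_samp, 6, 1), p$n_genes, n_samp,
                dimnames = list(gene_ids, sample_ids))
    tgt <- entity == "DSRCT"
    m[biomarkers, tgt] <- m[biomarkers, tgt] + p$expression_effect
    for (g in module) {
      m[g, ] <- m[anchor, ] + stats::rnorm(n_samp, 0, p$module_noise_sd)
    }
    expr <- expression_matrix(m, stats::setNames(entity, sample_ids))

    # knockdown proteomics, two cell lines, planted program drops by -effect
    proteins <- gene_ids[seq_len(p$n_proteins)]
    planted_dep <- intersect(c(biomarkers, module), proteins)
    kd_tables <- list()
    for (line in c("lineA", "lineB")) {
      base <- stats::rnorm(p$n_proteins, 6, 1)
      eff <- stats::rnorm(p$n_proteins, 0, p$kd_background_sd)
      eff[match(planted_dep, proteins)] <- -p$dep_effect
      ctrl <- base + matrix(stats::rnorm(p$n_proteins * p$kd_replicates, 0,
                                         p$kd_replicate_sd),
                            p$n_proteins)
      kd <- base + eff + matrix(stats::rnorm(p$n_proteins * p$kd_replicates, 0,
                                             p$kd_replicate_sd),
                                p$n_proteins)
      dimnames(ctrl) <- list(proteins, sprintf("%s_ctrl_%d", line,
                                               seq_len(p$kd_replicates)))
      dimnames(kd) <- list(proteins, sprintf("%s_kd_%d", line,
                                             seq_len(p$kd_replicates)))
      kd_tables[[line]] <- list(control = ctrl, knockdown = kd)
    }

    # fusion-binding peaks: one dedicated peak per planted biomarker near its
    # TSS; background peaks near random gene TSSs, avoiding the (indirect)
    # module loci
    planted_rows <- match(biomarkers, gene_ids)
    peak_list <- data.frame(
      chrom = genes$chrom[planted_rows],
      start = genes$tss[planted_rows] - 5000,
      end = genes$tss[planted_rows] - 4000,
      name = paste0("peak_bm_", biomarkers),
      score = stats::runif(length(biomarkers), 20, 40),
      stringsAsFactors = FALSE)
    eligible <- setdiff(seq_len(p$n_genes), match(c(module, biomarkers), gene_ids))
    bg <- sample(eligible, p$n_background_peaks, replace = TRUE)
    off <- stats::runif(p$n_background_peaks, -80000, 80000)
    bg_start <- pmax(0, round(genes$tss[bg] + off))
    peaks <- rbind(peak_list, data.frame(
      chrom = genes$chrom[bg], start = bg_start, end = bg_start + 1000,
      name = sprintf("peak_bg_%03d", seq_len(p$n_background_peaks)),
      score = stats::runif(p$n_background_peaks, 1, 10),
      stringsAsFactors = FALSE))

    # stitched H3K27ac regions with a hockey-stick tail
    n_reg <- p$n_enhancer_regions
    sig <- stats::rgamma(n_reg, shape = 2, scale = 2)
    se_idx <- sample(n_reg, p$n_planted_se)
    sig[se_idx] <- stats::runif(p$n_planted_se, 60, 150)
    reg_start <- seq_len(n_reg) * 50000
    h3k27ac <- data.frame(
      region_id = sprintf("R%03d", seq_len(n_reg)),
      chrom = paste0("chr", (seq_len(n_reg) - 1) %% 8 + 1),
      start = reg_start, end = reg_start + 20000,
      component_peak_count = 1L + stats::rpois(n_reg, 2),
      total_signal = sig, stringsAsFactors = FALSE)

    # methylation: logit-normal betas; planted CpGs inside the anchor gene
    # body drop by meth_shift in target samples
    anchor_row <- genes[genes$gene_id == anchor, ]
    hypo_ids <- sprintf("cg%05d", seq_len(p$n_hypo_cpgs))
    other_ids <- sprintf("cg%05d", p$n_hypo_cpgs + seq_len(p$n_cpgs - p$n_hypo_cpgs))
    cpg_annotation <- rbind(
      data.frame(cpg_id = hypo_ids, chrom = anchor_row$chrom,
                 position = round(seq(anchor_row$start + 500,
                                      anchor_row$end - 500,
                                      length.out = p$n_hypo_cpgs)),
                 stringsAsFactors = FALSE),
      data.frame(cpg_id = other_ids,
                 chrom = paste0("chr", sample(8, p$n_cpgs - p$n_hypo_cpgs,
                                              replace = TRUE)),
                 position = sample(1000000:50000000,
                                   p$n_cpgs - p$n_hypo_cpgs),
                 stringsAsFactors = FALSE))
    meth_entities <- c(rep("DSRCT", p$n_meth_target),
                       rep(sprintf("mimic_%02d", seq_len(13)),
                           length.out = p$n_meth_mimic))
    n_meth <- length(meth_entities)
    meth_ids <- sprintf("M%03d", seq_len(n_meth))
    mu_logit <- stats::rnorm(p$n_cpgs, 1.0, 0.8)
    beta <- stats::plogis(matrix(stats::rnorm(p$n_cpgs * n_meth, mu_logit, 0.5),
                                 p$n_cpgs, n_meth,
                                 dimnames = list(c(hypo_ids, other_ids),
                                                 meth_ids)))
    mtgt <- meth_entities == "DSRCT"
    beta[hypo_ids, mtgt] <- pmax(beta[hypo_ids, mtgt] - p$meth_shift, 0.01)

    # single-cell counts: NB, planted program elevated in tumor cells
    n_cells <- p$n_tumor_cells + p$n_normal_cells
    cell_type <- rep(c("tumor", "normal"), c(p$n_tumor_cells, p$n_normal_cells))
    cell_ids <- sprintf("C%04d", seq_len(n_cells))
    size <- 1 / p$sc_dispersion
    mu <- matrix(1, p$n_genes, n_cells, dimnames = list(gene_ids, cell_ids))
    mu[c(biomarkers, module), cell_type == "tumor"] <- 8
    counts <- matrix(stats::rnbinom(length(mu), size = size, mu = mu),
                     p$n_genes, n_cells, dimnames = dimnames(mu))

    irs_cohort <- generate_irs_cohort(
      n_target = 61, n_mimics_total = 249, n_mimic_entities = 18,
      contamination = p$irs_contamination,
      seed = sample.int(2^31 - 1, 1))

    truth <- list(
      planted_biomarkers = biomarkers, target_entity = "DSRCT",
      anchor_gene = anchor,
      expression_effect = p$expression_effect, dep_effect = p$dep_effect,
      coexpression_module = module, dep_planted = planted_dep,
      hypomethylated_cpgs = hypo_ids,
      se_regions = sort(h3k27ac$region_id[se_idx]),
      seed = seed)

    structure(list(
      expression = expr, gene_annotation = genes, kd_tables = kd_tables,
      protein_gene_map = stats::setNames(proteins, proteins),
      peaks = peaks, h3k27ac_regions = h3k27ac,
      methylation = list(beta = beta,
                         entity = stats::setNames(meth_entities, meth_ids),
                         cpg_annotation = cpg_annotation),
      single_cell = list(counts = counts,
                         cell_labels = stats::setNames(cell_type, cell_ids)),
      irs_cohort = irs_cohort, truth = truth, params = p),
      class = "synthetic_bundle")
  })
}

#' Generate a synthetic IHC cohort
#'
#' Target-entity samples draw IRS uniformly from {6, 8, 9, 12} (the products
#' reachable with strong staining), realized as consistent
#' (intensity, percent-positive) pairs; mimic samples are negative (IRS 0)
#' except for a `contamination` fraction with weak staining scoring 2-4.
#'
#' @param n_target Number of target-entity samples (>= 1; default 61).
#' @param n_mimics_per_entity Mimic samples per mimic entity; overrides
#'   `n_mimics_total` when given.
#' @param n_mimic_entities Number of mimic entities (default 18).
#' @param n_mimics_total Total mimic samples (default 249), spread as evenly
#'   as possible over the entities.
#' @param contamination Fraction of mimic samples with weak staining, in
#'   \[0, 1) (default 0.02).
#' @param seed Integer seed.
#' @return data.frame: sample_id, entity, intensity, percent_positive,
#'   proportion_category, irs.
#' @export
generate_irs_cohort <- function(n_target = 61, n_mimics_per_entity = NULL,
                                n_mimic_entities = 18, n_mimics_total = 249,
                                contamination = 0.02, seed = 1) {
  stopifnot(n_target >= 1, contamination >= 0, contamination < 1)
  if (!is.null(n_mimics_per_entity)) {
    stopifnot(all(n_mimics_per_entity >= 1))
    counts <- rep(n_mimics_per_entity, length.out = n_mimic_entities)
  } else {
    base <- n_mimics_total %/% n_mimic_entities
    counts <- rep(base, n_mimic_entities)
    extra <- n_mimics_total - sum(counts)
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1
    stopifnot(all(counts >= 1))
  }
  # (intensity, band) pairs realizing each IRS value used by the generator
  pairs <- list(`6` = rbind(c(2, 3), c(3, 2)), `8` = rbind(c(2, 4)),
                `9` = rbind(c(3, 3)), `12` = rbind(c(3, 4)),
                `2` = rbind(c(1, 2), c(2, 1)), `3` = rbind(c(1, 3), c(3, 1)),
                `4` = rbind(c(1, 4), c(2, 2), c(4, 1))[1:3, , drop = FALSE])
  band_pct <- function(category) {
    switch(category + 1L, 0,
           stats::runif(1, 1, 9.5),       # (0,10)
           stats::runif(1, 10, 50),       # [10,50]
           stats::runif(1, 50.5, 80),     # (50,80]
           stats::runif(1, 80.5, 100))    # (80,100]
  }
  realize <- function(irs_value) {
    opts <- pairs[[as.character(irs_value)]]
    opts <- opts[opts[, 1] <= 3 & opts[, 2] <= 4, , drop = FALSE]
    pick <- opts[sample(nrow(opts), 1), ]
    pct <- band_pct(pick[2])
    rec <- compute_irs(pick[1], pct)
    stopifnot(rec$irs == irs_value)
    rec
  }
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_target)) {
      rec <- realize(sample(c(6, 8, 9, 12), 1))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("T%03d", i), entity = "DSRCT",
        intensity = rec$intensity, percent_positive = rec$percent_positive,
        proportion_category = rec$proportion_category, irs = rec$irs)
    }
    k <- 0L
    for (e in seq_len(n_mimic_entities)) {
      for (i in seq_len(counts[e])) {
        k <- k + 1L
        if (stats::runif(1) < contamination) {
          rec <- realize(sample(c(2, 3, 4), 1))
        } else {
          rec <- compute_irs(0L, 0)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("N%03d", k),
          entity = sprintf("mimic_%02d", e),
          intensity = rec$intensity, percent_positive = rec$percent_positive,
          proportion_category = rec$proportion_category, irs = rec$irs)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
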