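#' Pipeline configuration
#'
#' Bundles every tunable threshold of the pipeline into one validated object
#' that can be serialized to YAML and read back unchanged, so a whole run is
#' reproducible from a single artifact.
#'
#' @param deg_lfc Log2 fold-change gate for one-vs-rest differential
#'   expression (log2 units; default 2.5).
#' @param deg_padj Adjusted-p gate for differential expression (default 0.01).
#' @param dep_lfc Log2 fold-change gate for knockdown proteomics (default 1.0).
#' @param dep_padj Adjusted-p gate for knockdown proteomics (default 0.01).
#' @param max_tss_distance Maximum peak-edge-to-TSS distance, in bp, for
#'   peak-to-gene assignment (default 100000).
#' @param stitching_distance Maximum gap, in bp, across which enhancer peaks
#'   are stitched into one region (default 12500, the canonical ROSE constant).
#' @param ssgsea_alpha Rank-weight exponent for single-sample GSEA
#'   (default 0.25).
#' @param gsea_permutations Number of gene-sampling permutations for the
#'   preranked-GSEA null (default 1000).
#' @param irs_positive_cutoff IRS cutoff of the diagnostic decision rule:
#'   a sample is called compatible with the target entity iff IRS > cutoff
#'   (default 1, integer in [0, 12]).
#' @param random_seed Integer seed controlling every stochastic step.
#' @param paths Named list of input/output locations (free-form).
#'
#' @return An object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(deg_lfc = 2.5, deg_padj = 0.01,
                            dep_lfc = 1.0, dep_padj = 0.01,
                            max_tss_distance = 100000L,
                            stitching_distance = 12500L,
                            ssgsea_alpha = 0.25,
                            gsea_permutations = 1000L,
                            irs_positive_cutoff = 1L,
                            random_seed = 1L,
                            paths = list()) {
  cfg <- list(
    thresholds = list(deg_lfc = as.numeric(deg_lfc), deg_padj = as.numeric(deg_padj),
                      dep_lfc = as.numeric(dep_lfc), dep_padj = as.numeric(dep_padj)),
    peak_assignment = list(max_tss_distance = as.integer(max_tss_distance)),
    stitching_distance = as.integer(stitching_distance),
    ssgsea_alpha = as.numeric(ssgsea_alpha),
    gsea_permutations = as.integer(gsea_permutations),
    irs_positive_cutoff = as.integer(irs_positive_cutoff),
    random_seed = as.integer(random_seed),
    paths = paths
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  pos <- c(deg_lfc = th$deg_lfc, deg_padj = th$deg_padj,
           dep_lfc = th$dep_lfc, dep_padj = th$dep_padj,
           max_tss_distance = cfg$peak_assignment$max_tss_distance,
           ssgsea_alpha = cfg$ssgsea_alpha,
           gsea_permutations = cfg$gsea_permutations)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  # alpha = 0 is a legal rank-only scoring mode
  bad <- setdiff(bad, if (identical(cfg$ssgsea_alpha, 0)) "ssgsea_alpha" else character())
  if (cfg$ssgsea_alpha < 0) bad <- union(bad, "ssgsea_alpha")
  if (cfg$stitching_distance < 0) bad <- c(bad, "stitching_distance")
  if (length(bad) > 0) {
    stop("pipeline_config: non-positive threshold(s): ", paste(bad, collapse = ", "))
  }
  if (cfg$irs_positive_cutoff < 0 || cfg$irs_positive_cutoff > 12) {
    stop("pipeline_config: irs_positive_cutoff must lie in [0, 12]")
  }
  invisible(cfg)
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config A `pipeline_config` object.
#' @param path File path.
#' @return `read_config` returns a `pipeline_config`; writing returns the path
#'   invisibly. Serializing then parsing is an identity.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    raw$thresholds,
    list(max_tss_distance = raw$peak_assignment$max_tss_distance,
         stitching_distance = raw$stitching_distance,
         ssgsea_alpha = raw$ssgsea_alpha,
         gsea_permutations = raw$gsea_permutations,
         irs_positive_cutoff = raw$irs_positive_cutoff,
         random_seed = raw$random_seed,
         paths = if (length(raw$paths) == 0) list() else raw$paths)
  ))
}

#' Run log
#'
#' A lightweight append-only record of pipeline stages: each stage contributes
#' exactly one record carrying a timestamp, the seed in force, and the feature
#' counts passing its gate. Re-running with identical seed and inputs must
#' reproduce identical counts.
#'
#' @param seed Integer seed recorded in the header.
#' @return An environment of class `run_log`.
#' @export
run_log <- function(seed = NA_integer_) {
  log <- new.env(parent = emptyenv())
  log$seed <- seed
  log$records <- list()
  class(log) <- "run_log"
  log
}

#' @param log A `run_log`.
#' @param stage Stage name (one record per stage).
#' @param counts Named integer vector of features passing the stage's gate(s).
#' @param digest Optional input digest string.
#' @rdname run_log
#' @export
log_stage <- function(log, stage, counts = integer(), digest = NA_character_) {
  stopifnot(inherits(log, "run_log"))
  if (stage %in% vapply(log$records, `[[`, "", "stage")) {
    stop("run_log: stage '", stage, "' already recorded")
  }
  log$records[[length(log$records) + 1L]] <- list(
    stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    counts = counts, digest = digest)
  invisible(log)
}

#' @rdname run_log
#' @export
log_counts <- function(log) {
  stopifnot(inherits(log, "run_log"))
  stats::setNames(
    lapply(log$records, `[[`, "counts"),
    vapply(log$records, `[[`, "", "stage"))
}

#' @param path File path for the plain-text log.
#' @rdname run_log
#' @export
write_run_log <- function(log, path) {
  stopifnot(inherits(log, "run_log"))
  lines <- c(sprintf("# run log (seed %s)", log$seed))
  for (r in log$records) {
    cts <- if (length(r$counts) > 0) {
      paste(sprintf("%s=%s", names(r$counts), r$counts), collapse = " ")
    } else ""
    lines <- c(lines, sprintf("%s\t%s\t%s\t%s", r$time, r$stage, cts, r$digest))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a log2 expression matrix with entity labels
#'
#' Expects a TSV with feature IDs in the first column and sample IDs in the
#' header, plus a two-column label file (sample, entity). Missing values are
#' rejected, not imputed: the pipeline assumes already-normalized, complete
#' log2 matrices.
#'
#' @param path Matrix TSV path.
#' @param label_path Label TSV path (columns `sample`, `entity`).
#' @return An `expression_matrix`: a numeric matrix (features x samples) with
#'   an `entity` attribute naming each sample's entity.
#' @export
read_expression_matrix <- function(path, label_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate feature ID(s): ", paste(dup, collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  lab <- utils::read.delim(label_path, stringsAsFactors = FALSE)
  labels <- stats::setNames(as.character(lab$entity), as.character(lab$sample))
  expression_matrix(m, labels)
}

#' Construct an expression matrix object
#'
#' @param values Numeric matrix, features x samples, log2 scale, no missing
#'   values.
#' @param entity_labels Named character vector mapping every sample (column)
#'   to exactly one entity.
#' @return An `expression_matrix` (matrix with `entity` attribute).
#' @export
expression_matrix <- function(values, entity_labels) {
  stopifnot(is.matrix(values))
  if (anyNA(values)) stop("expression matrix contains missing values")
  unmatched <- setdiff(colnames(values), names(entity_labels))
  if (length(unmatched) > 0) {
    stop("samples without entity label: ", paste(unmatched, collapse = ", "))
  }
  attr(values, "entity") <- entity_labels[colnames(values)]
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @param x An `expression_matrix`.
#' @rdname expression_matrix
#' @export
entity_labels <- function(x) attr(x, "entity")

#' Write an expression matrix and its labels
#'
#' @param x An `expression_matrix`.
#' @param path Matrix TSV path.
#' @param label_path Label TSV path.
#' @export
write_expression_matrix <- function(x, path, label_path = NULL) {
  m <- unclass(x)[, , drop = FALSE]
  # %.17g keeps doubles bitwise round-trippable through the text format
  chr <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  df <- data.frame(feature = rownames(m), chr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(label_path)) {
    lab <- data.frame(sample = colnames(x), entity = unname(entity_labels(x)))
    utils::write.table(lab, label_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then members. Members are
#' deduplicated preserving first occurrence.
#'
#' @param path GMT path.
#' @return Named list of character vectors (member IDs); the `description`
#'   attribute on each element keeps the second field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, ": fewer than 3 fields")
    }
    members <- unique(fields[-(1:2)])
    attr(members, "description") <- fields[[2]]
    sets[[fields[[1]]]] <- members
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path GMT path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of scored peaks
#'
#' BED3+ with optional name (4th) and score (5th) columns; coordinates are
#' 0-based half-open throughout the pipeline. Score defaults to 0 when
#' absent. Input order is preserved; sorting is the consumer's job.
#'
#' @param path BED path.
#' @return A `data.frame` with columns chrom, start, end, name, score.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("BED line ", i, ": fewer than 3 fields")
    start <- as.numeric(f[[2]]); end <- as.numeric(f[[3]])
    if (is.na(start) || is.na(end)) stop("BED line ", i, ": non-numeric coordinates")
    if (start >= end) stop("BED line ", i, ": empty or inverted interval (start >= end)")
    out[[i]] <- data.frame(
      chrom = f[[1]], start = start, end = end,
      name = if (length(f) >= 4) f[[4]] else paste0("peak_", i),
      score = if (length(f) >= 5) as.numeric(f[[5]]) else 0,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     name = character(), score = numeric())
  }
  df
}

#' Write peaks as BED
#'
#' @param peaks data.frame with chrom, start, end, name, score.
#' @param path BED path.
#' @export
write_bed <- function(peaks, path) {
  utils::write.table(
    peaks[, c("chrom", "start", "end", "name", "score")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a generic TSV table
#'
#' Thin wrappers kept so every pipeline file passes through one code path.
#'
#' @param path TSV path.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @param df A data.frame.
#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
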