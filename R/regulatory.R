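#' Assign ChIP peaks to genes by TSS proximity
#'
#' A peak is assigned to every gene whose transcription start site lies
#' within `max_tss_distance` bp of the peak's nearest edge (distance 0 when
#' the TSS falls inside the peak). Coordinates are 0-based half-open; the
#' TSS of a minus-strand gene is its annotation `end`. A peak may serve
#' several genes; genes with at least one assigned peak form the candidate
#' fusion-target set.
#'
#' @param peaks data.frame with chrom, start, end, name, score (as from
#'   [read_bed()]).
#' @param genes data.frame with gene_id, chrom, strand, start, end. A `tss`
#'   column is honoured if present, otherwise derived from strand.
#' @param max_tss_distance Maximum edge-to-TSS distance in bp (> 0).
#' @return List with `assignments` (data.frame gene_id, peak, distance) and
#'   `target_genes` (character vector). Peaks on chromosomes absent from the
#'   annotation are skipped with a warning.
#' @export
assign_peaks_to_genes <- function(peaks, genes, max_tss_distance = 100000) {
  stopifnot(max_tss_distance > 0)
  tss <- if ("tss" %in% names(genes)) genes$tss else
    ifelse(genes$strand == "-", genes$end, genes$start)
  missing_chr <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (length(missing_chr) > 0) {
    warning("skipping peaks on chromosome(s) absent from annotation: ",
            paste(missing_chr, collapse = ", "))
    peaks <- peaks[!peaks$chrom %in% missing_chr, , drop = FALSE]
  }
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    same <- which(genes$chrom == peaks$chrom[i])
    # edge distance to a point TSS under 0-based half-open intervals
    d <- pmax(0, peaks$start[i] - tss[same], tss[same] - peaks$end[i])
    hit <- same[d <= max_tss_distance]
    if (length(hit) > 0) {
      out[[i]] <- data.frame(gene_id = genes$gene_id[hit],
                             peak = peaks$name[i],
                             distance = d[d <= max_tss_distance],
                             stringsAsFactors = FALSE)
    }
  }
  asg <- do.call(rbind, out)
  if (is.null(asg)) {
    asg <- data.frame(gene_id = character(), peak = character(),
                      distance = numeric())
  }
  asg <- asg[order(asg$gene_id, asg$distance, asg$peak), , drop = FALSE]
  rownames(asg) <- NULL
  list(assignments = asg, target_genes = sort(unique(asg$gene_id)))
}

#' Stitch enhancer peaks into regions
#'
#' Peaks on the same chromosome whose gap is at most `stitching_distance` bp
#' are merged transitively (ROSE-style). Each stitched region records how
#' many peaks it absorbed and the sum of their signals.
#'
#' @param peaks data.frame with chrom, start, end, name, score.
#' @param stitching_distance Maximum gap in bp (>= 0; default 12500).
#' @return data.frame chrom, start, end, component_peak_count, total_signal,
#'   sorted by chrom then start; intervals are pairwise disjoint per
#'   chromosome.
#' @export
stitch_peaks <- function(peaks, stitching_distance = 12500) {
  stopifnot(stitching_distance >= 0)
  if (nrow(peaks) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      component_peak_count = integer(), total_signal = numeric()))
  }
  gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end))  # to 1-based closed
  red <- GenomicRanges::reduce(gr, min.gapwidth = stitching_distance + 1,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end = GenomicRanges::end(red),
    component_peak_count = lengths(revmap),
    total_signal = vapply(revmap, function(ix) sum(peaks$score[ix]), 0),
    stringsAsFactors = FALSE)
}

#' Call super-enhancers by the rank-curve tangent cutoff
#'
#' Regions are sorted by total signal ascending; rank and signal are scaled
#' to `x_i = i/n` and `y_i = s_i / s_max` (division by the maximum keeps an
#' all-positive vector inside (0, 1]). The cutoff index is
#' `i* = argmax_i (x_i - y_i)` — where the scaled curve's tangent has slope
#' one for a convex profile — with ties broken toward the larger index.
#' Regions with `total_signal > s_{i*}` are super-enhancers.
#'
#' @param stitched data.frame as from [stitch_peaks()] (or any table with a
#'   `total_signal` column); >= 2 rows with non-identical signals.
#' @return The input with `rank` (1 = lowest signal) and `is_super` columns,
#'   sorted ascending by signal, plus attributes `cutoff_signal`,
#'   `cutoff_index`, `n_super`, and `weak_elbow` (TRUE when
#'   `max(x - y) < 0.1`, i.e. no pronounced hockey-stick).
#' @export
call_super_enhancers <- function(stitched) {
  s <- stitched$total_signal
  if (length(s) < 2 || length(unique(s)) == 1) {
    stop("degenerate signal vector, no cutoff")
  }
  ord <- order(s)
  s <- s[ord]
  n <- length(s)
  gap <- seq_len(n) / n - s / max(s)
  istar <- max(which(gap == max(gap)))   # ties toward the larger index
  cutoff <- s[istar]
  out <- stitched[ord, , drop = FALSE]
  out$rank <- seq_len(n)
  out$is_super <- out$total_signal > cutoff
  rownames(out) <- NULL
  attr(out, "cutoff_signal") <- cutoff
  attr(out, "cutoff_index") <- istar
  attr(out, "n_super") <- sum(out$is_super)
  attr(out, "weak_elbow") <- max(gap) < 0.1
  out
}
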