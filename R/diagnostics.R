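#' Immunoreactive score (IRS) from staining intensity and positivity
#'
#' Classical Remmele-Stegner scheme: staining intensity (0-3) times the
#' positive-cell proportion category, banded as 0 for 0%, 1 for (0,10)%,
#' 2 for [10,50]%, 3 for (50,80]%, 4 for (80,100]%. Band edges are
#' config-exposed so a modified banding can be dialled in.
#'
#' @param intensity Integer in {0,1,2,3}.
#' @param percent_positive Percentage of stained cells in [0, 100].
#' @param band_edges Upper edges of bands 1-3 (default c(10, 50, 80)); band
#'   2 is closed on both sides at the default edges.
#' @return List: intensity, percent_positive, proportion_category, irs
#'   (product, in 0..12).
#' @export
compute_irs <- function(intensity, percent_positive,
                        band_edges = c(10, 50, 80)) {
  if (!intensity %in% 0:3) stop("intensity must be in {0,1,2,3}")
  if (!is.finite(percent_positive) || percent_positive < 0 ||
      percent_positive > 100) {
    stop("percent_positive must lie in [0, 100]")
  }
  category <- if (percent_positive == 0) 0L
    else if (percent_positive < band_edges[1]) 1L
    else if (percent_positive <= band_edges[2]) 2L
    else if (percent_positive <= band_edges[3]) 3L
    else 4L
  list(intensity = as.integer(intensity),
       percent_positive = percent_positive,
       proportion_category = category,
       irs = as.integer(intensity) * category)
}

#' Cutoff-indexed diagnostic sensitivity/specificity curve
#'
#' For every integer cutoff c in 0..12, classifies "positive iff IRS >= c"
#' and tabulates TP/FP/TN/FN with the target entity as the positive class.
#' Also reports the two named operating points of the proposed workflow:
#' the rule "IRS > 1" (c = 2) and the largest cutoff that preserves 100%
#' sensitivity.
#'
#' @param records data.frame with columns entity and irs (integers 0..12).
#' @param target_entity Positive-class label (>= 1 record each class).
#' @return List: `curve` (data.frame cutoff, sensitivity, specificity, TP,
#'   FP, TN, FN; percentages), `operating_points` (specificity at the
#'   IRS > 1 rule; max cutoff with sensitivity 100).
#' @export
diagnostic_curve <- function(records, target_entity) {
  if (anyNA(records$irs)) stop("missing IRS value(s)")
  is_tgt <- records$entity == target_entity
  if (sum(is_tgt) < 1 || sum(!is_tgt) < 1) {
    stop("need >= 1 target and >= 1 non-target record")
  }
  rows <- lapply(0:12, function(cc) {
    pos <- records$irs >= cc
    tp <- sum(pos & is_tgt); fn <- sum(!pos & is_tgt)
    fp <- sum(pos & !is_tgt); tn <- sum(!pos & !is_tgt)
    data.frame(cutoff = cc,
               sensitivity = 100 * tp / (tp + fn),
               specificity = 100 * tn / (tn + fp),
               TP = tp, FP = fp, TN = tn, FN = fn)
  })
  curve <- do.call(rbind, rows)
  full_sens <- curve$cutoff[curve$sensitivity == 100]
  list(curve = curve,
       operating_points = list(
         specificity_irs_gt1 = curve$specificity[curve$cutoff == 2],
         sensitivity_irs_gt1 = curve$sensitivity[curve$cutoff == 2],
         max_cutoff_full_sensitivity =
           if (length(full_sens) > 0) max(full_sens) else NA_integer_))
}

#' Diagnostic decision rule
#'
#' The proposed workflow: a sample with IRS above the cutoff is compatible
#' with the target-entity diagnosis; at or below it, the diagnosis should be
#' reconsidered with molecular testing (the boundary is exclusive: IRS <=
#' cutoff triggers reconsideration).
#'
#' @param irs Integer IRS in 0..12.
#' @param cutoff Decision cutoff (default 1).
#' @return `"compatible_with_target"` or `"reconsider_molecular_testing"`.
#' @export
classify_sample <- function(irs, cutoff = 1) {
  stopifnot(irs %in% 0:12)
  if (irs > cutoff) "compatible_with_target" else "reconsider_molecular_testing"
}
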