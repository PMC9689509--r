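#' Segmentation quality metrics
#'
#' Pixel accuracy (PA), mean per-class pixel accuracy (MPA) and mean
#' intersection-over-union (MIOU) between a predicted and a reference label
#' mask, all in percent.  Classes absent from both masks are excluded from
#' the class means.
#'
#' @param pred,truth Integer matrices of class indices in `[0, num_classes)`,
#'   same shape.
#' @param num_classes Number of classes.
#' @return List with elements `pa`, `mpa`, `miou` (percent).
#' @export
segmentation_metrics <- function(pred, truth, num_classes) {
  if (!all(dim(pred) == dim(truth))) stop("incompatible masks: shape mismatch")
  p <- as.vector(pred); t <- as.vector(truth)
  if (any(p < 0 | p >= num_classes | t < 0 | t >= num_classes))
    stop("mask values outside [0, num_classes)")
  cm <- matrix(0, num_classes, num_classes)  # rows truth, cols pred
  tab <- table(factor(t, levels = 0:(num_classes - 1)),
               factor(p, levels = 0:(num_classes - 1)))
  cm[] <- as.numeric(tab)
  diagc <- diag(cm)
  truth_n <- rowSums(cm); pred_n <- colSums(cm)
  present <- truth_n + pred_n > 0
  acc <- diagc / truth_n          # per-class accuracy (NaN when class absent)
  iou <- diagc / (truth_n + pred_n - diagc)
  present_t <- truth_n > 0
  list(pa = 100 * sum(diagc) / sum(cm),
       mpa = 100 * mean(acc[present_t]),
       miou = 100 * mean(iou[present]))
}

#' Mismatch rate of a stereo matching result
#'
#' Fraction of mismatched pairs among all produced pairs, in percent — the
#' statistic used to compare corner matching against descriptor-based
#' (SURF) matching.
#'
#' @param n_mismatched Number of mismatched pairs.
#' @param n_total Total number of pairs.
#' @return Percentage, rounded to 1 decimal place.
#' @export
mismatch_rate <- function(n_mismatched, n_total) {
  stopifnot(n_total >= 1, n_mismatched >= 0, n_mismatched <= n_total)
  round(100 * n_mismatched / n_total, 1)
}
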