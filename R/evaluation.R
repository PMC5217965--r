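.mask_counts <- function(X, Y) {
  stopifnot(identical(dim(X), dim(Y)))
  x <- as.logical(X)
  y <- as.logical(Y)
  c(nx = sum(x), ny = sum(y), inter = sum(x & y))
}

#' Dice similarity coefficient
#'
#' DSC(X, Y) = 2|X intersect Y| / (|X| + |Y|): 1 for identical masks, 0 for
#' disjoint ones. Symmetric in its arguments.
#'
#' @param X Segmented binary mask; @param Y reference binary mask (same
#'   grid). At least one must be nonempty.
#' @return Scalar in [0, 1].
#' @export
dsc <- function(X, Y) {
  n <- .mask_counts(X, Y)
  if (n["nx"] + n["ny"] == 0) stop("DSC undefined: both masks are empty")
  unname(2 * n["inter"] / (n["nx"] + n["ny"]))
}

#' False positive ratio
#'
#' FPR(X, Y) = (|X union Y| - |Y|) / |Y| = |X \\ Y| / |Y|: the number of
#' segmented voxels outside the reference, relative to the reference size.
#'
#' @inheritParams dsc
#' @return Nonnegative scalar (can exceed 1).
#' @export
fpr <- function(X, Y) {
  n <- .mask_counts(X, Y)
  if (n["ny"] == 0) stop("FPR undefined: reference mask is empty")
  unname((n["nx"] - n["inter"]) / n["ny"])
}

#' False negative ratio
#'
#' FNR(X, Y) = (|X union Y| - |X|) / |Y| = |Y \\ X| / |Y|: the fraction of
#' reference voxels missed by the segmentation.
#'
#' @inheritParams dsc
#' @return Scalar in [0, 1].
#' @export
fnr <- function(X, Y) {
  n <- .mask_counts(X, Y)
  if (n["ny"] == 0) stop("FNR undefined: reference mask is empty")
  unname((n["ny"] - n["inter"]) / n["ny"])
}

#' Evaluate a segmentation against reference labels
#'
#' Computes DSC, FPR and FNR per organ, taking as reference the voxels of
#' the ground-truth label volume carrying that organ's category id.
#'
#' @param result A [integrate_masks()] result (or a named list of masks).
#' @param truth Integer reference label volume (category ids).
#' @param comparison_id Optional identifier recorded in the report (for
#'   example "SM1" for SVM-versus-manual).
#' @return data.frame with columns `organ`, `DSC`, `FPR`, `FNR`, `n_seg`,
#'   `n_ref` and `comparison`.
#' @export
evaluate_segmentation <- function(result, truth, comparison_id = NA_character_) {
  masks <- if (inherits(result, "segmentation_result")) result$masks else result
  stopifnot(is.list(masks), !is.null(names(masks)))
  rows <- lapply(names(masks), function(organ) {
    X <- masks[[organ]]
    Y <- truth == category_id(organ)
    data.frame(organ = organ,
               DSC = dsc(X, Y), FPR = fpr(X, Y), FNR = fnr(X, Y),
               n_seg = sum(X), n_ref = sum(Y),
               comparison = comparison_id)
  })
  do.call(rbind, rows)
}

#' Compare two sets of accuracy values with the Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test between per-subject metric
#' values of two segmentation runs (for example SVM-based versus RF-based
#' DSC values). Exact for small samples without ties, normal approximation
#' otherwise.
#'
#' @param metric_values_a,metric_values_b Nonempty numeric vectors.
#' @return Two-sided p-value.
#' @export
compare_runs <- function(metric_values_a, metric_values_b) {
  if (length(metric_values_a) == 0L || length(metric_values_b) == 0L) {
    stop("both samples must be nonempty")
  }
  stats::wilcox.test(metric_values_a, metric_values_b,
                     alternative = "two.sided")$p.value
}
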