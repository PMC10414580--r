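#' Per-class true/false positive and false negative counts
#'
#' Pools each diagnosis code's binary confusion counts across the evaluation
#' set: `tp` (in truth and predicted), `fp` (predicted, not in truth), `fn`
#' (in truth, not predicted). `tp + fn` equals the class prevalence `n_j`.
#'
#' @inheritParams medtric
#' @return A numeric matrix with one row per catalog code and columns
#'   `tp`, `fp`, `fn`, `n`.
#' @export
per_class_counts <- function(eval_set) {
  stopifnot(inherits(eval_set, "evaluation_set"))
  codes <- eval_set$catalog$codes
  tp <- fp <- fn <- stats::setNames(integer(length(codes)), codes)
  for (i in seq_along(eval_set$truth)) {
    y <- eval_set$truth[[i]]
    z <- eval_set$prediction[[i]]
    hit <- intersect(y, z)
    tp[hit] <- tp[hit] + 1L
    fn[setdiff(y, z)] <- fn[setdiff(y, z)] + 1L
    fp[setdiff(z, y)] <- fp[setdiff(z, y)] + 1L
  }
  cbind(tp = tp, fp = fp, fn = fn, n = tp + fn)
}

# ratio with the 0/0 -> 0 convention used throughout the label-based and
# example-based metrics (classes never predicted and never present, empty
# predictions, etc.)
safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

#' Label-based multi-label metrics (macro and micro averages)
#'
#' Macro metrics average per-class binary precision/recall/F1 over all catalog
#' codes; micro metrics pool the tp/fp/fn counts first. Any 0/0 ratio is
#' defined as 0.
#'
#' @inheritParams medtric
#' @return Named numeric vector: `macro_precision`, `macro_recall`,
#'   `macro_f1`, `micro_precision`, `micro_recall`, `micro_f1`.
#' @export
label_based <- function(eval_set) {
  cc <- per_class_counts(eval_set)
  p_j <- safe_div(cc[, "tp"], cc[, "tp"] + cc[, "fp"])
  r_j <- safe_div(cc[, "tp"], cc[, "tp"] + cc[, "fn"])
  f_j <- safe_div(2 * p_j * r_j, p_j + r_j)
  tp <- sum(cc[, "tp"]); fp <- sum(cc[, "fp"]); fn <- sum(cc[, "fn"])
  micro_p <- safe_div(tp, tp + fp)
  micro_r <- safe_div(tp, tp + fn)
  c(macro_precision = mean(p_j), macro_recall = mean(r_j),
    macro_f1 = mean(f_j),
    micro_precision = micro_p, micro_recall = micro_r,
    micro_f1 = safe_div(2 * micro_p * micro_r, micro_p + micro_r))
}

#' Example-based multi-label metrics
#'
#' Per-instance set-overlap quantities averaged over the evaluation set:
#' Hamming loss (symmetric difference / catalog size), accuracy (Jaccard),
#' precision (overlap / predicted), recall (overlap / truth), F1, and subset
#' accuracy (exact-match indicator). Precision divides by the predicted-set
#' size and recall by the truth-set size, the standard convention; 0/0 is 0.
#'
#' @inheritParams medtric
#' @return Named numeric vector: `hamming`, `accuracy`, `precision`,
#'   `recall`, `f1`, `subset_accuracy`.
#' @export
example_based <- function(eval_set) {
  stopifnot(inherits(eval_set, "evaluation_set"))
  P <- length(eval_set$catalog$codes)
  per <- mapply(function(y, z) {
    ninter <- length(intersect(y, z))
    nunion <- length(y) + length(z) - ninter
    c(hamming = (nunion - ninter) / P,
      accuracy = safe_div(ninter, nunion),
      precision = safe_div(ninter, length(z)),
      recall = safe_div(ninter, length(y)),
      f1 = safe_div(2 * ninter, length(y) + length(z)),
      subset_accuracy = as.numeric(ninter == length(y) &&
                                     length(y) == length(z)))
  }, eval_set$truth, eval_set$prediction)
  rowMeans(per)
}

#' Weighted-accuracy challenge metric
#'
#' The cardiology-benchmark score built from the soft multi-class confusion
#' matrix `A`, with `a_jk` accumulating `1/|truth U prediction|` whenever code
#' j is in the truth and code k in the prediction of the same instance. The
#' weighted total `t = sum_jk w_jk a_jk` is normalised between the system that
#' always predicts the normal class (score 0) and the perfect system
#' (score 1). Unlike the clinically aligned score it can go below 0, and with
#' an identity weight matrix it reduces to (Jaccard) accuracy.
#'
#' @inheritParams medtric
#' @param weights Optional P x P reward matrix with unit diagonal and entries
#'   in (0, 1]; defaults to the similarity matrix of `config`.
#' @param normal_code Code of the normal class; defaults to the catalog's.
#' @return A single numeric score (1 = perfect, 0 = always-normal baseline).
#' @export
challenge_metric <- function(eval_set, config = NULL, weights = NULL,
                             normal_code = NULL) {
  stopifnot(inherits(eval_set, "evaluation_set"))
  codes <- eval_set$catalog$codes
  if (is.null(weights)) {
    if (is.null(config))
      stop("supply either a config or a weights matrix", call. = FALSE)
    weights <- config$similarity
  }
  if (!all(dim(weights) == rep(length(codes), 2L)))
    stop("weights must be a ", length(codes), " x ", length(codes),
         " matrix", call. = FALSE)
  if (any(abs(diag(weights) - 1) > 1e-12) ||
      any(weights <= 0) || any(weights > 1))
    stop("weights must have a unit diagonal and entries in (0, 1]",
         call. = FALSE)
  if (is.null(normal_code)) normal_code <- eval_set$catalog$normal_code
  if (is.null(normal_code) || !(normal_code %in% codes))
    stop("challenge metric needs a normal class in the catalog",
         call. = FALSE)

  t_of <- function(pred_list) {
    A <- matrix(0, length(codes), length(codes),
                dimnames = list(codes, codes))
    for (i in seq_along(eval_set$truth)) {
      y <- eval_set$truth[[i]]
      z <- pred_list[[i]]
      if (length(z) == 0L) next
      denom <- length(union(y, z))
      A[y, z] <- A[y, z] + 1 / denom
    }
    sum(weights * A)
  }

  t_obs <- t_of(eval_set$prediction)
  t_perfect <- t_of(eval_set$truth)
  t_normal <- t_of(rep(list(normal_code), length(eval_set$truth)))
  if (abs(t_perfect - t_normal) < 1e-12)
    stop("degenerate normalisation: perfect and all-normal predictions score ",
         "identically", call. = FALSE)
  (t_obs - t_normal) / (t_perfect - t_normal)
}
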