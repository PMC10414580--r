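#' Assemble a validated evaluation set
#'
#' An evaluation set pairs each instance's ground-truth label set with the
#' label set a diagnostic system predicted, and records per-class prevalence
#' `n_j` = number of instances whose ground truth contains code j. Prevalence
#' is computed from ground truths only: predictions cannot define how common a
#' condition is.
#'
#' Ground-truth sets must be non-empty. "No finding" is expressed through an
#' explicit normal class in the catalog, never through the empty set, because
#' the per-instance score averages similarity over truth codes and is undefined
#' for an empty truth. Predictions may be empty (an inactive system).
#'
#' @param truth List of character vectors (one ground-truth label set per
#'   instance); a single character vector is taken as one instance.
#' @param prediction List of character vectors, same length as `truth`.
#' @param catalog A [diagnosis_catalog()].
#' @param ids Optional character vector of instance identifiers; defaults to
#'   `"1"`, `"2"`, ...
#' @param config Optional [metric_config()]; when supplied, ground truths
#'   containing a contradictory pair are rejected.
#' @return An object of class `evaluation_set`: list with `catalog`, `ids`,
#'   `truth`, `prediction` (lists of de-duplicated character vectors) and
#'   `prevalence` (named integer vector over all catalog codes).
#' @examples
#' cat2 <- diagnosis_catalog(c("A", "B"))
#' es <- evaluation_set(list(c("A"), c("A", "B")), list(c("A"), c("B")), cat2)
#' es$prevalence
#' @export
evaluation_set <- function(truth, prediction, catalog, ids = NULL,
                           config = NULL) {
  stopifnot(inherits(catalog, "diagnosis_catalog"))
  if (is.character(truth)) truth <- list(truth)
  if (is.character(prediction)) prediction <- list(prediction)
  if (length(truth) != length(prediction))
    stop("truth and prediction must have the same number of instances",
         call. = FALSE)
  N <- length(truth)
  if (N < 1L) stop("an evaluation set needs at least one instance",
                   call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_len(N))
  ids <- as.character(ids)
  if (length(ids) != N) stop("ids must match the number of instances",
                             call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate instance ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)

  truth <- lapply(truth, as_label_set)
  prediction <- lapply(prediction, as_label_set)
  for (i in seq_len(N)) {
    if (length(truth[[i]]) == 0L)
      stop(sprintf("instance '%s' has an empty ground-truth set; ",
                   ids[[i]]),
           "encode 'no finding' with an explicit normal class", call. = FALSE)
    check_codes(truth[[i]], catalog, "ground truth", ids[[i]])
    check_codes(prediction[[i]], catalog, "prediction", ids[[i]])
  }
  if (!is.null(config)) check_truth_contradictions(truth, config, ids)

  prev <- stats::setNames(integer(length(catalog$codes)), catalog$codes)
  tab <- table(factor(unlist(truth), levels = catalog$codes))
  prev[names(tab)] <- as.integer(tab)

  structure(list(catalog = catalog, ids = ids, truth = truth,
                 prediction = prediction, prevalence = prev),
            class = "evaluation_set")
}

#' @export
print.evaluation_set <- function(x, ...) {
  N <- length(x$ids)
  cat("Evaluation set:", N, "instances over", length(x$catalog$codes),
      "diagnosis codes\n")
  card <- lengths(x$truth)
  cat("  label cardinality: mean ", format(round(mean(card), 2)),
      ", range [", min(card), ", ", max(card), "]\n", sep = "")
  nz <- x$prevalence[x$prevalence > 0]
  cat("  prevalence: ", length(nz), " codes observed, n_j in [",
      min(nz), ", ", max(nz), "]\n", sep = "")
  invisible(x)
}

#' Classify a prediction against its ground truth
#'
#' Partitions any (truth, prediction) pair into exactly one of five kinds:
#' `perfect` (sets equal), `missed` (prediction a proper subset of truth, which
#' includes the empty prediction), `over` (truth a proper subset of
#' prediction), `wrong` (non-empty prediction disjoint from truth), or `mixed`
#' (partial overlap with both missed and extra labels). The `degree` counts
#' the severity within a kind: missed labels for `missed`, extra labels for
#' `over`, predicted labels for `wrong`, 0 for `perfect` and `mixed`.
#'
#' @param truth Non-empty character vector of ground-truth codes.
#' @param prediction Character vector of predicted codes (possibly empty).
#' @return A list with elements `kind` (character) and `degree` (integer).
#' @examples
#' classify_prediction(c("CRBBB", "AF", "QAb"), "CRBBB")  # missed, degree 2
#' @export
classify_prediction <- function(truth, prediction) {
  truth <- as_label_set(truth)
  prediction <- as_label_set(prediction)
  if (length(truth) == 0L)
    stop("ground truth must be non-empty", call. = FALSE)
  n_common <- length(intersect(prediction, truth))
  n_missed <- length(truth) - n_common
  n_extra <- length(prediction) - n_common
  if (n_missed == 0L && n_extra == 0L) {
    list(kind = "perfect", degree = 0L)
  } else if (n_extra == 0L) {           # prediction a proper subset (or empty)
    list(kind = "missed", degree = n_missed)
  } else if (n_missed == 0L) {          # truth a proper subset
    list(kind = "over", degree = n_extra)
  } else if (n_common == 0L) {          # disjoint, non-empty
    list(kind = "wrong", degree = length(prediction))
  } else {
    list(kind = "mixed", degree = 0L)
  }
}
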