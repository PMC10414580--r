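#' Per-label score contribution of one instance
#'
#' The clinically aligned score decomposes each instance into correct, missed
#' and extra predictions, and scores code j as
#' \itemize{
#'   \item `+s_j / n_j` if j is correctly predicted (j in both sets),
#'   \item `-s_j / n_j` if j is missed (in truth, not predicted),
#'   \item `s_j / n* * (mean_k w_jk - 1)` if j is an extra prediction, where
#'     the mean runs over the truth codes k and `n*` is the largest prevalence
#'     among the instance's truth codes,
#'   \item `0` if j appears in neither set.
#' }
#' Dividing by the prevalence `n_j` makes the aggregate score independent of
#' how common each condition is in the evaluation set; the extra-prediction
#' branch is a negative penalty, strictly smaller in magnitude than a missed
#' diagnosis of any truth code, softened by clinical similarity `w_jk`.
#'
#' @param code Catalog code to score.
#' @param truth Non-empty ground-truth label set (character vector).
#' @param prediction Predicted label set.
#' @param prevalence Named integer vector of per-class prevalence counts
#'   (as in `evaluation_set()$prevalence`).
#' @param config A [metric_config()].
#' @return A single numeric contribution `a_i(j)`.
#' @seealso [contradiction_penalty()], [instance_score()], [medtric()]
#' @export
label_contribution <- function(code, truth, prediction, prevalence, config) {
  s <- config$significance[[code]]
  in_truth <- code %in% truth
  in_pred <- code %in% prediction
  if (in_truth && in_pred) {
    s / prevalence[[code]]
  } else if (in_truth) {
    -s / prevalence[[code]]
  } else if (in_pred) {
    n_star <- max(prevalence[truth])
    s / n_star * (mean(config$similarity[code, truth]) - 1)
  } else {
    0
  }
}

#' Contradiction penalty for one predicted code
#'
#' A predicted code j that co-occurs in the prediction with codes it clinically
#' contradicts (C_jk = 1) incurs `-(1/n_j) * sum_k s_k * C_jk` over the
#' predicted codes k. Each member of a contradictory predicted pair incurs its
#' own penalty, scaled by its own prevalence. A code never present in any
#' ground truth has `n_j = 0`; the configured `prevalence_floor` is substituted
#' so the penalty stays finite (and maximal).
#'
#' @inheritParams label_contribution
#' @return A non-positive numeric penalty `b_i(j)` (0 when `code` is not
#'   predicted or contradicts nothing predicted).
#' @export
contradiction_penalty <- function(code, prediction, prevalence, config) {
  if (!(code %in% prediction)) return(0)
  cross <- sum(config$significance[prediction] *
                 config$contradiction[code, prediction])
  if (cross == 0) return(0)
  n_j <- prevalence[[code]]
  if (n_j == 0L) n_j <- config$prevalence_floor
  -cross / n_j
}

#' Score one instance with full per-code breakdown
#'
#' Sums the per-label contributions and contradiction penalties over the
#' catalog for a single (truth, prediction) pair, using the prevalence counts
#' of the evaluation set the pair belongs to.
#'
#' @param truth Non-empty ground-truth label set.
#' @param prediction Predicted label set.
#' @param eval_set The [evaluation_set()] supplying prevalence counts (or any
#'   list with a `prevalence` element).
#' @param config A [metric_config()].
#' @return A list of class `instance_score` with `per_code_a` and `per_code_b`
#'   (named vectors over the codes touched by the instance) and `total`.
#' @examples
#' cat2 <- diagnosis_catalog(c("A", "B"))
#' es <- evaluation_set(list(c("A", "B")), list("A"), cat2)
#' instance_score(c("A", "B"), "A", es, metric_config(cat2))
#' @export
instance_score <- function(truth, prediction, eval_set, config) {
  truth <- as_label_set(truth)
  prediction <- as_label_set(prediction)
  if (length(truth) == 0L)
    stop("ground truth must be non-empty", call. = FALSE)
  prev <- eval_set$prevalence
  touched <- union(truth, prediction)
  a <- vapply(touched, label_contribution, numeric(1),
              truth = truth, prediction = prediction,
              prevalence = prev, config = config)
  b <- vapply(touched, contradiction_penalty, numeric(1),
              prediction = prediction, prevalence = prev, config = config)
  structure(list(per_code_a = a, per_code_b = b, total = sum(a) + sum(b)),
            class = "instance_score")
}

# fast internal instance total: index-based, no name lookups.
# iy, iz: integer indices of truth/prediction codes; s: significance vector;
# w: similarity matrix; C: contradiction matrix; n: prevalence (floored copy
# used only for penalties); n_raw: true prevalence.
instance_total_idx <- function(iy, iz, s, w, C, n_raw, floor_n, any_contra) {
  correct <- iy[match(iy, iz, 0L) > 0L]
  missed <- iy[match(iy, iz, 0L) == 0L]
  extra <- iz[match(iz, iy, 0L) == 0L]
  tot <- sum(s[correct] / n_raw[correct]) - sum(s[missed] / n_raw[missed])
  if (length(extra)) {
    n_star <- max(n_raw[iy])
    wsub <- w[extra, iy, drop = FALSE]
    tot <- tot + sum(s[extra] / n_star * (rowMeans(wsub) - 1))
  }
  if (any_contra && length(iz) > 1L) {
    cross <- as.vector(C[iz, iz, drop = FALSE] %*% s[iz])
    if (any(cross > 0)) {
      nz <- n_raw[iz]
      nz[nz == 0L] <- floor_n
      tot <- tot - sum(cross / nz)
    }
  }
  tot
}

#' Compute the clinically aligned diagnostic score
#'
#' Scores a whole evaluation set: per-instance totals (per-label rewards and
#' penalties plus contradiction penalties) are summed into `t(Y, Z)` and
#' normalised between the inactive system that predicts nothing (score 0) and
#' the perfect system that reproduces every ground truth (score 1):
#' `M = (t(Y,Z) - t(Y,0)) / (t(Y,Y) - t(Y,0))`.
#'
#' Because every contribution is divided by its class prevalence, replicating
#' instances or shifting the case mix leaves the score unchanged, and scaling
#' all significance weights by a common factor cancels in the normalisation.
#'
#' @param eval_set An [evaluation_set()].
#' @param config A [metric_config()] over the same catalog.
#' @param breakdowns If `TRUE`, attach a per-instance list of
#'   [instance_score()] breakdowns.
#' @return An object of class `medtric_result`: list with `score`, `raw_t`,
#'   `null_t`, `perfect_t` and (optionally) `breakdowns`.
#' @examples
#' cat2 <- diagnosis_catalog(c("A", "B"))
#' es <- evaluation_set(list(c("A", "B"), "A"), list("A", "A"), cat2)
#' medtric(es, metric_config(cat2))
#' @export
medtric <- function(eval_set, config, breakdowns = FALSE) {
  stopifnot(inherits(eval_set, "evaluation_set"),
            inherits(config, "metric_config"))
  if (!identical(config$codes, eval_set$catalog$codes))
    stop("config and evaluation set use different catalogs", call. = FALSE)
  check_truth_contradictions(eval_set$truth, config, eval_set$ids)

  codes <- config$codes
  s <- unname(config$significance)
  w <- config$similarity
  C <- config$contradiction
  n <- unname(eval_set$prevalence)
  any_contra <- any(C != 0)

  iy_list <- lapply(eval_set$truth, match, codes)
  iz_list <- lapply(eval_set$prediction, match, codes)
  totals <- mapply(instance_total_idx, iy_list, iz_list,
                   MoreArgs = list(s = s, w = w, C = C, n_raw = n,
                                   floor_n = config$prevalence_floor,
                                   any_contra = any_contra))
  raw_t <- sum(totals)

  # each observed code contributes s_j/n_j per occurrence, n_j occurrences:
  # the null (all-empty) and perfect baselines collapse to -/+ sum of s_j
  # over observed codes (contradiction-free truths guarantee no C terms).
  s_observed <- sum(s[n > 0L])
  null_t <- -s_observed
  perfect_t <- s_observed
  if (perfect_t <= null_t)
    stop("degenerate normalisation: no observed code has positive significance",
         call. = FALSE)

  res <- list(score = (raw_t - null_t) / (perfect_t - null_t),
              raw_t = raw_t, null_t = null_t, perfect_t = perfect_t)
  if (breakdowns) {
    res$breakdowns <- mapply(instance_score, eval_set$truth,
                             eval_set$prediction,
                             MoreArgs = list(eval_set = eval_set,
                                             config = config),
                             SIMPLIFY = FALSE)
    names(res$breakdowns) <- eval_set$ids
  }
  structure(res, class = "medtric_result")
}

#' @export
print.medtric_result <- function(x, digits = 4, ...) {
  cat("MedTric score: ", format(round(x$score, digits)), "\n", sep = "")
  cat("  raw t(Y,Z) = ", format(signif(x$raw_t, 6)),
      ",  null t(Y,0) = ", format(signif(x$null_t, 6)),
      ",  perfect t(Y,Y) = ", format(signif(x$perfect_t, 6)), "\n", sep = "")
  invisible(x)
}

#' Clinical-order guarantee margin per diagnosis
#'
#' For each observed code k, computes the margin
#' `xi_k = (s_k/n_k) * (fp_k * (n_k/n*) * (1 - w*_k) - 2 * fn_k)`
#' where `fp_k`/`fn_k` are the code's false positives/negatives in the
#' evaluation set, `n*` is the largest prevalence in the set and `w*_k` the
#' smallest similarity in row k. `xi_k` bounds from above the difference
#' between the score of a purely-missing and a purely-over-calling system with
#' these error counts: when `xi_k < 0` for every k, missed diagnoses are
#' guaranteed to score below over-diagnoses (the clinical order holds).
#' Conservatively this is the case whenever each code's false positives do not
#' exceed twice its false negatives; lowering `w*` or the relative prevalence
#' `n_k/n*` widens the region.
#'
#' @inheritParams medtric
#' @return Named numeric vector of margins, `NA` for codes never observed in
#'   any ground truth.
#' @export
clinical_order_margin <- function(eval_set, config) {
  stopifnot(inherits(eval_set, "evaluation_set"),
            inherits(config, "metric_config"))
  counts <- per_class_counts(eval_set)
  n <- eval_set$prevalence
  n_star <- max(n)
  w <- config$similarity
  off <- w
  diag(off) <- NA
  w_star <- apply(off, 1, min, na.rm = TRUE)
  if (length(config$codes) == 1L) w_star[] <- 1  # no off-diagonal entries
  s <- config$significance
  xi <- stats::setNames(rep(NA_real_, length(config$codes)), config$codes)
  obs <- names(n)[n > 0L]
  xi[obs] <- s[obs] / n[obs] *
    (counts[obs, "fp"] * (n[obs] / n_star) * (1 - w_star[obs]) -
       2 * counts[obs, "fn"])
  xi
}
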