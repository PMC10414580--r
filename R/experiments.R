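#' Simulate one prediction from a classifier with known sensitivity and
#' specificity
#'
#' Emulates a per-class black-box classifier: each ground-truth code is
#' reported independently with probability `p` (sensitivity) and each other
#' catalog code with probability `1 - q` (one minus specificity). Uses R's
#' global random number stream.
#'
#' @param truth Non-empty character vector of ground-truth codes.
#' @param catalog A [diagnosis_catalog()].
#' @param p Sensitivity in (0, 1).
#' @param q Specificity in (0, 1).
#' @return A character vector (possibly empty): the simulated prediction set.
#' @examples
#' set.seed(1)
#' random_prediction(c("C01", "C02"), synthetic_catalog(10), p = 0.8, q = 0.95)
#' @export
random_prediction <- function(truth, catalog, p, q) {
  stopifnot(p > 0, p < 1, q > 0, q < 1)
  truth <- as_label_set(truth)
  others <- setdiff(catalog$codes, truth)
  c(truth[stats::runif(length(truth)) < p],
    others[stats::runif(length(others)) < 1 - q])
}

#' Group candidate predictions into pure error-type buckets
#'
#' Buckets candidates by their [classify_prediction()] kind and degree:
#' `"wrong.2"`, `"missed.1"`, `"over.3"`, `"perfect.0"`, ... Mixed candidates
#' (simultaneous missed and extra labels) fall outside the pure error
#' taxonomy and are discarded.
#'
#' @param truth Non-empty character vector of ground-truth codes.
#' @param candidates List of candidate prediction sets (character vectors).
#' @return Named list mapping `"kind.degree"` to the list of member
#'   candidates; empty buckets are absent.
#' @examples
#' bucket_candidates(c("A", "B", "C"), list(c("A", "B"), character(0)))
#' @export
bucket_candidates <- function(truth, candidates) {
  out <- list()
  for (z in candidates) {
    cl <- classify_prediction(truth, z)
    if (cl$kind == "mixed") next
    key <- paste0(cl$kind, ".", cl$degree)
    out[[key]] <- c(out[[key]], list(as_label_set(z)))
  }
  out
}

# order bucket keys in ascending clinical quality:
# wrong (worst degree first) < missed < over < perfect
order_bucket_keys <- function(keys) {
  parts <- strsplit(keys, ".", fixed = TRUE)
  kind <- vapply(parts, `[[`, character(1), 1L)
  degree <- as.integer(vapply(parts, `[[`, character(1), 2L))
  rank <- match(kind, c("wrong", "missed", "over", "perfect"))
  keys[order(rank, -degree)]
}

new_experiment_result <- function(metric, estimate, replicate_values, params,
                                  details = NULL) {
  structure(list(metric = metric, estimate = estimate,
                 replicate_values = replicate_values, params = params,
                 details = details),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment result for metric '", x$metric, "'\n", sep = "")
  cat("  estimate: ", format(signif(x$estimate, 6)),
      "  (", length(x$replicate_values), " repeats, range [",
      format(signif(min(x$replicate_values), 6)), ", ",
      format(signif(max(x$replicate_values), 6)), "])\n", sep = "")
  invisible(x)
}

#' Clinical-order monotonicity rate of a metric
#'
#' Monte-Carlo probe of whether a metric ranks error patterns in clinical
#' order. For each of `rho` sampled ground truths, `gamma` candidate
#' predictions are drawn from the sensitivity/specificity classifier of
#' [random_prediction()], grouped into pure error-type buckets
#' ([bucket_candidates()]), and each bucket is scored as the mean metric value
#' of its members on a one-instance evaluation set. The sample passes when the
#' bucket scores strictly increase along
#' `wrong (worst first) < missed < over < perfect` over the buckets present;
#' ties count as violations. The monotonicity rate tau is the percentage of
#' passing samples, replicated `repeats` times.
#'
#' Loss-type metrics (Hamming) are orientation-adjusted before comparison so
#' that larger always means clinically better. A sample producing fewer than
#' two buckets is resampled (up to 100 attempts, then skipped).
#'
#' @param metrics Character vector of builtin metric names (see Details), or a
#'   named list mixing builtin names and functions of an `evaluation_set`.
#'   Builtins: `r paste0('\x60', builtin_metric_names, '\x60', collapse = ", ")`.
#' @param catalog A [diagnosis_catalog()]; defaults to a 10-code synthetic
#'   catalog.
#' @param config A [metric_config()] for the score-based metrics; defaults to
#'   equal significance and constant similarity `w0 = 0.8` on `catalog`.
#' @param p,q Sensitivity and specificity of the candidate generator.
#' @param rho Number of sampled ground truths per repeat.
#' @param repeats Number of experiment repetitions (replicate spread).
#' @param gamma Candidate predictions generated per sample.
#' @param cardinality Integer vector of ground-truth set sizes, sampled
#'   uniformly, or a zero-argument function returning one truth set
#'   (character vector) per call.
#' @param seed Optional integer seed.
#' @param detail If `TRUE`, attach per-sample records (buckets present and
#'   pass/fail per metric).
#' @return A single `experiment_result` (estimate = mean tau in percent across
#'   repeats, `replicate_values` = per-repeat tau) when one metric is
#'   requested, otherwise a named list of them. All requested metrics share
#'   the same sampled truths and candidates.
#' @examples
#' r <- monotonicity_rate("medtric", p = 0.8, q = 0.95, rho = 10,
#'                        repeats = 2, gamma = 40, seed = 7)
#' r$estimate
#' @export
monotonicity_rate <- function(metrics = "medtric", catalog = NULL,
                              config = NULL, p = 0.8, q = 0.95,
                              rho = 100, repeats = 10, gamma = 200,
                              cardinality = 1:3, seed = NULL,
                              detail = FALSE) {
  if (is.null(catalog)) catalog <- synthetic_catalog(10)
  if (is.null(config)) config <- metric_config(catalog, similarity = 0.8)
  stopifnot(p > 0, p < 1, q > 0, q < 1, rho >= 1, repeats >= 1, gamma >= 1)
  metrics <- normalize_metrics(metrics)
  if (!is.null(seed)) set.seed(seed)

  codes <- catalog$codes
  P <- length(codes)
  scorers <- lapply(metrics, singleton_scorer, catalog = catalog,
                    config = config)
  orient <- vapply(names(metrics), metric_orientation, numeric(1))
  sample_truth <- if (is.function(cardinality)) {
    function() match(as_label_set(cardinality()), codes)
  } else {
    cardinality <- as.integer(cardinality)
    stopifnot(all(cardinality >= 1L), all(cardinality <= P))
    function()
      sample.int(P, cardinality[sample.int(length(cardinality), 1L)])
  }

  n_metrics <- length(metrics)
  tau <- matrix(NA_real_, repeats, n_metrics,
                dimnames = list(NULL, names(metrics)))
  details <- if (detail) vector("list", repeats)
  n_skipped <- 0L

  for (rep_i in seq_len(repeats)) {
    pass <- matrix(NA, rho, n_metrics)
    sig <- character(rho)
    for (r in seq_len(rho)) {
      buckets <- NULL
      for (attempt in 1:100) {
        iy <- sample_truth()
        k <- length(iy)
        others <- setdiff(seq_len(P), iy)
        keep <- matrix(stats::runif(gamma * k) < p, gamma, k)
        extra <- matrix(stats::runif(gamma * (P - k)) < 1 - q, gamma, P - k)
        n_common <- rowSums(keep)
        n_extra <- rowSums(extra)
        n_missed <- k - n_common
        kind <- ifelse(n_missed == 0L & n_extra == 0L, "perfect",
                ifelse(n_extra == 0L, "missed",
                ifelse(n_missed == 0L, "over",
                ifelse(n_common == 0L, "wrong", "mixed"))))
        degree <- ifelse(kind == "missed", n_missed,
                  ifelse(kind == "over", n_extra,
                  ifelse(kind == "wrong", n_extra, 0L)))
        pure <- which(kind != "mixed")
        if (length(unique(paste0(kind[pure], ".", degree[pure]))) >= 2L) {
          members <- lapply(pure, function(g)
            c(iy[keep[g, ]], others[extra[g, ]]))
          buckets <- split(members, paste0(kind[pure], ".", degree[pure]))
          break
        }
      }
      if (is.null(buckets)) { n_skipped <- n_skipped + 1L; next }
      keys <- order_bucket_keys(names(buckets))
      sig[r] <- paste(keys, collapse = ";")
      scores <- vapply(seq_along(scorers), function(m) {
        sc <- scorers[[m]]
        vapply(keys, function(key)
          mean(vapply(buckets[[key]], function(iz) sc(iy, iz), numeric(1))),
          numeric(1))
      }, numeric(length(keys)))
      scores <- matrix(scores, nrow = length(keys))
      for (m in seq_len(n_metrics)) {
        o <- orient[m] * scores[, m]
        pass[r, m] <- all(diff(o) > 1e-12)
      }
    }
    tau[rep_i, ] <- 100 * colMeans(pass, na.rm = TRUE)
    if (detail) {
      df <- data.frame(sample = seq_len(rho), buckets = sig,
                       stringsAsFactors = FALSE)
      for (m in seq_len(n_metrics))
        df[[paste0("pass_", names(metrics)[m])]] <- pass[, m]
      details[[rep_i]] <- df
    }
  }
  if (n_skipped > 0L)
    message(n_skipped, " sample(s) skipped: fewer than two buckets after ",
            "100 attempts")

  params <- list(p = p, q = q, rho = rho, repeats = repeats, gamma = gamma,
                 P = P, seed = seed)
  out <- lapply(seq_len(n_metrics), function(m)
    new_experiment_result(names(metrics)[m], mean(tau[, m]), tau[, m],
                          params, details))
  names(out) <- names(metrics)
  if (n_metrics == 1L) out[[1L]] else out
}

#' Sample single-label ground truths from a two-class prevalence mixture
#'
#' Builds `l` single-label ground-truth sets, each `{a_M}` with probability
#' `alpha` and `{a_m}` otherwise — the two-class evaluation subset whose class
#' mix is governed by `alpha`.
#'
#' @param catalog A [diagnosis_catalog()].
#' @param a_M,a_m Two distinct catalog codes (the frequent and rare class).
#' @param alpha Mixing probability in `[0, 1]`.
#' @param l Number of instances.
#' @return List of `l` single-code character vectors.
#' @export
prevalence_subset <- function(catalog, a_M, a_m, alpha, l) {
  stopifnot(a_M %in% catalog$codes, a_m %in% catalog$codes, a_M != a_m,
            alpha >= 0, alpha <= 1, l >= 1)
  is_M <- stats::runif(l) < alpha
  lapply(ifelse(is_M, a_M, a_m), identity)
}

#' Prevalence-dispersion of a metric
#'
#' Measures how much a metric drifts when only the class mix of the evaluation
#' set changes while classifier quality is held fixed. For each of `eta` draws
#' of `alpha ~ U(0, 1)`, an `l`-instance two-class set is built with
#' [prevalence_subset()], predictions are simulated with per-class
#' sensitivities `p_M` (frequent class) and `p_m` (rare class) and specificity
#' `q` on every other catalog code, and the metric is evaluated on the
#' resulting set. The dispersion `sigma` is the standard deviation of the
#' `eta` metric values; a prevalence-invariant metric has `sigma` near 0.
#' Replicated `repeats` times.
#'
#' @inheritParams monotonicity_rate
#' @param p_M,p_m Sensitivity for the frequent and rare class, with
#'   `0 < p_m <= p_M < 1`.
#' @param q Specificity applied to every non-truth catalog code.
#' @param eta Number of `alpha` draws per repeat.
#' @param l Instances per evaluation set.
#' @param a_M,a_m Codes of the two mixed classes; default the catalog's first
#'   two codes.
#' @return A single `experiment_result` (estimate = mean sigma across repeats)
#'   or a named list of them; all requested metrics are evaluated on the same
#'   simulated draws.
#' @examples
#' r <- dispersion(c("medtric", "f1"), eta = 10, l = 40, repeats = 2,
#'                 seed = 11)
#' sapply(r, function(x) x$estimate)
#' @export
dispersion <- function(metrics = "medtric", catalog = NULL, config = NULL,
                       p_M = 0.9, p_m = 0.5, q = 0.95, eta = 50, l = 100,
                       repeats = 10, a_M = NULL, a_m = NULL, seed = NULL) {
  if (is.null(catalog)) catalog <- synthetic_catalog(10)
  if (is.null(config)) config <- metric_config(catalog, similarity = 0.8)
  stopifnot(p_m > 0, p_m <= p_M, p_M < 1, q > 0, q < 1,
            eta >= 1, l >= 1, repeats >= 1)
  metrics <- normalize_metrics(metrics)
  if (!is.null(seed)) set.seed(seed)
  codes <- catalog$codes
  if (is.null(a_M)) a_M <- codes[1L]
  if (is.null(a_m)) a_m <- codes[2L]
  stopifnot(a_M != a_m)

  n_metrics <- length(metrics)
  sigma <- matrix(NA_real_, repeats, n_metrics,
                  dimnames = list(NULL, names(metrics)))
  for (rep_i in seq_len(repeats)) {
    vals <- matrix(NA_real_, eta, n_metrics)
    for (d in seq_len(eta)) {
      alpha <- stats::runif(1)
      truths <- prevalence_subset(catalog, a_M, a_m, alpha, l)
      preds <- lapply(truths, function(y) {
        sens <- if (y == a_M) p_M else p_m
        random_prediction(y, catalog, sens, q)
      })
      es <- evaluation_set(truths, preds, catalog)
      vals[d, ] <- dataset_metric_values(es, config, metrics)
    }
    sigma[rep_i, ] <- apply(vals, 2, stats::sd)
  }
  params <- list(p_M = p_M, p_m = p_m, q = q, eta = eta, l = l,
                 repeats = repeats, a_M = a_M, a_m = a_m, seed = seed)
  out <- lapply(seq_len(n_metrics), function(m)
    new_experiment_result(names(metrics)[m], mean(sigma[, m]), sigma[, m],
                          params))
  names(out) <- names(metrics)
  if (n_metrics == 1L) out[[1L]] else out
}

#' Synthesise multi-label ground truths
#'
#' Fixture generator emulating the label structure of multi-label diagnostic
#' datasets: controllable label-set cardinality and per-class prevalence skew,
#' with contradictory pairs rejection-resampled away when a config is given.
#'
#' @inheritParams monotonicity_rate
#' @param n_instances Number of ground-truth sets to draw.
#' @param propensities Positive per-class sampling weights (named vector over
#'   catalog codes, unnamed vector in catalog order, or `NULL` for uniform).
#' @return List of `n_instances` character vectors (ground-truth sets).
#' @examples
#' truths <- synthesize_dataset(synthetic_catalog(5), 20, seed = 3)
#' @export
synthesize_dataset <- function(catalog, n_instances, cardinality = 1:3,
                               propensities = NULL, config = NULL,
                               seed = NULL) {
  stopifnot(inherits(catalog, "diagnosis_catalog"), n_instances >= 1)
  if (!is.null(seed)) set.seed(seed)
  codes <- catalog$codes
  P <- length(codes)
  cardinality <- as.integer(cardinality)
  stopifnot(all(cardinality >= 1L), all(cardinality <= P))
  if (is.null(propensities)) {
    prob <- rep(1 / P, P)
  } else {
    if (!is.null(names(propensities))) {
      missing <- setdiff(codes, names(propensities))
      if (length(missing))
        stop("propensities missing for code(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      propensities <- propensities[codes]
    }
    stopifnot(length(propensities) == P, all(propensities > 0))
    prob <- propensities / sum(propensities)
  }
  check_ok <- function(y) {
    if (is.null(config) || length(y) < 2L) return(TRUE)
    all(config$contradiction[y, y] == 0)
  }
  lapply(seq_len(n_instances), function(i) {
    k <- cardinality[sample.int(length(cardinality), 1L)]
    for (attempt in 1:1000) {
      y <- codes[sample.int(P, k, prob = prob)]
      if (check_ok(y)) return(y)
    }
    stop("could not draw a contradiction-free truth set of size ", k,
         call. = FALSE)
  })
}
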