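# Registry of metric evaluators used by the simulation experiments.
#
# Two forms are needed: fast singleton scorers working on integer code indices
# (the monotonicity probe scores tens of thousands of one-instance sets), and
# dataset-level evaluators for the dispersion experiment. Both are thin
# re-expressions of the exported metric functions; test-oracle.R pins their
# agreement.

builtin_metric_names <- c(
  "medtric",
  "macro_precision", "macro_recall", "macro_f1",
  "micro_precision", "micro_recall", "micro_f1",
  "hamming", "accuracy", "precision", "recall", "f1", "subset_accuracy",
  "challenge_metric")

# +1 when larger values mean better performance, -1 for losses (Hamming);
# the monotonicity chain is checked on orientation-adjusted values.
metric_orientation <- function(name) if (identical(name, "hamming")) -1 else 1

# normalise the user-facing `metrics` argument to a named list whose elements
# are builtin names (character) or functions of an evaluation_set
normalize_metrics <- function(metrics) {
  if (is.function(metrics)) metrics <- list(custom = metrics)
  if (is.character(metrics)) {
    bad <- setdiff(metrics, builtin_metric_names)
    if (length(bad))
      stop("unknown metric(s): ", paste(bad, collapse = ", "),
           "; available: ", paste(builtin_metric_names, collapse = ", "),
           call. = FALSE)
    metrics <- stats::setNames(as.list(metrics), metrics)
  }
  if (!is.list(metrics) || is.null(names(metrics)) ||
      any(!nzchar(names(metrics))))
    stop("metrics must be builtin names or a named list of functions",
         call. = FALSE)
  metrics
}

# fast scorer on a single instance given integer truth/prediction indices
singleton_scorer <- function(metric, catalog, config) {
  codes <- catalog$codes
  P <- length(codes)
  if (is.function(metric)) {
    f <- metric
    return(function(iy, iz) {
      es <- evaluation_set(list(codes[iy]), list(codes[iz]), catalog)
      f(es)
    })
  }
  s <- unname(config$significance)
  w <- config$similarity
  C <- config$contradiction
  any_contra <- any(C != 0)
  floor_n <- config$prevalence_floor
  inorm <- if (!is.null(catalog$normal_code))
    match(catalog$normal_code, codes) else NA_integer_

  counts <- function(iy, iz) {
    tp <- sum(match(iz, iy, 0L) > 0L)
    c(tp = tp, fp = length(iz) - tp, fn = length(iy) - tp)
  }

  switch(metric,
    medtric = function(iy, iz) {
      n_raw <- integer(P)
      n_raw[iy] <- 1L
      S <- sum(s[iy])
      t_i <- instance_total_idx(iy, iz, s, w, C, n_raw, floor_n, any_contra)
      (t_i + S) / (2 * S)
    },
    micro_precision = function(iy, iz) {
      k <- counts(iy, iz); safe_div(k["tp"], k["tp"] + k["fp"])[[1]]
    },
    micro_recall = function(iy, iz) {
      k <- counts(iy, iz); safe_div(k["tp"], k["tp"] + k["fn"])[[1]]
    },
    micro_f1 = function(iy, iz) {
      k <- counts(iy, iz)
      p <- safe_div(k["tp"], k["tp"] + k["fp"])
      r <- safe_div(k["tp"], k["tp"] + k["fn"])
      safe_div(2 * p * r, p + r)[[1]]
    },
    macro_precision = function(iy, iz) sum(match(iz, iy, 0L) > 0L) / P,
    macro_recall = function(iy, iz) sum(match(iz, iy, 0L) > 0L) / P,
    macro_f1 = function(iy, iz) sum(match(iz, iy, 0L) > 0L) / P,
    hamming = function(iy, iz) {
      tp <- sum(match(iz, iy, 0L) > 0L)
      (length(iy) + length(iz) - 2 * tp) / P
    },
    accuracy = function(iy, iz) {
      tp <- sum(match(iz, iy, 0L) > 0L)
      safe_div(tp, length(iy) + length(iz) - tp)
    },
    precision = function(iy, iz)
      safe_div(sum(match(iz, iy, 0L) > 0L), length(iz)),
    recall = function(iy, iz)
      safe_div(sum(match(iz, iy, 0L) > 0L), length(iy)),
    f1 = function(iy, iz)
      safe_div(2 * sum(match(iz, iy, 0L) > 0L), length(iy) + length(iz)),
    subset_accuracy = function(iy, iz)
      as.numeric(length(iy) == length(iz) &&
                   all(match(iz, iy, 0L) > 0L)),
    challenge_metric = {
      if (is.na(inorm))
        stop("challenge_metric needs a catalog with a normal class",
             call. = FALSE)
      function(iy, iz) {
        t_obs <- if (length(iz))
          sum(w[iy, iz]) / length(union(iy, iz)) else 0
        t_perf <- sum(w[iy, iy]) / length(iy)
        t_nsr <- sum(w[iy, inorm]) / length(union(iy, inorm))
        (t_obs - t_nsr) / (t_perf - t_nsr)
      }
    },
    stop("unknown builtin metric: ", metric, call. = FALSE)
  )
}

# evaluate the requested metrics on a full evaluation set, computing each
# metric family at most once
dataset_metric_values <- function(eval_set, config, metrics) {
  names_chr <- vapply(metrics, function(m)
    if (is.character(m)) m else "", character(1))
  lb <- eb <- NULL
  need <- function(fam) any(names_chr %in% fam)
  if (need(c("macro_precision", "macro_recall", "macro_f1",
             "micro_precision", "micro_recall", "micro_f1")))
    lb <- label_based(eval_set)
  if (need(c("hamming", "accuracy", "precision", "recall", "f1",
             "subset_accuracy")))
    eb <- example_based(eval_set)
  vapply(metrics, function(m) {
    if (is.function(m)) return(m(eval_set))
    switch(m,
      medtric = medtric(eval_set, config)$score,
      challenge_metric = challenge_metric(eval_set, config),
      if (m %in% names(lb)) lb[[m]] else eb[[m]])
  }, numeric(1))
}
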