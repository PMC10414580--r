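#' Metric configuration: significance, similarity, contradictions
#'
#' Bundles the domain-knowledge inputs of the clinically aligned score:
#' per-diagnosis significance weights `s_j > 0`, a similarity matrix `w` with
#' unit diagonal and off-diagonal entries strictly inside (0, 1) giving partial
#' credit for over-calling a condition clinically similar to a true one, and a
#' symmetric binary contradiction matrix `C` flagging pairs of diagnoses that
#' cannot co-occur (e.g. hypo- and hypertension).
#'
#' Scalars broadcast: a single `significance` value applies to every code, and
#' a single `similarity` value `w0` fills every off-diagonal entry. Because the
#' score is invariant to a common rescaling of the significance weights, they
#' are accepted raw and never renormalised internally.
#'
#' @param catalog A [diagnosis_catalog()].
#' @param significance Positive scalar or named numeric vector covering every
#'   catalog code.
#' @param similarity Scalar `w0` in (0, 1), or a P x P numeric matrix with unit
#'   diagonal and off-diagonal entries in (0, 1). Rows/columns follow catalog
#'   order (dimnames, when present, must match).
#' @param contradiction `NULL` (no contradictions), a list/2-column matrix of
#'   code pairs, or a full symmetric 0/1 P x P matrix with zero diagonal.
#' @param prevalence_floor Positive integer used in place of a zero prevalence
#'   count when a predicted code never occurs in any ground-truth set, keeping
#'   the contradiction penalty finite (and maximal) for such codes.
#' @return An object of class `metric_config` with elements `codes`,
#'   `significance` (named vector), `similarity`, `contradiction` (matrices
#'   with dimnames) and `prevalence_floor`.
#' @examples
#' cat3 <- diagnosis_catalog(c("hypo", "hyper", "normal"))
#' metric_config(cat3, contradiction = list(c("hypo", "hyper")))
#' @export
metric_config <- function(catalog, significance = 1, similarity = 0.5,
                          contradiction = NULL, prevalence_floor = 1L) {
  stopifnot(inherits(catalog, "diagnosis_catalog"))
  codes <- catalog$codes
  P <- length(codes)

  s <- expand_significance(significance, codes)
  w <- expand_similarity(similarity, codes)
  C <- expand_contradiction(contradiction, codes)

  prevalence_floor <- as.integer(prevalence_floor)
  if (length(prevalence_floor) != 1L || is.na(prevalence_floor) ||
      prevalence_floor < 1L)
    stop("prevalence_floor must be a positive integer", call. = FALSE)

  structure(list(codes = codes, significance = s, similarity = w,
                 contradiction = C, prevalence_floor = prevalence_floor),
            class = "metric_config")
}

expand_significance <- function(significance, codes) {
  if (is.null(names(significance))) {
    if (length(significance) == 1L) {
      s <- stats::setNames(rep(as.numeric(significance), length(codes)), codes)
    } else if (length(significance) == length(codes)) {
      s <- stats::setNames(as.numeric(significance), codes)
    } else {
      stop("significance must be a scalar, a vector of length P, ",
           "or a named vector", call. = FALSE)
    }
  } else {
    missing <- setdiff(codes, names(significance))
    if (length(missing))
      stop("significance missing for code(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    s <- stats::setNames(as.numeric(significance[codes]), codes)
  }
  if (anyNA(s) || any(s <= 0))
    stop("significance weights must all be > 0", call. = FALSE)
  s
}

expand_similarity <- function(similarity, codes) {
  P <- length(codes)
  if (is.matrix(similarity) || is.data.frame(similarity)) {
    w <- as.matrix(similarity)
    if (!all(dim(w) == c(P, P)))
      stop("similarity matrix must be ", P, " x ", P, call. = FALSE)
    if (!is.null(rownames(w))) {
      if (!setequal(rownames(w), codes) || !setequal(colnames(w), codes))
        stop("similarity matrix dimnames must match the catalog codes",
             call. = FALSE)
      w <- w[codes, codes]
    }
    storage.mode(w) <- "double"
  } else {
    if (length(similarity) != 1L || is.na(similarity))
      stop("similarity must be a scalar w0 or a full matrix", call. = FALSE)
    w0 <- as.numeric(similarity)
    if (P > 1L && (w0 <= 0 || w0 >= 1))
      stop("scalar similarity w0 must lie strictly inside (0, 1)",
           call. = FALSE)
    w <- matrix(w0, P, P)
    diag(w) <- 1
  }
  dimnames(w) <- list(codes, codes)
  if (any(abs(diag(w) - 1) > 0))
    stop("similarity matrix must have a unit diagonal", call. = FALSE)
  off <- w[row(w) != col(w)]
  if (length(off) && (any(is.na(off)) || any(off <= 0) || any(off >= 1)))
    stop("off-diagonal similarity entries must lie strictly inside (0, 1)",
         call. = FALSE)
  w
}

expand_contradiction <- function(contradiction, codes) {
  P <- length(codes)
  if (is.null(contradiction)) {
    C <- matrix(0, P, P)
  } else if (is.matrix(contradiction) && all(dim(contradiction) == c(P, P))) {
    C <- contradiction
    if (!is.null(rownames(C))) C <- C[codes, codes]
    storage.mode(C) <- "double"
  } else {
    # list of pairs, or a 2-column matrix/data.frame of code pairs
    if (is.data.frame(contradiction)) contradiction <- as.matrix(contradiction)
    if (is.matrix(contradiction)) {
      if (ncol(contradiction) != 2L)
        stop("contradiction pairs must have two columns", call. = FALSE)
      contradiction <- split(contradiction, seq_len(nrow(contradiction)))
    }
    C <- matrix(0, P, P, dimnames = list(codes, codes))
    for (pair in contradiction) {
      pair <- as.character(pair)
      if (length(pair) != 2L)
        stop("each contradiction entry must name exactly two codes",
             call. = FALSE)
      bad <- setdiff(pair, codes)
      if (length(bad))
        stop("contradiction pair names unknown code(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      if (pair[1] == pair[2])
        stop("a code cannot contradict itself: ", pair[1], call. = FALSE)
      C[pair[1], pair[2]] <- 1
      C[pair[2], pair[1]] <- 1
    }
  }
  dimnames(C) <- list(codes, codes)
  if (!all(C %in% c(0, 1)))
    stop("contradiction matrix entries must be 0 or 1", call. = FALSE)
  if (any(diag(C) != 0))
    stop("contradiction matrix must have a zero diagonal", call. = FALSE)
  if (!isTRUE(all.equal(C, t(C))))
    stop("contradiction matrix must be symmetric", call. = FALSE)
  C
}

#' @export
print.metric_config <- function(x, ...) {
  P <- length(x$codes)
  off <- x$similarity[row(x$similarity) != col(x$similarity)]
  cat("Metric configuration for", P, "codes\n")
  cat("  significance: ",
      if (length(unique(x$significance)) == 1L)
        paste0("uniform (", format(x$significance[[1]]), ")")
      else paste0("range [", format(min(x$significance)), ", ",
                  format(max(x$significance)), "]"), "\n", sep = "")
  cat("  similarity:   ",
      if (length(off) == 0L) "none (single class)"
      else if (length(unique(off)) == 1L)
        paste0("constant w0 = ", format(off[[1]]))
      else paste0("matrix, off-diagonal range [", format(min(off)), ", ",
                  format(max(off)), "]"), "\n", sep = "")
  cat("  contradictory pairs: ", sum(x$contradiction) / 2, "\n", sep = "")
  invisible(x)
}

# codes of truth sets must not contain a contradictory pair
check_truth_contradictions <- function(truth_list, config, ids) {
  if (all(config$contradiction == 0)) return(invisible(TRUE))
  for (i in seq_along(truth_list)) {
    y <- truth_list[[i]]
    if (length(y) < 2L) next
    sub <- config$contradiction[y, y, drop = FALSE]
    if (any(sub == 1)) {
      idx <- which(sub == 1, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "ground truth of instance '%s' contains contradictory codes %s and %s",
        ids[[i]], y[idx[1]], y[idx[2]]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
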