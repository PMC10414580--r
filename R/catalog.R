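#' Define a catalog of diagnosis codes
#'
#' A diagnosis catalog is the finite, ordered set of codes a diagnostic system
#' can emit. Every label set (ground truth or prediction) must draw from it.
#' One code may optionally be designated the "normal" (no-finding) class; this
#' is required by [challenge_metric()] and is how an absence of findings is
#' expressed, since empty ground-truth sets are rejected.
#'
#' @param codes Character vector of distinct, non-empty diagnosis identifiers.
#'   Their order fixes the row/column order of every matrix in a
#'   [metric_config()].
#' @param normal_code Optional single code in `codes` designating the normal
#'   ("no finding") class.
#' @return An object of class `diagnosis_catalog` with elements `codes` and
#'   `normal_code`.
#' @examples
#' cat3 <- diagnosis_catalog(c("CRBBB", "AF", "QAb"))
#' ecg <- diagnosis_catalog(c("NSR", "AF", "STach"), normal_code = "NSR")
#' @export
diagnosis_catalog <- function(codes, normal_code = NULL) {
  codes <- as.character(codes)
  if (length(codes) < 1L)
    stop("a diagnosis catalog needs at least one code", call. = FALSE)
  if (anyNA(codes) || any(!nzchar(codes)))
    stop("diagnosis codes must be non-empty strings", call. = FALSE)
  if (anyDuplicated(codes))
    stop("duplicate diagnosis codes: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(normal_code)) {
    normal_code <- as.character(normal_code)
    if (length(normal_code) != 1L || !(normal_code %in% codes))
      stop("normal_code must be a single member of the catalog", call. = FALSE)
  }
  structure(list(codes = codes, normal_code = normal_code),
            class = "diagnosis_catalog")
}

#' @export
print.diagnosis_catalog <- function(x, ...) {
  cat("Diagnosis catalog:", length(x$codes), "codes\n")
  cat(" ", paste(utils::head(x$codes, 12L), collapse = ", "),
      if (length(x$codes) > 12L) "..." else "", "\n")
  if (!is.null(x$normal_code)) cat("  normal class:", x$normal_code, "\n")
  invisible(x)
}

#' Generate a synthetic diagnosis catalog
#'
#' Convenience constructor for simulation studies: `n` generic codes
#' `"C01"`, `"C02"`, ... with no normal class.
#'
#' @param n Number of codes.
#' @param prefix Prefix for the generated identifiers.
#' @return A [diagnosis_catalog()].
#' @examples
#' synthetic_catalog(10)
#' @export
synthetic_catalog <- function(n = 10, prefix = "C") {
  diagnosis_catalog(sprintf("%s%02d", prefix, seq_len(n)))
}

# normalise a label set: de-duplicate, drop empties, keep character type
as_label_set <- function(x) {
  x <- as.character(x)
  x <- x[!is.na(x) & nzchar(x)]
  unique(x)
}

# check that all codes of a label set belong to the catalog
check_codes <- function(labels, catalog, what, id) {
  bad <- setdiff(labels, catalog$codes)
  if (length(bad))
    stop(sprintf("unknown code(s) %s in %s of instance '%s'",
                 paste(sQuote(bad), collapse = ", "), what, id),
         call. = FALSE)
  invisible(labels)
}
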