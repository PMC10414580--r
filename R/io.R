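#' Read labelled instance pairs from CSV or JSON
#'
#' CSV files need columns `instance_id`, `truth`, `prediction`, with label
#' sets written as pipe-separated code lists (`"CRBBB|AF|QAb"`); an empty
#' field is the empty set. JSON files hold an array of objects with keys
#' `id`, `truth`, `prediction` (arrays of codes). A UTF-8 byte-order mark and
#' surrounding whitespace are tolerated; duplicate codes within a field are
#' collapsed with a warning.
#'
#' @param path Path to the label file.
#' @param catalog A [diagnosis_catalog()]; every referenced code must belong
#'   to it.
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @return A list with elements `ids`, `truth`, `prediction`, ready for
#'   [evaluation_set()].
#' @seealso [read_evaluation_set()]
#' @export
read_label_file <- function(path, catalog, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (format == "json") {
    rows <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    ids <- vapply(rows, function(r) as.character(r$id), character(1))
    truth <- lapply(rows, function(r) trimws(unlist(r$truth)))
    prediction <- lapply(rows, function(r)
      trimws(unlist(r$prediction)))
  } else {
    df <- utils::read.csv(path, colClasses = "character",
                          fileEncoding = "UTF-8-BOM", strip.white = TRUE)
    needed <- c("instance_id", "truth", "prediction")
    missing <- setdiff(needed, names(df))
    if (length(missing))
      stop("label CSV is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    split_labels <- function(field, row, what) {
      out <- trimws(strsplit(trimws(field), "|", fixed = TRUE)[[1]])
      out <- out[nzchar(out)]
      if (anyDuplicated(out))
        warning(sprintf("line %d: duplicate code(s) in %s collapsed", row + 1L,
                        what), call. = FALSE)
      unique(out)
    }
    ids <- df$instance_id
    truth <- lapply(seq_len(nrow(df)), function(i)
      split_labels(df$truth[i], i, "truth"))
    prediction <- lapply(seq_len(nrow(df)), function(i)
      split_labels(df$prediction[i], i, "prediction"))
  }
  list(ids = ids, truth = truth, prediction = prediction)
}

#' Read a label file straight into a validated evaluation set
#'
#' @inheritParams read_label_file
#' @param config Optional [metric_config()] used to reject contradictory
#'   ground truths at load time.
#' @return An [evaluation_set()].
#' @export
read_evaluation_set <- function(path, catalog, config = NULL,
                                format = c("auto", "csv", "json")) {
  pairs <- read_label_file(path, catalog, format)
  evaluation_set(pairs$truth, pairs$prediction, catalog, ids = pairs$ids,
                 config = config)
}

#' Write instance pairs to a CSV label file
#'
#' Inverse of [read_label_file()]: one row per instance with pipe-separated
#' label sets. Reading the file back reproduces the pairs exactly.
#'
#' @param eval_set An [evaluation_set()] (or list with `ids`, `truth`,
#'   `prediction`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_file <- function(eval_set, path) {
  join <- function(sets) vapply(sets, paste, character(1), collapse = "|")
  df <- data.frame(instance_id = eval_set$ids,
                   truth = join(eval_set$truth),
                   prediction = join(eval_set$prediction),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Load a catalog and metric configuration from JSON or YAML
#'
#' The file must provide `codes` and may provide `normal_code`,
#' `significance` (scalar or map), `similarity` (scalar `w0` or full matrix),
#' `contradiction` (list of code pairs or full matrix) and `prevalence_floor`.
#' Scalar values broadcast as in [metric_config()].
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `catalog` and `config`.
#' @examples
#' tmp <- tempfile(fileext = ".json")
#' writeLines('{"codes": ["A", "B"], "significance": 1,
#'             "similarity": 0.5}', tmp)
#' cfg <- load_config(tmp)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(raw$codes))
    stop("config must list the catalog under 'codes'", call. = FALSE)
  catalog <- diagnosis_catalog(unlist(raw$codes),
                               normal_code = raw$normal_code)
  sig <- raw$significance
  if (is.list(sig)) sig <- unlist(sig)
  if (is.null(sig)) sig <- 1
  sim <- raw$similarity
  if (is.list(sim) && all(lengths(sim) == length(raw$codes)))
    sim <- do.call(rbind, sim)
  if (is.null(sim)) sim <- 0.5
  contra <- raw$contradiction
  config <- metric_config(catalog, significance = sig, similarity = sim,
                          contradiction = contra,
                          prevalence_floor = raw$prevalence_floor %||% 1L)
  list(catalog = catalog, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a machine-readable run report
#'
#' Serialises a report (scores, experiment results, seeds, configuration
#' echo) to JSON with deterministic field order and 12 significant digits, or
#' to CSV when the report is a flat named vector/list of numbers.
#'
#' @param report Named list (JSON) or named numeric vector / flat list (CSV).
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(12),
                         pretty = TRUE, null = "null")
  } else {
    vals <- unlist(report)
    df <- data.frame(field = names(vals), value = as.character(vals),
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

# strip an experiment_result down to plain lists for reporting
report_experiment <- function(x) {
  list(metric = x$metric, estimate = x$estimate,
       replicate_values = as.numeric(x$replicate_values),
       params = x$params[!vapply(x$params, is.null, logical(1))])
}
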