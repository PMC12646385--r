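#' Read a cohort from CSV plus JSON metadata sidecar
#'
#' The CSV is RFC-4180 with a header row; an empty field is a missing value.
#' The JSON sidecar is a list of objects
#' `{name, vtype, role, categories?, is_qi, is_parameter_of_interest}`
#' covering every column. Values are read as declared: categorical columns
#' become factors over the declared categories, continuous columns numeric.
#'
#' @param table_path Path to the CSV file.
#' @param metadata_path Path to the JSON metadata file.
#' @param dataset_id Optional dataset id; defaults to the id stored in the
#'   metadata file, or the CSV basename.
#' @return A validated [cohort()].
#' @export
read_cohort <- function(table_path, metadata_path, dataset_id = NULL) {
  md <- jsonlite::read_json(metadata_path, simplifyVector = FALSE)
  if (!is.null(md$variables)) {
    if (is.null(dataset_id)) dataset_id <- md$dataset_id
    vars <- md$variables
  } else vars <- md
  meta <- lapply(vars, function(v)
    variable_meta(v$name, v$vtype, v$role,
                  categories = if (!is.null(v$categories))
                    unlist(v$categories) else NULL,
                  is_qi = isTRUE(v$is_qi),
                  is_parameter_of_interest = isTRUE(v$is_parameter_of_interest)))
  if (is.null(dataset_id))
    dataset_id <- sub("\\.csv$", "", basename(table_path))
  tab <- utils::read.csv(table_path, colClasses = "character",
                         na.strings = "", check.names = FALSE)
  nm <- vapply(meta, `[[`, character(1), "name")
  if (!setequal(names(tab), nm))
    stop("column/metadata mismatch between '", table_path, "' and '",
         metadata_path, "'")
  cohort(tab[, nm, drop = FALSE], meta, dataset_id)
}

#' Write a cohort to CSV plus JSON metadata sidecar
#'
#' Lossless for the declared types: `read_cohort(write_cohort(x))` returns an
#' identical cohort. Missing cells are written as empty fields.
#'
#' @param x A [cohort()].
#' @param table_path CSV output path.
#' @param metadata_path JSON output path.
#' @return Invisibly, `c(table_path, metadata_path)`.
#' @export
write_cohort <- function(x, table_path, metadata_path) {
  validate_cohort(x)
  tab <- x$records
  for (j in seq_along(tab)) if (is.factor(tab[[j]]))
    tab[[j]] <- as.character(tab[[j]])
  utils::write.csv(tab, table_path, row.names = FALSE, na = "")
  md <- list(dataset_id = x$dataset_id,
             variables = lapply(unname(x$meta), function(m) {
               v <- list(name = m$name, vtype = m$vtype, role = m$role,
                         is_qi = m$is_qi,
                         is_parameter_of_interest = m$is_parameter_of_interest)
               if (!is.null(m$categories)) v$categories <- as.list(m$categories)
               v
             }))
  jsonlite::write_json(md, metadata_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(table_path, metadata_path))
}

#' Split a population into fixed train and holdout index sets
#'
#' Draws two disjoint random index sets of the requested sizes. The split is a
#' function of `(dataset_id, seed)` only — not of the variant — so all
#' population variants of one dataset share the same training and holdout
#' records, and varying the variable set never changes which records are used.
#'
#' @param x A [cohort()] (the population).
#' @param n_train,n_holdout Sizes of the two sets; their sum must not exceed
#'   the population size. Defaults mirror the study design (10 000 each,
#'   a 50:50 split of a 20 000-record population).
#' @param seed Master seed.
#' @return A list with integer vectors `train_ids` and `holdout_ids`
#'   (1-based row indices into `x$records`), class `train_holdout_split`.
#' @export
split_train_holdout <- function(x, n_train = 10000, n_holdout = 10000,
                                seed = 1) {
  n <- nrow(x$records)
  if (n_train + n_holdout > n)
    stop("n_train + n_holdout (", n_train + n_holdout,
         ") exceeds population size (", n, ")")
  idx <- with_seed(derive_seed(seed, "split", x$dataset_id), sample.int(n))
  structure(list(train_ids = sort(idx[seq_len(n_train)]),
                 holdout_ids = sort(idx[n_train + seq_len(n_holdout)])),
            class = "train_holdout_split")
}

#' Read or write a long-format metric table
#'
#' The metric table is the long-format record of every evaluation: one row
#' per (dataset, generator, variant, adjunct count, metric, replicate) with
#' the metric value. It is the input to [fit_metric_effect()].
#'
#' @param metrics A data.frame with columns `dataset_id, generator_id,
#'   variant_id, k_adjunct, metric_name, replicate, value`.
#' @param path CSV path.
#' @return `read_metric_table` returns the data.frame; `write_metric_table`
#'   the path, invisibly.
#' @export
write_metric_table <- function(metrics, path) {
  stopifnot(all(c("dataset_id", "generator_id", "k_adjunct",
                  "metric_name", "value") %in% names(metrics)))
  utils::write.csv(metrics, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  utils::read.csv(path, na.strings = "", check.names = FALSE,
                  stringsAsFactors = FALSE)
}

# One metric-table row (list form, rbind-ed by callers).
metric_record <- function(dataset_id, generator_id, variant_id, k_adjunct,
                          metric_name, replicate, value) {
  data.frame(dataset_id = dataset_id, generator_id = generator_id,
             variant_id = variant_id, k_adjunct = k_adjunct,
             metric_name = metric_name, replicate = replicate,
             value = value, stringsAsFactors = FALSE)
}
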