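#' Variable metadata
#'
#' Describes one column of a [cohort()]: its measurement type, its role in the
#' downstream task, and two analysis flags. Roles follow the core/adjunct
#' split: `core_predictor` variables (plus the single binary `outcome`) are the
#' ones the predefined downstream task needs; `adjunct` variables are present
#' in the source data but task-irrelevant.
#'
#' @param name Column name (unique within a cohort).
#' @param vtype `"categorical"` or `"continuous"`.
#' @param role `"core_predictor"`, `"outcome"`, or `"adjunct"`.
#' @param categories Character vector of declared categories (categorical
#'   variables only; required for those).
#' @param is_qi Is the variable a quasi-identifier, i.e. plausibly part of an
#'   adversary's background knowledge?
#' @param is_parameter_of_interest Is this core predictor the inferential
#'   parameter of interest of the downstream logistic model?
#' @return An object of class `variable_meta`.
#' @export
variable_meta <- function(name, vtype, role, categories = NULL,
                          is_qi = FALSE, is_parameter_of_interest = FALSE) {
  vtype <- match.arg(vtype, c("categorical", "continuous"))
  role <- match.arg(role, c("core_predictor", "outcome", "adjunct"))
  if (vtype == "categorical") {
    if (is.null(categories) || length(categories) < 1L)
      stop("categorical variable '", name, "' needs declared categories")
    categories <- as.character(categories)
  } else if (!is.null(categories)) {
    stop("continuous variable '", name, "' must not declare categories")
  }
  structure(list(name = as.character(name), vtype = vtype, role = role,
                 categories = categories, is_qi = isTRUE(is_qi),
                 is_parameter_of_interest = isTRUE(is_parameter_of_interest)),
            class = "variable_meta")
}

#' Assemble a cohort
#'
#' A cohort is the universal currency of the pipeline: a rectangular table of
#' records plus one [variable_meta()] per column and a dataset identifier.
#' Missing values are represented uniformly as `NA` in memory (empty fields on
#' disk). Categorical columns are stored as factors over their declared
#' categories, so a category literally named `"0"` never collides with the
#' number 0 in a continuous column.
#'
#' @param records A data.frame of records.
#' @param meta A list of [variable_meta()], one per column, same order.
#' @param dataset_id Identifier string.
#' @return An object of class `cohort`.
#' @export
cohort <- function(records, meta, dataset_id = "cohort") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(is.list(meta))
  meta <- lapply(meta, function(m) {
    if (!inherits(m, "variable_meta")) do.call(variable_meta, m) else m
  })
  names(meta) <- vapply(meta, `[[`, character(1), "name")
  for (m in meta) {
    if (m$vtype == "categorical" && m$name %in% names(records)) {
      x <- as.character(records[[m$name]])
      bad <- !is.na(x) & !(x %in% m$categories)
      if (any(bad))
        stop("column '", m$name, "' contains undeclared categories: ",
             paste(unique(x[bad]), collapse = ", "))
      records[[m$name]] <- factor(x, levels = m$categories)
    } else if (m$name %in% names(records)) {
      records[[m$name]] <- as.numeric(records[[m$name]])
    }
  }
  obj <- structure(list(records = records, meta = meta,
                        dataset_id = as.character(dataset_id)),
                   class = "cohort")
  validate_cohort(obj)
  obj
}

#' Validate cohort invariants
#'
#' Checks that every column has metadata (and vice versa), names are unique,
#' exactly one variable has the outcome role and is binary categorical, at
#' most one variable is flagged parameter-of-interest (and is a core
#' predictor), categorical columns contain only declared categories or
#' missing, and there is at least one record.
#'
#' @param x A `cohort`.
#' @return `x`, invisibly; stops with a descriptive error on violation.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  nm_rec <- names(x$records)
  nm_meta <- vapply(x$meta, `[[`, character(1), "name")
  if (anyDuplicated(nm_meta)) stop("duplicate variable names in metadata")
  if (!setequal(nm_rec, nm_meta) || length(nm_rec) != length(nm_meta))
    stop("column/metadata mismatch: records have [",
         paste(setdiff(nm_rec, nm_meta), collapse = ", "),
         "] not in metadata; metadata has [",
         paste(setdiff(nm_meta, nm_rec), collapse = ", "), "] not in records")
  if (nrow(x$records) < 1L) stop("cohort must contain at least one record")
  roles <- vapply(x$meta, `[[`, character(1), "role")
  out <- which(roles == "outcome")
  if (length(out) != 1L)
    stop("exactly one variable must have role 'outcome' (found ",
         length(out), ")")
  om <- x$meta[[out]]
  if (om$vtype != "categorical" || length(om$categories) != 2L)
    stop("outcome variable '", om$name,
         "' must be binary categorical (2 declared categories)")
  poi <- vapply(x$meta, `[[`, logical(1), "is_parameter_of_interest")
  if (sum(poi) > 1L) stop("at most one parameter-of-interest variable allowed")
  if (any(poi & roles != "core_predictor"))
    stop("parameter of interest must be a core predictor")
  for (m in x$meta) {
    if (m$vtype == "categorical") {
      v <- x$records[[m$name]]
      bad <- !is.na(v) & !(as.character(v) %in% m$categories)
      if (any(bad))
        stop("column '", m$name, "' contains undeclared categories: ",
             paste(unique(as.character(v)[bad]), collapse = ", "))
    }
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  roles <- vapply(x$meta, `[[`, character(1), "role")
  cat("<cohort '", x$dataset_id, "'> ", nrow(x$records), " records x ",
      length(x$meta), " variables (",
      sum(roles == "core_predictor"), " core predictors, ",
      sum(roles == "adjunct"), " adjunct, 1 outcome)\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$records)

# --- role helpers ----------------------------------------------------------

cohort_roles <- function(x) vapply(x$meta, `[[`, character(1), "role")

#' Names of variables by role
#'
#' @param x A `cohort`.
#' @return Character vector of column names.
#' @export
core_names <- function(x) {
  r <- cohort_roles(x)
  names(r)[r == "core_predictor"]
}

#' @rdname core_names
#' @export
adjunct_names <- function(x) {
  r <- cohort_roles(x)
  names(r)[r == "adjunct"]
}

#' @rdname core_names
#' @export
outcome_name <- function(x) {
  r <- cohort_roles(x)
  names(r)[r == "outcome"]
}

#' @rdname core_names
#' @export
qi_names <- function(x) {
  q <- vapply(x$meta, `[[`, logical(1), "is_qi")
  names(x$meta)[q]
}

# Restrict a cohort to a subset of columns (outcome handled by caller).
select_cohort <- function(x, cols) {
  missing_cols <- setdiff(cols, names(x$records))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  cohort(x$records[, cols, drop = FALSE], x$meta[cols], x$dataset_id)
}

# Subset rows without re-validating column contents.
subset_rows <- function(x, idx) {
  y <- x
  y$records <- x$records[idx, , drop = FALSE]
  rownames(y$records) <- NULL
  y
}
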