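#' Pairwise normalized mutual information report
#'
#' Computes NMI for every pair of variables in a cohort (including
#' self-pairs), labelling each pair core-to-core, core-to-adjunct, or
#' adjunct-to-adjunct. This is the diagnostic used to characterize how much
#' of a core variable's information is carried by other variables — whether
#' adjuncts are redundant with the core or independent of it.
#'
#' Continuous variables are discretized into `n_bins` equal-frequency bins.
#' NMI is computed from the empirical joint over pairwise-complete
#' observations, normalized by the geometric mean of the marginal entropies:
#' `NMI(X, Y) = I(X; Y) / sqrt(H(X) H(Y))`, which lies in `[0, 1]`, equals 1
#' for any bijective relabeling, and is symmetric. A constant variable has
#' zero entropy; its NMI against anything is defined as 0 (with a warning).
#'
#' @param x A [cohort()] with at least 2 variables.
#' @param n_bins Number of equal-frequency bins for continuous variables.
#' @return A data.frame of class `nmi_report` with columns `var_i`, `var_j`,
#'   `group`, `nmi`.
#' @export
pairwise_nmi <- function(x, n_bins = 10) {
  validate_cohort(x)
  nm_all <- names(x$records)
  if (length(nm_all) < 2) stop("need at least 2 variables")
  roles <- cohort_roles(x)
  disc <- lapply(nm_all, function(nm) {
    v <- x$records[[nm]]
    if (x$meta[[nm]]$vtype == "continuous") quantile_bins(as.numeric(v), n_bins)
    else factor(as.character(v), levels = x$meta[[nm]]$categories)
  })
  names(disc) <- nm_all
  ent <- vapply(disc, function(f) {
    tb <- table(f); tb <- tb[tb > 0]
    if (!sum(tb)) return(0)
    p <- tb / sum(tb)
    -sum(p * log(p))
  }, numeric(1))
  if (any(ent == 0))
    warning("constant variable(s): ",
            paste(nm_all[ent == 0], collapse = ", "),
            "; NMI against them is defined as 0")
  grp <- function(a, b) {
    ra <- if (roles[a] == "adjunct") "adjunct" else "core"
    rb <- if (roles[b] == "adjunct") "adjunct" else "core"
    paste(sort(c(ra, rb), decreasing = TRUE), collapse = "_")
  }
  rows <- list()
  for (i in seq_along(nm_all)) for (j in i:length(nm_all)) {
    a <- nm_all[i]; b <- nm_all[j]
    val <- if (ent[i] == 0 || ent[j] == 0) 0
      else if (i == j) 1
      else {
        ok <- !is.na(disc[[a]]) & !is.na(disc[[b]])
        mi <- discrete_mi(droplevels(disc[[a]][ok]), droplevels(disc[[b]][ok]))
        ha <- entropy_of(disc[[a]][ok]); hb <- entropy_of(disc[[b]][ok])
        if (ha == 0 || hb == 0) 0 else min(1, mi / sqrt(ha * hb))
      }
    rows[[length(rows) + 1L]] <-
      data.frame(var_i = a, var_j = b, group = grp(a, b), nmi = val,
                 stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows), class = c("nmi_report", "data.frame"))
}

entropy_of <- function(f) {
  tb <- table(f); tb <- tb[tb > 0]
  if (!sum(tb)) return(0)
  p <- tb / sum(tb)
  -sum(p * log(p))
}

#' Look up one pair's NMI in a report
#'
#' @param report An `nmi_report`.
#' @param a,b Variable names (order-insensitive).
#' @return The NMI value.
#' @export
nmi_value <- function(report, a, b) {
  hit <- (report$var_i == a & report$var_j == b) |
    (report$var_i == b & report$var_j == a)
  if (!any(hit)) stop("pair not found: ", a, ", ", b)
  report$nmi[which(hit)[1]]
}
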