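#' Cluster-based fidelity between a real and a synthetic cohort
#'
#' Pools the real and synthetic records, clusters them, and measures how far
#' the real-record fraction of each cluster deviates from the overall real
#' fraction `c`. With cluster weights `w_j = n_j / n`, the raw statistic is
#' `U = sum_j w_j (p_j - c)^2` where `p_j` is the real fraction in cluster
#' `j`. `U` is 0 under perfect mixing and attains its maximum `c (1 - c)`
#' when every cluster is purely real or purely synthetic, so
#' `score = 1 - U / (c (1 - c))` lies in `[0, 1]` with 1 = maximum fidelity.
#'
#' Records are encoded before clustering: categoricals one-hot, continuous
#' standardized by pooled mean/sd, and missing values replaced by the pooled
#' mean with a companion missingness indicator column. k-means runs with a
#' fixed seed and 10 restarts for a deterministic score.
#'
#' @param real,synthetic [cohort()]s with the same schema. Fidelity is
#'   conventionally evaluated on the projected core subset
#'   ([project_core()]); the caller chooses the projection.
#' @param G Number of clusters (default 20).
#' @param seed Seed for k-means initialization.
#' @param assignments Optional precomputed integer cluster assignment for the
#'   pooled rows (real first), bypassing k-means — used for hand-constructed
#'   checks.
#' @return A list of class `cluster_fidelity_result` with `score`,
#'   `n_clusters`, `raw_statistic` (U) and `real_fraction` (c).
#' @export
cluster_fidelity <- function(real, synthetic, G = 20, seed = 1,
                             assignments = NULL) {
  if (!setequal(names(real$records), names(synthetic$records)))
    stop("real and synthetic cohorts must share a schema")
  n_r <- nrow(real$records); n_s <- nrow(synthetic$records)
  if (n_r < 1 || n_s < 1) stop("both cohorts must be nonempty")
  n <- n_r + n_s
  cc <- n_r / n
  if (is.null(assignments)) {
    if (G < 2) stop("G must be at least 2")
    if (G > n) stop("G exceeds the pooled number of rows")
    X <- encode_numeric(rbind_records(real, synthetic), real$meta)
    km <- with_seed(derive_seed(seed, "fidelity"),
                    stats::kmeans(X, centers = G, nstart = 10,
                                  iter.max = 50))
    assignments <- km$cluster
  } else {
    stopifnot(length(assignments) == n)
    G <- length(unique(assignments))
  }
  is_real <- c(rep(TRUE, n_r), rep(FALSE, n_s))
  nj <- tapply(rep(1, n), assignments, sum)
  pj <- tapply(is_real, assignments, mean)
  U <- sum((nj / n) * (pj - cc)^2)
  score <- 1 - U / (cc * (1 - cc))
  structure(list(score = score, n_clusters = G, raw_statistic = U,
                 real_fraction = cc),
            class = "cluster_fidelity_result")
}

#' Mean cluster fidelity over a synthetic ensemble
#'
#' @param real Real comparison [cohort()].
#' @param ensemble A `synthetic_ensemble`.
#' @param G,seed As in [cluster_fidelity()].
#' @param core_only Project both sides to core columns first (the
#'   conventional evaluation scope)?
#' @return List with `mean_score` and `per_replicate` scores.
#' @export
ensemble_fidelity <- function(real, ensemble, G = 20, seed = 1,
                              core_only = TRUE) {
  if (core_only) real <- project_core(real)
  scores <- vapply(seq_along(ensemble$replicates), function(r) {
    syn <- ensemble$replicates[[r]]
    if (core_only) syn <- project_core(syn)
    cluster_fidelity(real, syn, G = G,
                     seed = derive_seed(seed, "fid", r))$score
  }, numeric(1))
  list(mean_score = mean(scores), per_replicate = scores)
}

# Stack two cohorts' records (same columns, real first).
rbind_records <- function(a, b) {
  cols <- names(a$records)
  rbind(a$records[, cols, drop = FALSE], b$records[, cols, drop = FALSE])
}

# Numeric design matrix: one-hot categoricals, standardized continuous,
# missing -> mean fill + indicator column.
encode_numeric <- function(records, meta) {
  out <- list()
  for (nm in names(records)) {
    v <- records[[nm]]
    m <- meta[[nm]]
    if (!is.null(m) && m$vtype == "categorical") {
      v <- factor(as.character(v), levels = m$categories)
      for (lev in m$categories)
        out[[paste0(nm, "=", lev)]] <- as.numeric(!is.na(v) & v == lev)
      if (anyNA(v)) out[[paste0(nm, "=NA")]] <- as.numeric(is.na(v))
    } else {
      v <- as.numeric(v)
      if (anyNA(v)) {
        out[[paste0(nm, "__NA")]] <- as.numeric(is.na(v))
        v[is.na(v)] <- mean(v, na.rm = TRUE)
      }
      s <- stats::sd(v)
      out[[nm]] <- if (is.na(s) || s < 1e-12) v - mean(v)
        else (v - mean(v)) / s
    }
  }
  do.call(cbind, out)
}
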