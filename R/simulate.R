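#' Specify a simulated medical-style cohort
#'
#' Describes a cross-sectional cohort with known ground truth, emulating the
#' structural features of tabular medical datasets: mixed
#' categorical/continuous variables, a binary outcome with configurable class
#' imbalance (from roughly balanced down to 99:1), a pool of task-irrelevant
#' adjunct variables that are either statistically independent of the core or
#' redundant with it, missing values, and flagged quasi-identifiers.
#'
#' Dependence is driven by a Gaussian copula: core predictors arise from
#' latent standard normals with correlation matrix `latent_correlation`; a
#' configurable fraction of them is discretized into categoricals by quantile
#' thresholds (2-5 bins). The binary outcome follows a logistic model on the
#' latent core values, with the intercept calibrated so the marginal
#' prevalence matches `outcome_prevalence`. Adjunct variables are generated
#' per-mode: `independent` (fresh noise, unrelated to the core), `redundant`
#' (a noisy copy of one core latent), or `informative` (a noisy linear
#' combination of core latents). Missingness is MCAR on non-outcome columns.
#'
#' @param n_records Number of records.
#' @param n_core_predictors Number of core predictors (medical datasets in
#'   this setting typically carry 6-20 core variables).
#' @param adjunct_pool_size Size of the adjunct pool `m`.
#' @param outcome_prevalence Marginal prevalence of the positive outcome
#'   class, in (0, 1).
#' @param beta Logistic coefficients on the latent core predictors; recycled
#'   to length `n_core_predictors`.
#' @param latent_correlation Correlation matrix of the core latents (unit
#'   diagonal, positive semi-definite). Default: exchangeable with
#'   correlation `rho`.
#' @param rho Exchangeable latent correlation used when `latent_correlation`
#'   is not supplied.
#' @param adjunct_modes List of per-adjunct mode descriptors, each
#'   `list(mode = "independent")`,
#'   `list(mode = "redundant", source = <core index>, sd = <noise sd>)`, or
#'   `list(mode = "informative", weights = <vector>, sd = <noise sd>)`.
#'   Default: alternating redundant (noise sd 0.5) and independent adjuncts,
#'   mirroring the observation that real adjunct variables are sometimes
#'   strongly and sometimes barely related to the core.
#' @param categorical_fraction Fraction of predictors (core and adjunct)
#'   discretized into categoricals.
#' @param missing_rate MCAR missingness probability on non-outcome columns.
#' @param qi_count Number of variables flagged as quasi-identifiers (the
#'   first `qi_count` non-outcome columns).
#' @param n_bins_range Integer range of quantile-bin counts used when
#'   discretizing a latent into a categorical.
#' @param seed Seed for the cohort draw.
#' @param dataset_id Identifier of the simulated dataset.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_records = 20000, n_core_predictors = 10,
                        adjunct_pool_size = 8, outcome_prevalence = 0.3,
                        beta = c(1, -0.5), latent_correlation = NULL,
                        rho = 0.3, adjunct_modes = NULL,
                        categorical_fraction = 0.5, missing_rate = 0.05,
                        qi_count = 4, n_bins_range = 2:5, seed = 1,
                        dataset_id = "sim") {
  p <- n_core_predictors
  stopifnot(p >= 1, adjunct_pool_size >= 0,
            outcome_prevalence > 0, outcome_prevalence < 1,
            missing_rate >= 0, missing_rate < 1)
  beta <- rep_len(as.numeric(beta), p)
  if (is.null(latent_correlation)) {
    latent_correlation <- matrix(rho, p, p)
    diag(latent_correlation) <- 1
  }
  R <- as.matrix(latent_correlation)
  if (nrow(R) != p || ncol(R) != p) stop("latent_correlation must be p x p")
  if (max(abs(R - t(R))) > 1e-8) stop("latent_correlation must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-8)) stop("latent_correlation needs unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("latent_correlation is not positive semi-definite")
  if (is.null(adjunct_modes) && adjunct_pool_size > 0) {
    adjunct_modes <- lapply(seq_len(adjunct_pool_size), function(j) {
      if (j %% 2L == 1L)
        list(mode = "redundant", source = ((j - 1L) %/% 2L) %% p + 1L, sd = 0.5)
      else list(mode = "independent")
    })
  }
  if (adjunct_pool_size == 0) adjunct_modes <- list()
  stopifnot(length(adjunct_modes) == adjunct_pool_size)
  structure(list(n_records = n_records, n_core_predictors = p,
                 adjunct_pool_size = adjunct_pool_size,
                 outcome_prevalence = outcome_prevalence, beta = beta,
                 latent_correlation = R, adjunct_modes = adjunct_modes,
                 categorical_fraction = categorical_fraction,
                 missing_rate = missing_rate, qi_count = qi_count,
                 n_bins_range = as.integer(n_bins_range), seed = seed,
                 dataset_id = dataset_id),
            class = "cohort_spec")
}

#' Calibrate the logistic intercept for a target prevalence
#'
#' With latent core predictors `Z ~ N(0, R)` and linear predictor
#' `c + beta' Z`, the marginal outcome prevalence is
#' `E[plogis(c + s W)]` where `W ~ N(0,1)` and `s^2 = beta' R beta`.
#' The intercept `c` solving prevalence = `pi` is found by monotone
#' root-finding on that one-dimensional Gaussian integral.
#'
#' @param beta Coefficient vector.
#' @param R Latent correlation matrix (defaults to identity).
#' @param prevalence Target marginal prevalence in (0, 1).
#' @return The calibrated intercept (scalar).
#' @examples
#' calibrate_intercept(c(0, 0), prevalence = 0.5)  # 0 by symmetry
#' @export
calibrate_intercept <- function(beta, R = diag(length(beta)),
                                prevalence) {
  stopifnot(prevalence > 0, prevalence < 1)
  beta <- as.numeric(beta)
  s <- sqrt(max(0, drop(t(beta) %*% R %*% beta)))
  if (s < 1e-12) return(stats::qlogis(prevalence))
  marg <- function(c0)
    stats::integrate(function(w) stats::plogis(c0 + s * w) * stats::dnorm(w),
                     -Inf, Inf, rel.tol = 1e-10)$value - prevalence
  lo <- stats::qlogis(prevalence) - 5 * s - 5
  hi <- stats::qlogis(prevalence) + 5 * s + 5
  if (marg(lo) > 0 || marg(hi) < 0)
    stop("no bracketing interval found for intercept calibration")
  stats::uniroot(marg, c(lo, hi), tol = 1e-9)$root
}

# Quantile-discretize a numeric vector into `k` roughly equal-frequency
# labelled bins; returns a factor with levels "b1".."bk".
quantile_bins <- function(x, k) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = k + 1),
                        na.rm = TRUE, names = FALSE)
  qs[1] <- -Inf; qs[k + 1] <- Inf
  qs <- unique(qs)
  cut(x, breaks = qs, labels = paste0("b", seq_len(length(qs) - 1L)),
      include.lowest = TRUE)
}

#' Simulate a cohort with known ground truth
#'
#' Draws one cohort according to a [cohort_spec()]. The returned ground truth
#' records the generating logistic coefficients, the calibrated intercept,
#' the target prevalence, and the declared parameter of interest (the first
#' continuous core predictor), enabling parameter-recovery checks downstream.
#'
#' Identical spec (including seed) always yields a bit-identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `cohort` (a [cohort()]) and `ground_truth`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- spec$n_core_predictors; m <- spec$adjunct_pool_size
  n <- spec$n_records
  with_seed(derive_seed(spec$seed, "simulate", spec$dataset_id), {
    L <- chol(spec$latent_correlation + diag(1e-10, p))
    Z <- matrix(stats::rnorm(n * p), n, p) %*% L
    colnames(Z) <- paste0("x", seq_len(p))

    intercept <- calibrate_intercept(spec$beta, spec$latent_correlation,
                                     spec$outcome_prevalence)
    eta <- intercept + drop(Z %*% spec$beta)
    y <- stats::rbinom(n, 1L, stats::plogis(eta))

    # which predictors get discretized: the trailing fraction, so x1 (the
    # parameter of interest) stays continuous whenever any predictor does
    n_cat_core <- round(spec$categorical_fraction * p)
    cat_core <- if (n_cat_core > 0) (p - n_cat_core + 1L):p else integer(0)

    records <- as.data.frame(Z)
    meta <- vector("list", p)
    for (j in seq_len(p)) {
      nm <- colnames(Z)[j]
      if (j %in% cat_core) {
        k <- spec$n_bins_range[(j - 1L) %% length(spec$n_bins_range) + 1L]
        f <- quantile_bins(Z[, j], k)
        records[[nm]] <- f
        meta[[j]] <- variable_meta(nm, "categorical", "core_predictor",
                                   categories = levels(f))
      } else {
        meta[[j]] <- variable_meta(nm, "continuous", "core_predictor")
      }
    }
    poi_idx <- if (length(cat_core) < p) setdiff(seq_len(p), cat_core)[1] else NA
    if (!is.na(poi_idx)) meta[[poi_idx]]$is_parameter_of_interest <- TRUE

    # adjunct columns
    if (m > 0) {
      n_cat_adj <- round(spec$categorical_fraction * m)
      cat_adj <- if (n_cat_adj > 0) (m - n_cat_adj + 1L):m else integer(0)
      for (j in seq_len(m)) {
        mode <- spec$adjunct_modes[[j]]
        nm <- paste0("a", j)
        v <- switch(mode$mode,
          independent = stats::rnorm(n),
          redundant = Z[, mode$source] + stats::rnorm(n, 0, mode$sd),
          informative = drop(Z %*% rep_len(mode$weights, p)) +
            stats::rnorm(n, 0, mode$sd),
          stop("unknown adjunct mode: ", mode$mode))
        if (j %in% cat_adj) {
          k <- spec$n_bins_range[(j - 1L) %% length(spec$n_bins_range) + 1L]
          f <- quantile_bins(v, k)
          records[[nm]] <- f
          meta <- c(meta, list(variable_meta(nm, "categorical", "adjunct",
                                             categories = levels(f))))
        } else {
          records[[nm]] <- v
          meta <- c(meta, list(variable_meta(nm, "continuous", "adjunct")))
        }
      }
    }

    records$outcome <- factor(as.character(y), levels = c("0", "1"))
    meta <- c(meta, list(variable_meta("outcome", "categorical", "outcome",
                                       categories = c("0", "1"))))

    # MCAR missingness on non-outcome columns
    if (spec$missing_rate > 0) {
      for (nm in setdiff(names(records), "outcome")) {
        blank <- stats::runif(n) < spec$missing_rate
        records[[nm]][blank] <- NA
      }
    }

    # flag quasi-identifiers: first qi_count non-outcome variables
    n_qi <- min(spec$qi_count, length(meta) - 1L)
    non_out <- which(vapply(meta, `[[`, character(1), "role") != "outcome")
    for (j in non_out[seq_len(n_qi)]) meta[[j]]$is_qi <- TRUE

    gt <- list(beta = spec$beta, intercept = intercept,
               prevalence = spec$outcome_prevalence,
               parameter_of_interest =
                 if (!is.na(poi_idx)) colnames(Z)[poi_idx] else NA_character_,
               parameter_of_interest_coef =
                 if (!is.na(poi_idx)) spec$beta[poi_idx] else NA_real_)
    list(cohort = cohort(records, meta, spec$dataset_id), ground_truth = gt)
  })
}
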