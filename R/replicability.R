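#' Point estimate with standard error and confidence interval
#'
#' @param estimate Point estimate.
#' @param standard_error Standard error (nonnegative).
#' @param alpha Two-sided significance level (default 0.05).
#' @param df Degrees of freedom for the interval quantile (`Inf` = normal).
#' @param ci_low,ci_high Optional explicit bounds; computed from the SE and
#'   quantile when omitted.
#' @return An `estimate_ci` list.
#' @export
estimate_ci <- function(estimate, standard_error, alpha = 0.05, df = Inf,
                        ci_low = NULL, ci_high = NULL) {
  stopifnot(standard_error >= 0, alpha > 0, alpha < 1)
  q <- if (is.finite(df)) stats::qt(1 - alpha / 2, df)
    else stats::qnorm(1 - alpha / 2)
  if (is.null(ci_low)) ci_low <- estimate - q * standard_error
  if (is.null(ci_high)) ci_high <- estimate + q * standard_error
  if (ci_low > estimate || ci_high < estimate)
    stop("confidence interval must contain the estimate")
  structure(list(estimate = estimate, standard_error = standard_error,
                 ci_low = ci_low, ci_high = ci_high, alpha = alpha, df = df),
            class = "estimate_ci")
}

#' Logistic-regression estimate of the parameter of interest
#'
#' Fits a maximum-likelihood logistic model of the binary outcome on the
#' given predictors and returns the flagged coefficient with its Wald
#' standard error and two-sided confidence interval. Non-convergence and
#' (quasi-)complete separation are reported as a distinguishable condition
#' (`logistic_fit_error`), so callers can record the replicate as missing
#' rather than silently using a degenerate fit.
#'
#' @param x A [cohort()].
#' @param predictors Predictor column names (default: core predictors).
#' @param parameter_of_interest Name of the coefficient to report; for a
#'   categorical predictor this is the name of its first non-reference dummy.
#'   Default: the cohort's flagged parameter-of-interest variable.
#' @param alpha Significance level (default 0.05).
#' @return An [estimate_ci()].
#' @export
fit_logistic_estimate <- function(x, predictors = NULL,
                                  parameter_of_interest = NULL,
                                  alpha = 0.05) {
  validate_cohort(x)
  if (is.null(predictors)) predictors <- core_names(x)
  if (is.null(parameter_of_interest)) {
    poi <- vapply(x$meta, `[[`, logical(1), "is_parameter_of_interest")
    if (!any(poi)) stop("no parameter of interest flagged")
    parameter_of_interest <- names(x$meta)[poi][1]
  }
  if (!parameter_of_interest %in% predictors)
    stop("parameter of interest must be among the predictors")
  y <- outcome01(x)
  if (length(unique(y)) < 2)
    stop(errorCondition("outcome is constant; logistic fit impossible",
                        class = "logistic_fit_error"))
  df <- x$records[, predictors, drop = FALSE]
  df <- droplevels(df)
  df$.y <- y
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                     family = stats::binomial()))
  co <- summary(fit)$coefficients
  hit <- grep(paste0("^", parameter_of_interest), rownames(co))
  if (!length(hit))
    stop(errorCondition(paste0("coefficient for '", parameter_of_interest,
                               "' dropped from the fit"),
                        class = "logistic_fit_error"))
  est <- co[hit[1], "Estimate"]; se <- co[hit[1], "Std. Error"]
  if (!fit$converged || !is.finite(est) || !is.finite(se) ||
      abs(est) > 25 || se > 100)
    stop(errorCondition(
      "logistic fit did not converge (possible complete separation)",
      class = "logistic_fit_error"))
  estimate_ci(est, se, alpha = alpha)
}

#' Combine estimates across synthetic replicates
#'
#' Multiple-imputation-style pooling of the per-replicate estimates: with
#' `m` replicates, the pooled estimate is the mean `q_bar`; the
#' within-replicate variance `w_bar` is the mean squared SE; the
#' between-replicate variance `b` is the sample variance of the estimates
#' (0 when `m = 1`); total variance `T = w_bar + b/m` (partial-synthesis
#' form), `SE = sqrt(T)`. The interval uses a t quantile with
#' Barnard-Rubin-style degrees of freedom
#' `nu = (m - 1) (1 + w_bar / (b/m))^2`, infinite when `b = 0`.
#'
#' An alternative fully-synthetic variance rule `T = (1 + 1/m) b - w_bar`
#' (floored at `w_bar`) is available via `rule = "full"`.
#'
#' @param estimates List of [estimate_ci()]s, one per replicate (`m >= 1`).
#' @param alpha Significance level of the combined interval.
#' @param rule `"partial"` (default) or `"full"` variance rule.
#' @return A combined [estimate_ci()].
#' @export
combine_estimates <- function(estimates, alpha = 0.05,
                              rule = c("partial", "full")) {
  rule <- match.arg(rule)
  estimates <- estimates[!vapply(estimates, is.null, logical(1))]
  m <- length(estimates)
  if (m == 0) stop("no estimates to combine")
  qs <- vapply(estimates, `[[`, numeric(1), "estimate")
  ses <- vapply(estimates, `[[`, numeric(1), "standard_error")
  q_bar <- mean(qs)
  w_bar <- mean(ses^2)
  b <- if (m > 1) stats::var(qs) else 0
  Tvar <- switch(rule,
                 partial = w_bar + b / m,
                 full = max(w_bar, (1 + 1 / m) * b - w_bar))
  df <- if (b > 0) (m - 1) * (1 + w_bar / (b / m))^2 else Inf
  estimate_ci(q_bar, sqrt(Tvar), alpha = alpha, df = df)
}

#' Four replicability agreement metrics
#'
#' Compares a combined synthetic estimate against the real-data estimate:
#' \describe{
#'   \item{decision_agreement}{1 iff the estimates share their sign and their
#'     statistical-significance status (interval excludes 0) matches.}
#'   \item{estimate_agreement}{1 iff the synthetic estimate falls inside the
#'     real interval.}
#'   \item{standardized_difference_agreement}{1 iff
#'     `|q_syn - q_real| / sqrt(SE_syn^2 + SE_real^2)` does not exceed the
#'     two-sided normal quantile at the common alpha — i.e. the difference is
#'     consistent with no true difference.}
#'   \item{ci_overlap}{the proportion of overlap between the two intervals,
#'     averaged over both reference interval widths and truncated at 0:
#'     `max(0, ((min(U) - max(L))/(U_r - L_r) + (min(U) - max(L))/(U_s - L_s))/2)`.}
#' }
#'
#' @param real Real-data [estimate_ci()].
#' @param synthetic Combined synthetic [estimate_ci()] (same alpha).
#' @return A `replicability_result` list with the four metrics.
#' @export
replicability_metrics <- function(real, synthetic) {
  stopifnot(inherits(real, "estimate_ci"), inherits(synthetic, "estimate_ci"))
  if (abs(real$alpha - synthetic$alpha) > 1e-12)
    stop("real and synthetic intervals must use the same alpha")
  if (real$ci_high - real$ci_low <= 0)
    stop("real confidence interval has zero width")
  sig_r <- real$ci_low > 0 || real$ci_high < 0
  sig_s <- synthetic$ci_low > 0 || synthetic$ci_high < 0
  decision <- as.numeric(sign(synthetic$estimate) == sign(real$estimate) &&
                           sig_s == sig_r)
  estimate <- as.numeric(synthetic$estimate >= real$ci_low &&
                           synthetic$estimate <= real$ci_high)
  z <- stats::qnorm(1 - real$alpha / 2)
  sd_stat <- abs(synthetic$estimate - real$estimate) /
    sqrt(synthetic$standard_error^2 + real$standard_error^2)
  std_diff <- as.numeric(sd_stat <= z)
  inter <- min(real$ci_high, synthetic$ci_high) -
    max(real$ci_low, synthetic$ci_low)
  overlap <- max(0, (inter / (real$ci_high - real$ci_low) +
                       inter / (synthetic$ci_high - synthetic$ci_low)) / 2)
  structure(list(decision_agreement = decision,
                 estimate_agreement = estimate,
                 standardized_difference_agreement = std_diff,
                 ci_overlap = overlap),
            class = "replicability_result")
}

#' End-to-end replicability of an ensemble against real data
#'
#' Fits the inferential logistic model on the real training data and on each
#' synthetic replicate (core columns), pools the synthetic estimates with
#' [combine_estimates()], and returns the four agreement metrics. Replicates
#' whose logistic fit fails (separation, constant outcome) are recorded as
#' missing and excluded from pooling.
#'
#' @param real Real [cohort()] used for the reference fit (conventionally the
#'   training subset).
#' @param ensemble A `synthetic_ensemble`.
#' @param alpha Significance level.
#' @return List with `metrics` (a `replicability_result`), `real_estimate`,
#'   `synthetic_estimate`, and `n_failed` replicate count.
#' @export
ensemble_replicability <- function(real, ensemble, alpha = 0.05) {
  real_c <- project_core(real)
  real_est <- fit_logistic_estimate(real_c, alpha = alpha)
  ests <- lapply(ensemble$replicates, function(syn) {
    tryCatch(fit_logistic_estimate(project_core(syn), alpha = alpha),
             logistic_fit_error = function(e) NULL,
             error = function(e) NULL)
  })
  n_failed <- sum(vapply(ests, is.null, logical(1)))
  comb <- combine_estimates(ests, alpha = alpha)
  list(metrics = replicability_metrics(real_est, comb),
       real_estimate = real_est, synthetic_estimate = comb,
       n_failed = n_failed)
}
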