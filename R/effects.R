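#' Mixed-effects estimate of the adjunct-count effect on a metric
#'
#' Meta-analyzes a long-format metric table across datasets: the metric value
#' is regressed on the number of adjunct variables `k_adjunct` (fixed
#' effect), with the dataset as a random component — both a random intercept
#' and a random slope, since a dataset may shift the metric's level and
#' modulate the adjunct effect:
#' `value ~ 1 + k_adjunct + (1 + k_adjunct | dataset_id)`.
#'
#' Continuous metrics (fidelity score, AUROC, CI overlap) use a linear
#' mixed model (lme4/lmerTest) with Satterthwaite degrees of freedom for the
#' fixed-effect p-value; binary agreement metrics use a generalized mixed
#' model with a binomial logit link, reporting the odds ratio
#' `exp(coefficient)` with a Wald z p-value. The 95% CI is computed by
#' likelihood profiling, falling back to the Wald approximation when the
#' profile fails to converge (the method actually used is recorded). On a
#' singular random-effects fit the model is refit with uncorrelated
#' intercept and slope, also recorded.
#'
#' @param metric_table Data.frame with columns `dataset_id`, `generator_id`,
#'   `k_adjunct`, `metric_name`, `value` (see [write_metric_table()]).
#' @param metric_name Metric to model.
#' @param generator_id Generator whose rows are modeled (each generator is
#'   modeled separately); `NULL` uses all rows.
#' @param family `"linear"` or `"binomial_logit"`.
#' @param alpha Significance level (default 0.05).
#' @param ci_method `"profile"` (default, with Wald fallback) or `"wald"`.
#' @return An `effect_estimate` list with `fixed_effect` (coefficient, or
#'   odds ratio for the binomial family), `ci_low`, `ci_high`, `p_value`,
#'   `ci_method`, `family`, and bookkeeping fields.
#' @export
fit_metric_effect <- function(metric_table, metric_name, generator_id = NULL,
                              family = c("linear", "binomial_logit"),
                              alpha = 0.05,
                              ci_method = c("profile", "wald")) {
  family <- match.arg(family)
  ci_method <- match.arg(ci_method)
  d <- metric_table[metric_table$metric_name == metric_name, , drop = FALSE]
  if (!is.null(generator_id))
    d <- d[d$generator_id == generator_id, , drop = FALSE]
  d <- d[!is.na(d$value), , drop = FALSE]
  if (!nrow(d)) stop("no rows for metric '", metric_name, "'")
  if (length(unique(d$dataset_id)) < 2)
    stop("random effects need at least 2 distinct datasets; ",
         "use a fixed-effects model for a single dataset")
  if (length(unique(d$value)) < 2) stop("metric is constant; no effect to fit")
  if (family == "binomial_logit" && !all(d$value %in% c(0, 1)))
    stop("binomial_logit requires a binary metric")
  if (family == "linear" && all(d$value %in% c(0, 1)) &&
      length(unique(d$value)) == 2)
    warning("binary-looking metric fitted with the linear family")

  d$dataset_id <- factor(d$dataset_id)
  singular_refit <- FALSE
  if (family == "linear") {
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(value ~ k_adjunct + (1 + k_adjunct | dataset_id),
                     data = d)))
    if (lme4::isSingular(fit, tol = 1e-5)) {
      singular_refit <- TRUE
      fit <- suppressMessages(suppressWarnings(
        lmerTest::lmer(value ~ k_adjunct + (1 + k_adjunct || dataset_id),
                       data = d)))
    }
    co <- stats::coef(summary(fit))["k_adjunct", ]
    est <- co[["Estimate"]]; se <- co[["Std. Error"]]
    p <- co[["Pr(>|t|)"]]
    p_method <- "satterthwaite"
  } else {
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(value ~ k_adjunct + (1 + k_adjunct | dataset_id),
                  data = d, family = stats::binomial())))
    if (lme4::isSingular(fit, tol = 1e-5)) {
      singular_refit <- TRUE
      fit <- suppressMessages(suppressWarnings(
        lme4::glmer(value ~ k_adjunct + (1 + k_adjunct || dataset_id),
                    data = d, family = stats::binomial())))
    }
    co <- stats::coef(summary(fit))["k_adjunct", ]
    est <- co[["Estimate"]]; se <- co[["Std. Error"]]
    p <- co[["Pr(>|z|)"]]
    p_method <- "wald_z"
  }

  method_used <- ci_method
  ci <- NULL
  if (ci_method == "profile") {
    ci <- tryCatch(
      suppressMessages(suppressWarnings(
        stats::confint(fit, parm = "k_adjunct", level = 1 - alpha,
                       method = "profile")))["k_adjunct", ],
      error = function(e) NULL)
    if (is.null(ci) || anyNA(ci)) { ci <- NULL; method_used <- "wald" }
  }
  if (is.null(ci)) {
    z <- stats::qnorm(1 - alpha / 2)
    ci <- c(est - z * se, est + z * se)
  }

  if (family == "binomial_logit") {
    reported <- exp(est); lo <- exp(ci[1]); hi <- exp(ci[2])
  } else {
    reported <- est; lo <- ci[1]; hi <- ci[2]
  }
  structure(list(metric_name = metric_name,
                 generator_id = if (is.null(generator_id)) NA_character_
                   else generator_id,
                 family = family, fixed_effect = unname(reported),
                 ci_low = unname(lo), ci_high = unname(hi),
                 p_value = unname(p), raw_coefficient = unname(est),
                 std_error = unname(se), ci_method = method_used,
                 p_method = p_method, singular_refit = singular_refit,
                 n_rows = nrow(d)),
            class = "effect_estimate")
}

# Metric -> model family lookup used by effect_table / run_experiment.
metric_family <- function(metric_name) {
  if (metric_name %in% c("estimate_agreement", "decision_agreement",
                         "standardized_difference_agreement"))
    "binomial_logit" else "linear"
}

#' Effect table across generators and metrics
#'
#' Fits [fit_metric_effect()] for every (generator, metric) combination in a
#' metric table and assembles one row per combination with the fixed effect,
#' its CI, the p-value, and a significance flag at `alpha`. Binary agreement
#' metrics are fitted with the binomial-logit family (odds ratios), all
#' other metrics with the linear family. Rows are sorted generator-major.
#'
#' @param metric_table Long-format metric data.frame.
#' @param alpha Significance level for the flag (default 0.05).
#' @return A data.frame with columns `generator_id`, `metric_name`,
#'   `family`, `fixed_effect`, `ci_low`, `ci_high`, `p_value`,
#'   `significant`, `ci_method`, `note`.
#' @export
effect_table <- function(metric_table, alpha = 0.05) {
  gens <- unique(metric_table$generator_id)
  mets <- unique(metric_table$metric_name)
  rows <- list()
  for (g in gens) for (m in mets) {
    sub <- metric_table[metric_table$generator_id == g &
                          metric_table$metric_name == m, , drop = FALSE]
    if (!nrow(sub)) next
    fam <- metric_family(m)
    est <- tryCatch(fit_metric_effect(metric_table, m, g, family = fam,
                                      alpha = alpha),
                    error = function(e)
                      structure(list(error = conditionMessage(e)),
                                class = "effect_error"))
    rows[[length(rows) + 1L]] <- if (inherits(est, "effect_error"))
      data.frame(generator_id = g, metric_name = m, family = fam,
                 fixed_effect = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p_value = NA_real_, significant = NA,
                 ci_method = NA_character_, note = est$error,
                 stringsAsFactors = FALSE)
    else
      data.frame(generator_id = g, metric_name = m, family = fam,
                 fixed_effect = est$fixed_effect, ci_low = est$ci_low,
                 ci_high = est$ci_high, p_value = est$p_value,
                 significant = est$p_value < alpha,
                 ci_method = est$ci_method,
                 note = if (est$singular_refit) "uncorrelated RE refit" else "",
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(match(out$generator_id, gens), match(out$metric_name, mets)), ,
      drop = FALSE]
}
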