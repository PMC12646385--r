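# Small cohorts built in code, shared across test files.

# 4-variable mixed cohort: continuous core, categorical core (QI), adjunct,
# binary outcome; optional missing cells.
toy_cohort <- function(n = 10, seed = 1, with_missing = FALSE) {
  set.seed(seed)
  records <- data.frame(
    age = round(stats::rnorm(n, 50, 10), 2),
    sex = sample(c("f", "m"), n, replace = TRUE),
    extra = sample(c("low", "mid", "high"), n, replace = TRUE),
    outcome = sample(c("0", "1"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  records$outcome[1:2] <- c("0", "1")  # both classes always present
  if (with_missing) {
    records$age[1] <- NA
    records$sex[2] <- NA
  }
  cohort(records, list(
    variable_meta("age", "continuous", "core_predictor", is_qi = TRUE,
                  is_parameter_of_interest = TRUE),
    variable_meta("sex", "categorical", "core_predictor",
                  categories = c("f", "m"), is_qi = TRUE),
    variable_meta("extra", "categorical", "adjunct",
                  categories = c("low", "mid", "high")),
    variable_meta("outcome", "categorical", "outcome",
                  categories = c("0", "1"))),
    dataset_id = "toy")
}

# Cohort whose single core predictor separates/predicts the outcome with the
# given logistic slope; purely categorical apart from the predictor.
signal_cohort <- function(n = 2000, slope = 2, seed = 1,
                          dataset_id = "signal") {
  set.seed(seed)
  x <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(slope * x))
  cohort(data.frame(x = x, outcome = as.character(y),
                    stringsAsFactors = FALSE),
         list(variable_meta("x", "continuous", "core_predictor",
                            is_qi = TRUE, is_parameter_of_interest = TRUE),
              variable_meta("outcome", "categorical", "outcome",
                            categories = c("0", "1"))),
         dataset_id = dataset_id)
}

# Build an estimate_ci directly from explicit interval bounds.
ci_from_bounds <- function(estimate, lo, hi, se = (hi - lo) / (2 * 1.96)) {
  estimate_ci(estimate, se, ci_low = lo, ci_high = hi)
}

# Simulated long-format metric table with known fixed slope and
# dataset-level random intercepts; one row per (dataset, variant).
simulated_metric_table <- function(n_datasets = 12, n_variants = 200,
                                   slope = -0.001, intercept = 0.8,
                                   sd_intercept = 0.05, sd_noise = 0.01,
                                   sd_slope = 0, seed = 1,
                                   metric_name = "fidelity_cluster",
                                   generator_id = "st") {
  set.seed(seed)
  rows <- lapply(seq_len(n_datasets), function(d) {
    u0 <- stats::rnorm(1, 0, sd_intercept)
    u1 <- if (sd_slope > 0) stats::rnorm(1, 0, sd_slope) else 0
    k <- sample(0:120, n_variants, replace = TRUE)
    data.frame(dataset_id = paste0("d", d), generator_id = generator_id,
               variant_id = paste0("v", seq_len(n_variants)),
               k_adjunct = k, metric_name = metric_name,
               replicate = NA_integer_,
               value = intercept + u0 + (slope + u1) * k +
                 stats::rnorm(n_variants, 0, sd_noise),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
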