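#' Configure a full experiment run
#'
#' Bundles everything [run_experiment()] needs: the cohorts to simulate, how
#' variants are built, which generators to fit, which metrics to compute, and
#' the master seed. Defaults mirror the reference study design (training and
#' holdout of 10 000 records each, 10 synthetic replicates, significance
#' 0.05); scaled-down smoke runs override them freely.
#'
#' @param cohort_specs List of [cohort_spec()]s (at least one).
#' @param generators Character vector of generator ids among
#'   `"st"`, `"bn"`, `"independent"`, `"copy"`.
#' @param metrics Character subset of
#'   `c("fidelity", "tstr", "replicability", "privacy")`.
#' @param n_train,n_holdout Split sizes.
#' @param n_replicates Synthetic replicates per fitted generator.
#' @param enumerate_cap Enumerate the full variant space when the adjunct
#'   pool is at most this large; sample otherwise.
#' @param per_k_target,min_per_k Passed to [sample_variants()] for large
#'   pools.
#' @param fidelity_clusters Cluster count G of [cluster_fidelity()].
#' @param classifier TSTR classifier spec (an entry of
#'   [default_classifiers()]).
#' @param attack An [attack_config()] (its seed field is overridden by the
#'   run's derived seeds).
#' @param alpha Significance level.
#' @param seed Master seed; every stage derives child seeds from it.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort_specs, generators = c("st", "independent"),
                       metrics = c("fidelity", "tstr", "replicability",
                                   "privacy"),
                       n_train = 10000, n_holdout = 10000, n_replicates = 10,
                       enumerate_cap = 6, per_k_target = NULL, min_per_k = 5,
                       fidelity_clusters = 20, classifier = NULL,
                       attack = attack_config(), alpha = 0.05, seed = 1) {
  if (inherits(cohort_specs, "cohort_spec")) cohort_specs <- list(cohort_specs)
  stopifnot(length(cohort_specs) >= 1, n_replicates >= 1)
  known <- c("st", "bn", "independent", "copy")
  bad <- setdiff(generators, known)
  if (length(bad))
    stop("unknown generator id(s): ", paste(bad, collapse = ", "),
         " (registered: ", paste(known, collapse = ", "), ")")
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (is.null(classifier)) classifier <- default_classifiers()$gbm
  structure(list(cohort_specs = cohort_specs, generators = generators,
                 metrics = metrics, n_train = n_train, n_holdout = n_holdout,
                 n_replicates = n_replicates, enumerate_cap = enumerate_cap,
                 per_k_target = per_k_target, min_per_k = min_per_k,
                 fidelity_clusters = fidelity_clusters,
                 classifier = classifier, attack = attack, alpha = alpha,
                 seed = seed),
            class = "run_config")
}

fit_generator_by_id <- function(id, train, seed) {
  switch(id,
         st = fit_sequential_trees(train, seed = seed),
         bn = fit_bayesian_network(train, seed = seed),
         independent = fit_independent_marginals(train, seed = seed),
         copy = fit_copy_generator(train, seed = seed),
         stop("unknown generator id: ", id))
}

#' Run the full experiment
#'
#' For each configured cohort: simulate the population, fix one
#' train/holdout split shared by all variants, build the variant list
#' (enumerated for small pools, sampled for large ones), and for each
#' (variant, generator) cell: fit the generator on the variant's projected
#' training table, draw the synthetic ensemble, and compute the configured
#' evaluation metrics — cluster fidelity and TSTR on the projected core,
#' replicability agreement of the pooled logistic estimate, and membership
#' vulnerability in both adversary modes and both column scopes. Finally,
#' when at least two cohorts are present, mixed-effects models estimate the
#' adjunct-count effect per generator and metric.
#'
#' A failing cell is logged with its (dataset, variant, generator)
#' coordinates and the run continues; the failure list is returned in the
#' manifest. Identical config and master seed reproduce the metric table
#' byte for byte.
#'
#' @param config A [run_config()].
#' @return List with `metric_table` (long-format data.frame),
#'   `effect_table` (or NULL with fewer than 2 datasets), and `manifest`
#'   (seeds, sizes, timings, failures).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  rows <- list(); failures <- list()
  for (cs in config$cohort_specs) {
    sim <- simulate_cohort(cs)
    pop <- sim$cohort
    split <- split_train_holdout(pop, config$n_train, config$n_holdout,
                                 seed = config$seed)
    train_full <- subset_rows(pop, split$train_ids)
    holdout <- subset_rows(pop, split$holdout_ids)
    pool <- adjunct_names(pop)
    variants <- if (length(pool) <= config$enumerate_cap)
      enumerate_variants(core_names(pop), pool, pop$dataset_id,
                         enumerate_cap = config$enumerate_cap)
    else sample_variants(core_names(pop), pool,
                         per_k_target = config$per_k_target,
                         min_per_k = config$min_per_k,
                         seed = derive_seed(config$seed, "variants",
                                            pop$dataset_id),
                         dataset_id = pop$dataset_id)
    for (variant in variants) {
      train_v <- project_variant(train_full, variant)
      for (gid in config$generators) {
        cell <- tryCatch({
          fitted <- fit_generator_by_id(
            gid, train_v,
            derive_seed(config$seed, "fit", pop$dataset_id,
                        variant$variant_id, gid))
          ens <- generate(fitted, n_rows = nrow(train_v$records),
                          n_replicates = config$n_replicates,
                          seed = derive_seed(config$seed, "gen",
                                             pop$dataset_id,
                                             variant$variant_id, gid))
          evaluate_cell(pop, train_full, holdout, split, variant, ens, config)
        }, error = function(e) e)
        if (inherits(cell, "error")) {
          failures[[length(failures) + 1L]] <-
            list(dataset = pop$dataset_id, variant = variant$variant_id,
                 generator = gid, message = conditionMessage(cell))
        } else rows[[length(rows) + 1L]] <- cell
      }
    }
  }
  metric_table <- do.call(rbind, rows)
  rownames(metric_table) <- NULL

  eff <- NULL
  if (!is.null(metric_table) &&
      length(unique(metric_table$dataset_id)) >= 2) {
    agg <- aggregate_for_effects(metric_table)
    eff <- tryCatch(effect_table(agg, alpha = config$alpha),
                    error = function(e) NULL)
  }
  manifest <- list(seed = config$seed,
                   n_datasets = length(config$cohort_specs),
                   generators = config$generators, metrics = config$metrics,
                   n_replicates = config$n_replicates,
                   n_train = config$n_train, n_holdout = config$n_holdout,
                   n_cells_completed = length(rows),
                   failures = failures,
                   elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")),
                   package_version =
                     as.character(utils::packageVersion("adjunctsdg")))
  if (length(failures))
    warning(length(failures), " cell(s) failed; see manifest$failures")
  list(metric_table = metric_table, effect_table = eff, manifest = manifest)
}

# Metrics for one (variant, generator) cell, as metric-table rows.
evaluate_cell <- function(pop, train_full, holdout, split, variant, ens,
                          config) {
  out <- list()
  did <- pop$dataset_id; gid <- ens$generator_id
  vid <- variant$variant_id; k <- variant$k_adjunct
  rec <- function(metric, replicate, value)
    metric_record(did, gid, vid, k, metric, replicate, value)

  if ("fidelity" %in% config$metrics) {
    fid <- ensemble_fidelity(project_variant(holdout, variant), ens,
                             G = config$fidelity_clusters,
                             seed = derive_seed(config$seed, "fidel", did,
                                                vid, gid))
    for (r in seq_along(fid$per_replicate))
      out[[length(out) + 1L]] <- rec("fidelity_cluster", r,
                                     fid$per_replicate[r])
  }
  if ("tstr" %in% config$metrics) {
    ts <- tstr_auroc(ens, holdout, config$classifier,
                     seed = derive_seed(config$seed, "tstr", did, vid, gid))
    for (r in seq_along(ts$per_replicate_auroc))
      out[[length(out) + 1L]] <- rec(paste0("tstr_", ts$classifier_id), r,
                                     ts$per_replicate_auroc[r])
  }
  if ("replicability" %in% config$metrics) {
    rp <- ensemble_replicability(project_variant(train_full, variant), ens,
                                 alpha = config$alpha)
    for (mn in c("decision_agreement", "estimate_agreement",
                 "standardized_difference_agreement", "ci_overlap"))
      out[[length(out) + 1L]] <- rec(mn, NA_integer_, rp$metrics[[mn]])
  }
  if ("privacy" %in% config$metrics) {
    atk <- config$attack
    atk$seed <- derive_seed(config$seed, "attack", did, vid, gid)
    vp <- vulnerability_pair(pop, split$train_ids, ens, atk)
    for (mn in setdiff(names(vp), "per_replicate"))
      out[[length(out) + 1L]] <- rec(mn, NA_integer_, vp[[mn]])
  }
  do.call(rbind, out)
}

# Variant-level aggregation before mixed-effects modeling: continuous
# metrics enter as the mean over replicates; agreement metrics are already
# one row per variant.
aggregate_for_effects <- function(metric_table) {
  agg <- stats::aggregate(
    value ~ dataset_id + generator_id + variant_id + k_adjunct + metric_name,
    data = metric_table, FUN = mean, na.rm = TRUE, na.action = NULL)
  agg
}

#' Summarize a metric table
#'
#' Per-generator, per-metric means by adjunct count, plus membership
#' disclosure flags at the conventional 0.2 relative-F1 threshold.
#'
#' @param metric_table Long-format metric data.frame.
#' @param metrics Optional metric-name filter (must match at least one row).
#' @param risk_threshold Relative-F1 threshold for flagging (default 0.2).
#' @return Character vector of report lines (also printed).
#' @export
summarize_run <- function(metric_table, metrics = NULL,
                          risk_threshold = 0.2) {
  if (is.null(metric_table) || !nrow(metric_table)) stop("empty metric table")
  if (!is.null(metrics)) {
    metric_table <- metric_table[metric_table$metric_name %in% metrics, ,
                                 drop = FALSE]
    if (!nrow(metric_table)) stop("metric filter matched no rows")
  }
  lines <- character(0)
  for (g in unique(metric_table$generator_id)) {
    for (m in unique(metric_table$metric_name)) {
      sub <- metric_table[metric_table$generator_id == g &
                            metric_table$metric_name == m, , drop = FALSE]
      if (!nrow(sub)) next
      lines <- c(lines, sprintf("== %s / %s ==", g, m))
      mk <- stats::aggregate(value ~ k_adjunct, data = sub, FUN = mean,
                             na.rm = TRUE, na.action = NULL)
      lines <- c(lines, sprintf("  k=%-3d mean=%.4f", mk$k_adjunct, mk$value))
    }
  }
  risk <- metric_table[grepl("^membership_", metric_table$metric_name) &
                         !is.na(metric_table$value) &
                         metric_table$value >= risk_threshold, , drop = FALSE]
  if (nrow(risk))
    lines <- c(lines, sprintf(
      "FLAG: %s/%s %s relative F1 %.3f >= %.2f (above the acceptable-risk threshold)",
      risk$dataset_id, risk$generator_id, risk$metric_name, risk$value,
      risk_threshold))
  else
    lines <- c(lines, sprintf(
      "All membership relative-F1 values below %.2f (low residual risk).",
      risk_threshold))
  cat(lines, sep = "\n")
  invisible(lines)
}
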