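# Brute-force all-pairs reference matcher: an attack record is predicted a
# member iff some synthetic record mismatches it on at most h compared
# variables (categorical equality with NA as its own category; continuous
# within tol * sd).
brute_force_match <- function(attack, synthetic, meta, config) {
  h <- config$match_hamming_threshold
  vapply(seq_len(nrow(attack)), function(i) {
    any(vapply(seq_len(nrow(synthetic)), function(j) {
      mism <- 0
      for (nm in names(meta)) {
        a <- attack[[nm]][i]; s <- synthetic[[nm]][j]
        same <- if (meta[[nm]]$vtype == "categorical") {
          a <- as.character(a); s <- as.character(s)
          (is.na(a) && is.na(s)) || (!is.na(a) && !is.na(s) && a == s)
        } else {
          a <- as.numeric(a); s <- as.numeric(s)
          sdv <- sd(c(as.numeric(attack[[nm]]),
                      as.numeric(synthetic[[nm]])), na.rm = TRUE)
          if (!is.finite(sdv) || sdv == 0) sdv <- 1
          (is.na(a) && is.na(s)) ||
            (!is.na(a) && !is.na(s) &&
               abs(a - s) <= config$continuous_tolerance * sdv)
        }
        if (!same) mism <- mism + 1
      }
      mism <= h
    }, logical(1)))
  }, logical(1))
}

# population of n records with globally unique categorical QI profiles
unique_qi_population <- function(n = 40) {
  ids <- sprintf("id%02d", seq_len(n))
  cohort(data.frame(tag = ids,
                    outcome = rep(c("0", "1"), length.out = n),
                    stringsAsFactors = FALSE),
         list(variable_meta("tag", "categorical", "core_predictor",
                            categories = ids, is_qi = TRUE),
              variable_meta("outcome", "categorical", "outcome",
                            categories = c("0", "1"))),
         dataset_id = "uniq")
}

test_that("verbatim training rows with unique QI profiles give the
           hand-computed relative F1 of 1/3 at p = 0.5", {
  pop <- unique_qi_population(40)
  train_ids <- 1:20
  synthetic <- adjunctsdg:::subset_rows(pop, train_ids)  # verbatim copy
  cfg <- attack_config(attack_sample_size = 40, member_fraction = 0.5,
                       seed = 2)
  res <- membership_attack(pop, train_ids, synthetic, cfg, mode = "qi_only")
  # every member matches (recall 1); no non-member can match (precision 1)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)
  expect_equal(res$f1, 1)
  expect_equal(res$f1_naive, 2 / 3, tolerance = 1e-12)
  expect_equal(res$relative_f1, 1 / 3, tolerance = 1e-12)
})

test_that("synthetic values outside the population support never match", {
  pop <- unique_qi_population(30)
  syn_rec <- data.frame(tag = rep(NA_character_, 10),
                        outcome = rep(c("0", "1"), 5),
                        stringsAsFactors = FALSE)
  synthetic <- cohort(syn_rec, pop$meta, "uniq")
  # every synthetic QI is missing, every population QI observed: no matches
  res <- membership_attack(pop, 1:15, synthetic,
                           attack_config(attack_sample_size = 30, seed = 1),
                           mode = "qi_only")
  expect_equal(res$f1, 0)
  expect_equal(res$relative_f1, 0)
})

test_that("the naive predict-all baseline has relative F1 zero by
           construction", {
  p <- 0.5
  f1_naive <- 2 * p / (1 + p)
  expect_equal(f1_naive, 2 / 3, tolerance = 1e-12)
  expect_equal(max(0, f1_naive - f1_naive), 0)
  # and with p = 0.2 the baseline weakens
  expect_equal(2 * 0.2 / 1.2, 1 / 3, tolerance = 1e-12)
})

test_that("the indexed matcher agrees with the brute-force all-pairs oracle
           on mixed-type instances", {
  spec <- cohort_spec(n_records = 300, n_core_predictors = 4,
                      adjunct_pool_size = 2, missing_rate = 0.1,
                      qi_count = 3, seed = 51, dataset_id = "bf")
  pop <- simulate_cohort(spec)$cohort
  train_ids <- 1:150
  im <- fit_independent_marginals(adjunctsdg:::subset_rows(pop, train_ids))
  syn <- generate(im, n_rows = 200, n_replicates = 1, seed = 3)$replicates[[1]]
  for (h in c(0, 1)) {
    cfg <- attack_config(attack_sample_size = 60, seed = 7,
                         match_hamming_threshold = h)
    cols <- adjunctsdg:::attack_columns(pop, cfg, "qi_only")
    att <- pop$records[c(1:30, 151:180), cols, drop = FALSE]
    expect_identical(
      adjunctsdg:::match_members(att, syn$records[, cols, drop = FALSE],
                                 pop$meta[cols], cfg),
      brute_force_match(att, syn$records[, cols, drop = FALSE],
                        pop$meta[cols], cfg))
  }
})

test_that("the hash path (all-categorical, h = 0) agrees with brute force", {
  pop <- unique_qi_population(50)
  set.seed(9)
  syn_rec <- pop$records[sample(1:25, 40, replace = TRUE), , drop = FALSE]
  synthetic <- cohort(syn_rec, pop$meta, "uniq")
  cfg <- attack_config(attack_sample_size = 50, seed = 4)
  cols <- c("tag")
  att <- pop$records[, cols, drop = FALSE]
  expect_identical(
    adjunctsdg:::match_members(att, synthetic$records[, cols, drop = FALSE],
                               pop$meta[cols], cfg),
    brute_force_match(att, synthetic$records[, cols, drop = FALSE],
                      pop$meta[cols], cfg))
})

test_that("the copy generator dominates fitted generators in membership
           vulnerability, and results stay within [0,1]", {
  spec <- cohort_spec(n_records = 1200, n_core_predictors = 4,
                      adjunct_pool_size = 2, missing_rate = 0.02,
                      qi_count = 4, seed = 61, dataset_id = "dom")
  pop <- simulate_cohort(spec)$cohort
  sp <- split_train_holdout(pop, 400, 400, seed = 2)
  train <- adjunctsdg:::subset_rows(pop, sp$train_ids)
  cfg <- attack_config(attack_sample_size = 200, seed = 5)
  rel <- vapply(c("copy", "st", "bn", "independent"), function(gid) {
    fitted <- adjunctsdg:::fit_generator_by_id(gid, train, seed = 3)
    ens <- generate(fitted, n_rows = 400, n_replicates = 2, seed = 4)
    vp <- vulnerability_pair(pop, sp$train_ids, ens, cfg)
    vals <- unlist(vp[setdiff(names(vp), "per_replicate")])
    expect_true(all(vals >= 0 & vals <= 1))
    vp$membership_qi_full
  }, numeric(1))
  expect_gte(rel[["copy"]], rel[["st"]])
  expect_gte(rel[["copy"]], rel[["bn"]])
  expect_gte(rel[["copy"]], rel[["independent"]])
  expect_gt(rel[["copy"]], 0)  # the attack does find the copied rows
})

test_that("scope and mode contracts: core scope compares only core columns;
           qi mode requires declared QIs", {
  pop <- unique_qi_population(30)
  syn <- adjunctsdg:::subset_rows(pop, 1:15)
  cfg <- attack_config(attack_sample_size = 20, seed = 3)
  # core scope excludes nothing here (QI is core), so result is defined
  res <- membership_attack(pop, 1:15, syn, cfg, mode = "qi_only",
                           scope_cols = c("tag", "outcome"))
  expect_s3_class(res, "membership_attack_result")

  no_qi <- pop
  no_qi$meta$tag$is_qi <- FALSE
  expect_error(membership_attack(no_qi, 1:15, syn, cfg, mode = "qi_only"),
               "quasi-identifiers")
  expect_error(membership_attack(pop, 1:15, syn,
                                 attack_config(attack_sample_size = 500),
                                 mode = "qi_only"),
               "exceeds")
})
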