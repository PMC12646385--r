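fast_gbm <- function() default_classifiers(
  gbm_grid = data.frame(max_depth = 3L, eta = 0.3), gbm_nrounds = 60L)$gbm

test_that("rank-statistic AUROC: label-flip symmetry and tie handling", {
  set.seed(8)
  s <- rnorm(200); y <- rbinom(200, 1, 0.4)
  expect_equal(auroc(s, y), 1 - auroc(-s, y), tolerance = 1e-12)
  # ties count one half
  expect_equal(auroc(rep(1, 10), c(rep(0, 5), rep(1, 5))), 0.5)
  expect_equal(auroc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_error(auroc(s, rep(1, 200)), "one class")
})

test_that("a perfectly separating predictor carried into synthesis yields
           AUROC near 1", {
  x <- cohort(data.frame(x = c(seq(-2, -0.1, length.out = 250),
                               seq(0.1, 2, length.out = 250)),
                         outcome = rep(c("0", "1"), each = 250),
                         stringsAsFactors = FALSE),
              list(variable_meta("x", "continuous", "core_predictor",
                                 is_parameter_of_interest = TRUE),
                   variable_meta("outcome", "categorical", "outcome",
                                 categories = c("0", "1"))),
              dataset_id = "sep")
  cp <- fit_copy_generator(x, seed = 1)
  ens <- generate(cp, n_rows = 500, n_replicates = 2, seed = 2)
  res <- tstr_auroc(ens, x, fast_gbm(), seed = 1)
  expect_gte(res$mean_auroc, 0.99)
})

test_that("a permuted synthetic outcome drives AUROC to chance", {
  x <- signal_cohort(n = 10000, slope = 2, seed = 3)
  cp <- fit_copy_generator(x, seed = 1)
  # per-replicate noise-fit AUROCs fluctuate (the classifier is a step
  # function of x and the truth is monotone in x); the protocol's 10-replicate
  # mean is the stable quantity
  ens <- generate(cp, n_rows = 10000, n_replicates = 10, seed = 2)
  for (r in seq_along(ens$replicates)) {
    set.seed(100 + r)
    rec <- ens$replicates[[r]]$records
    rec$outcome <- rec$outcome[sample.int(nrow(rec))]
    ens$replicates[[r]] <- cohort(rec, x$meta, x$dataset_id)
  }
  res <- tstr_auroc(ens, x, fast_gbm(), seed = 1)
  expect_lt(abs(res$mean_auroc - 0.5), 0.03)
})

test_that("the mean is the arithmetic mean of per-replicate AUROCs and is
           insensitive to replicate order", {
  x <- signal_cohort(n = 800, seed = 5)
  cp <- fit_copy_generator(x, seed = 1)
  ens <- generate(cp, n_rows = 800, n_replicates = 3, seed = 4)
  res <- tstr_auroc(ens, x, fast_gbm(), seed = 1)
  expect_equal(res$mean_auroc, mean(res$per_replicate_auroc))
  ens_rev <- ens
  ens_rev$replicates <- rev(ens$replicates)
  res_rev <- tstr_auroc(ens_rev, x, fast_gbm(), seed = 1)
  expect_equal(sort(res$per_replicate_auroc),
               sort(res_rev$per_replicate_auroc), tolerance = 1e-9)
  expect_equal(mean(res$per_replicate_auroc),
               mean(res_rev$per_replicate_auroc), tolerance = 1e-9)
})

test_that("degenerate outcomes: single-class holdout errors, single-class
           replicate is skipped with a warning and recorded missing", {
  x <- signal_cohort(n = 300, seed = 6)
  cp <- fit_copy_generator(x, seed = 1)
  ens <- generate(cp, n_rows = 300, n_replicates = 2, seed = 2)
  bad_holdout <- x
  bad_holdout$records$outcome <- factor(rep("1", 300), c("0", "1"))
  expect_error(tstr_auroc(ens, bad_holdout, fast_gbm()), "single class")

  rec <- ens$replicates[[1]]$records
  rec$outcome <- factor(rep("1", nrow(rec)), c("0", "1"))
  ens$replicates[[1]] <- cohort(rec, x$meta, x$dataset_id)
  expect_warning(res <- tstr_auroc(ens, x, fast_gbm(), seed = 1),
                 "single-class")
  expect_true(is.na(res$per_replicate_auroc[1]))
  expect_false(is.na(res$mean_auroc))
})

test_that("both default classifiers emit probabilities in [0,1] and the
           boosted grid actually cross-validates", {
  specs <- default_classifiers()
  expect_identical(specs$gbm$cv_folds, 5L)
  expect_gt(nrow(specs$gbm$grid), 1)      # a grid to search
  expect_null(specs$mlp$grid)             # no grid search for the network
  x <- signal_cohort(n = 400, seed = 7)
  for (id in c("gbm", "mlp")) {
    spec <- if (id == "gbm") default_classifiers(
      gbm_grid = expand.grid(max_depth = c(2L, 3L), eta = 0.3),
      gbm_nrounds = 30L, cv_folds = 3L)$gbm else specs$mlp
    clf <- adjunctsdg:::fit_classifier(x, spec, seed = 1)
    pr <- clf$predict(x)
    expect_true(all(pr >= 0 & pr <= 1))
    expect_gt(auroc(pr, adjunctsdg:::outcome01(x)), 0.6)
  }
})

test_that("missing holdout values are imputed from training statistics only
           (no holdout leakage) for the network classifier", {
  x <- toy_cohort(n = 300, seed = 9, with_missing = TRUE)
  clf <- adjunctsdg:::fit_classifier(x, default_classifiers()$mlp, seed = 1)
  holdout <- toy_cohort(n = 50, seed = 10)
  holdout$records$age[1:25] <- NA
  pr <- clf$predict(holdout)
  expect_length(pr, 50)
  expect_false(anyNA(pr))
})
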