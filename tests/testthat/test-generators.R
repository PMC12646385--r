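# total-variation distance between the category frequencies of two factors
tv_distance <- function(a, b) {
  lev <- union(levels(a), levels(b))
  pa <- table(factor(a, lev)) / length(a)
  pb <- table(factor(b, lev)) / length(b)
  sum(abs(pa - pb)) / 2
}

phi_coefficient <- function(a, b) {
  tab <- table(a, b)
  (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]) /
    sqrt(prod(rowSums(tab)) * prod(colSums(tab)))
}

# outcome-only cohort plus a binary core column perfectly tied to it
mirrored_binary_cohort <- function(n = 400, seed = 2) {
  set.seed(seed)
  y <- sample(c("0", "1"), n, replace = TRUE)
  cohort(data.frame(x = y, outcome = y, stringsAsFactors = FALSE),
         list(variable_meta("x", "categorical", "core_predictor",
                            categories = c("0", "1")),
              variable_meta("outcome", "categorical", "outcome",
                            categories = c("0", "1"))),
         dataset_id = "mirror")
}

test_that("a single-column cohort synthesizes as an i.i.d. bootstrap of the
           empirical marginal", {
  set.seed(4)
  y <- sample(c("0", "1"), 300, replace = TRUE, prob = c(0.7, 0.3))
  x <- cohort(data.frame(outcome = y, stringsAsFactors = FALSE),
              list(variable_meta("outcome", "categorical", "outcome",
                                 categories = c("0", "1"))),
              dataset_id = "single")
  st <- fit_sequential_trees(x, seed = 1)
  syn <- generate(st, n_rows = 10000, n_replicates = 1,
                  seed = 2)$replicates[[1]]
  p_train <- mean(y == "1")
  p_syn <- mean(syn$records$outcome == "1")
  expect_lt(abs(p_syn - p_train), 3 * sqrt(p_train * (1 - p_train) / 10000))
})

test_that("sequential trees preserve a perfect binary association;
           independent marginals destroy it", {
  x <- mirrored_binary_cohort()
  st <- fit_sequential_trees(x, seed = 1)
  syn <- generate(st, n_rows = 10000, n_replicates = 1,
                  seed = 3)$replicates[[1]]
  expect_gte(phi_coefficient(syn$records$x, syn$records$outcome), 0.95)

  im <- fit_independent_marginals(x, seed = 1)
  syn_i <- generate(im, n_rows = 10000, n_replicates = 1,
                    seed = 3)$replicates[[1]]
  expect_lt(abs(phi_coefficient(syn_i$records$x, syn_i$records$outcome)),
            0.05)
})

test_that("generator fits and samples are deterministic in the seed", {
  x <- toy_cohort(n = 200, with_missing = TRUE)
  for (fitter in list(fit_sequential_trees, fit_bayesian_network,
                      fit_independent_marginals, fit_copy_generator)) {
    g1 <- fitter(x, seed = 5); g2 <- fitter(x, seed = 5)
    e1 <- generate(g1, n_rows = 300, n_replicates = 2, seed = 9)
    e2 <- generate(g2, n_rows = 300, n_replicates = 2, seed = 9)
    expect_identical(e1$replicates[[1]]$records, e2$replicates[[1]]$records)
    expect_identical(e1$replicates[[2]]$records, e2$replicates[[2]]$records)
    # distinct child seeds: replicates differ from each other
    expect_false(identical(e1$replicates[[1]]$records,
                           e1$replicates[[2]]$records))
  }
})

test_that("Bayesian network on mutually independent columns learns only
           weak edges and matches training marginals", {
  set.seed(6)
  n <- 50000
  x <- cohort(data.frame(
    g1 = sample(letters[1:3], n, replace = TRUE, prob = c(.5, .3, .2)),
    g2 = sample(c("u", "v"), n, replace = TRUE),
    z = rnorm(n),
    outcome = sample(c("0", "1"), n, replace = TRUE),
    stringsAsFactors = FALSE),
    list(variable_meta("g1", "categorical", "core_predictor",
                       categories = letters[1:3]),
         variable_meta("g2", "categorical", "core_predictor",
                       categories = c("u", "v")),
         variable_meta("z", "continuous", "core_predictor"),
         variable_meta("outcome", "categorical", "outcome",
                       categories = c("0", "1"))),
    dataset_id = "bn_indep")
  bn <- fit_bayesian_network(x, seed = 1)
  # every learned edge connects near-independent variables
  for (v in seq_along(bn$parent)) {
    pa <- bn$parent[v]
    if (!is.na(pa)) expect_lt(bn$mi_used[v, pa], 0.01)
  }
  syn <- generate(bn, n_rows = 20000, n_replicates = 1,
                  seed = 2)$replicates[[1]]
  expect_lt(tv_distance(syn$records$g1, x$records$g1), 0.03)
  expect_lt(tv_distance(syn$records$g2, x$records$g2), 0.03)
  expect_lt(tv_distance(syn$records$outcome, x$records$outcome), 0.03)
  # continuous marginal comes back on the same support
  expect_gt(ks.test(syn$records$z, x$records$z)$statistic, 0)  # defined
  expect_lt(abs(mean(syn$records$z) - mean(x$records$z)), 0.05)
})

test_that("Bayesian network reproduces a deterministic binary chain", {
  x <- mirrored_binary_cohort(n = 1000, seed = 9)
  bn <- fit_bayesian_network(x, seed = 1)
  syn <- generate(bn, n_rows = 10000, n_replicates = 1,
                  seed = 4)$replicates[[1]]
  expect_gte(mean(as.character(syn$records$x) ==
                    as.character(syn$records$outcome)), 0.98)
})

test_that("degenerate single-category columns sample that category always", {
  x <- cohort(data.frame(k = rep("only", 50),
                         outcome = rep(c("0", "1"), 25),
                         stringsAsFactors = FALSE),
              list(variable_meta("k", "categorical", "core_predictor",
                                 categories = "only"),
                   variable_meta("outcome", "categorical", "outcome",
                                 categories = c("0", "1"))),
              dataset_id = "const")
  for (fitter in list(fit_sequential_trees, fit_bayesian_network)) {
    g <- fitter(x, seed = 1)
    syn <- generate(g, n_rows = 200, n_replicates = 1,
                    seed = 1)$replicates[[1]]
    expect_true(all(as.character(syn$records$k) == "only"))
  }
})

test_that("independent marginals match training frequencies and reproduce
           the missingness rate", {
  x <- toy_cohort(n = 500, seed = 3)
  x$records$age[1:50] <- NA  # 10% missing
  im <- fit_independent_marginals(x, seed = 1)
  syn <- generate(im, n_rows = 20000, n_replicates = 1,
                  seed = 7)$replicates[[1]]
  p_train <- mean(x$records$sex == "f", na.rm = TRUE)
  p_syn <- mean(syn$records$sex == "f", na.rm = TRUE)
  expect_lt(abs(p_syn - p_train),
            3 * sqrt(p_train * (1 - p_train) / 20000))
  expect_lt(abs(mean(is.na(syn$records$age)) - 0.1),
            3 * sqrt(0.1 * 0.9 / 20000))
})

test_that("univariate synthetic marginals stay within TV 0.05 of training
           for both fitted generators", {
  spec <- cohort_spec(n_records = 10000, n_core_predictors = 4,
                      adjunct_pool_size = 0, missing_rate = 0.05,
                      seed = 17, dataset_id = "tv")
  x <- simulate_cohort(spec)$cohort
  for (fitter in list(fit_sequential_trees, fit_bayesian_network)) {
    g <- fitter(x, seed = 2)
    syn <- generate(g, n_rows = 10000, n_replicates = 1,
                    seed = 3)$replicates[[1]]
    for (nm in names(x$records)) {
      if (x$meta[[nm]]$vtype != "categorical") next
      a <- addNA(x$records[[nm]], ifany = TRUE)
      b <- addNA(syn$records[[nm]], ifany = TRUE)
      expect_lt(tv_distance(a, b), 0.05)
    }
  }
})

test_that("generation contract: sizes, schema, master-seed determinism", {
  x <- toy_cohort(n = 120)
  st <- fit_sequential_trees(x, seed = 1)
  ens <- generate(st, n_rows = 50, n_replicates = 3, seed = 11)
  expect_length(ens$replicates, 3)
  for (r in ens$replicates) {
    expect_identical(nrow(r$records), 50L)
    expect_identical(names(r$records), names(x$records))
  }
  ens2 <- generate(st, n_rows = 50, n_replicates = 3, seed = 11)
  expect_identical(lapply(ens$replicates, `[[`, "records"),
                   lapply(ens2$replicates, `[[`, "records"))
  expect_error(generate(st, n_rows = 0), "positive")
})

test_that("sequential synthesis of a variant table covers exactly its
           columns; evaluation subsets come from projection, not refits", {
  spec <- cohort_spec(n_records = 800, n_core_predictors = 3,
                      adjunct_pool_size = 4, seed = 3, dataset_id = "projk")
  pop <- simulate_cohort(spec)$cohort
  v <- variant_spec("projk", core_names(pop), c("a1", "a3"))
  train_v <- project_variant(pop, v)
  st <- fit_sequential_trees(train_v, seed = 1)
  syn <- generate(st, n_rows = 100, n_replicates = 1,
                  seed = 1)$replicates[[1]]
  expect_setequal(names(syn$records),
                  c(core_names(pop), "a1", "a3", "outcome"))
  core_view <- project_core(syn)
  expect_setequal(names(core_view$records), c(core_names(pop), "outcome"))
})

test_that("the plugin contract wraps an external sampler with schema
           guarantees", {
  x <- toy_cohort(n = 60)
  shuffler <- plugin_generator("shuffle",
    fit_fn = function(train, seed) train$records,
    sample_fn = function(state, n, seed) {
      set.seed(seed)
      state[sample.int(nrow(state), n, replace = TRUE), , drop = FALSE]
    })
  fitted <- shuffler$fit(x, seed = 2)
  ens <- generate(fitted, n_rows = 40, n_replicates = 2, seed = 3)
  expect_identical(ens$generator_id, "shuffle")
  expect_identical(names(ens$replicates[[1]]$records), names(x$records))
})
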