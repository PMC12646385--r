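test_that("cohort validation enforces the schema invariants", {
  expect_s3_class(toy_cohort(), "cohort")

  # no outcome role
  expect_error(
    cohort(data.frame(a = 1:3),
           list(variable_meta("a", "continuous", "core_predictor"))),
    "outcome")
  # non-binary outcome
  expect_error(
    cohort(data.frame(y = c("a", "b", "c")),
           list(variable_meta("y", "categorical", "outcome",
                              categories = c("a", "b", "c")))),
    "binary")
  # column/metadata mismatch
  expect_error(
    cohort(data.frame(a = 1:3, y = c("0", "1", "0")),
           list(variable_meta("y", "categorical", "outcome",
                              categories = c("0", "1")))),
    "mismatch")
  # undeclared category
  expect_error(
    cohort(data.frame(g = c("x", "zzz"), y = c("0", "1")),
           list(variable_meta("g", "categorical", "core_predictor",
                              categories = c("x")),
                variable_meta("y", "categorical", "outcome",
                              categories = c("0", "1")))),
    "undeclared")
  # two parameters of interest
  expect_error(
    cohort(data.frame(a = 1:2, b = 1:2, y = c("0", "1")),
           list(variable_meta("a", "continuous", "core_predictor",
                              is_parameter_of_interest = TRUE),
                variable_meta("b", "continuous", "core_predictor",
                              is_parameter_of_interest = TRUE),
                variable_meta("y", "categorical", "outcome",
                              categories = c("0", "1")))),
    "parameter")
})

test_that("write/read round-trip is the identity, including missing cells and
           a categorical category named '0'", {
  x <- toy_cohort(n = 12, with_missing = TRUE)
  # a categorical whose categories are the strings "0"/"1", next to a
  # continuous column holding the number 0
  x$records$extra <- NULL; x$meta$extra <- NULL
  x <- cohort(cbind(x$records,
                    flag = sample(c("0", "1"), 12, replace = TRUE),
                    zero = rep(0, 12)),
              c(x$meta,
                list(variable_meta("flag", "categorical", "adjunct",
                                   categories = c("0", "1")),
                     variable_meta("zero", "continuous", "adjunct"))),
              dataset_id = "toy")
  tmp_csv <- tempfile(fileext = ".csv"); tmp_json <- tempfile(fileext = ".json")
  write_cohort(x, tmp_csv, tmp_json)
  y <- read_cohort(tmp_csv, tmp_json)

  expect_identical(y$dataset_id, x$dataset_id)
  expect_identical(names(y$records), names(x$records))
  expect_identical(y$records, x$records)
  expect_identical(y$meta, x$meta)
  expect_true(is.factor(y$records$flag))     # "0" stayed categorical
  expect_true(is.numeric(y$records$zero))    # 0 stayed continuous
  expect_true(is.na(y$records$age[1]))       # missing survived as empty field
  # empty field on disk
  raw <- readLines(tmp_csv)
  expect_match(raw[2], "^,")  # first data row starts with the blank age cell
})

test_that("core-only cohort round-trips with only core roles in metadata", {
  x <- signal_cohort(n = 5)
  tmp_csv <- tempfile(fileext = ".csv"); tmp_json <- tempfile(fileext = ".json")
  write_cohort(x, tmp_csv, tmp_json)
  y <- read_cohort(tmp_csv, tmp_json)
  expect_setequal(unname(vapply(y$meta, `[[`, character(1), "role")),
                  c("core_predictor", "outcome"))
})

test_that("train/holdout split has exact disjoint sizes and is deterministic", {
  x <- toy_cohort(n = 40)
  sp <- split_train_holdout(x, 15, 20, seed = 9)
  expect_length(sp$train_ids, 15)
  expect_length(sp$holdout_ids, 20)
  expect_length(intersect(sp$train_ids, sp$holdout_ids), 0)
  expect_true(all(c(sp$train_ids, sp$holdout_ids) %in% seq_len(40)))

  sp2 <- split_train_holdout(x, 15, 20, seed = 9)
  expect_identical(sp, sp2)

  expect_error(split_train_holdout(x, 21, 20, seed = 9), "exceeds")
})

test_that("the split depends on (dataset_id, seed) only, not on the variant", {
  spec <- cohort_spec(n_records = 400, n_core_predictors = 3,
                      adjunct_pool_size = 3, seed = 2, dataset_id = "dsA")
  pop <- simulate_cohort(spec)$cohort
  v_narrow <- variant_spec("dsA", core_names(pop))
  v_wide <- variant_spec("dsA", core_names(pop), adjunct_names(pop))
  sp_narrow <- split_train_holdout(project_variant(pop, v_narrow), 100, 100, 5)
  sp_wide <- split_train_holdout(project_variant(pop, v_wide), 100, 100, 5)
  expect_identical(sp_narrow, sp_wide)
})

test_that("metric table round-trips through CSV", {
  tab <- simulated_metric_table(n_datasets = 2, n_variants = 5)
  tmp <- tempfile(fileext = ".csv")
  write_metric_table(tab, tmp)
  back <- read_metric_table(tmp)
  expect_equal(back$value, tab$value)
  expect_identical(back$dataset_id, tab$dataset_id)
})

test_that("derived child seeds are deterministic and decoupled across tags", {
  expect_identical(derive_seed(42, "a", 1), derive_seed(42, "a", 1))
  expect_false(derive_seed(42, "a", 1) == derive_seed(42, "a", 2))
  expect_false(derive_seed(42, "a") == derive_seed(43, "a"))
  s <- derive_seed(2^30, "x", "y", 99)
  expect_true(s >= 0 && s < 2^31 - 1)
})
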