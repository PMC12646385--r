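#' Area under the ROC curve by the rank statistic
#'
#' Computes AUROC as the Wilcoxon-Mann-Whitney rank statistic with tie
#' correction (midranks): the probability that a randomly chosen positive
#' scores above a randomly chosen negative, counting ties as 1/2.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (logical, 0/1, or a 2-level factor whose
#'   second level is the positive class).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("AUROC undefined: labels contain one class")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Default TSTR classifier specifications
#'
#' Two probabilistic binary classifiers for the train-on-synthetic
#' test-on-real evaluation: (a) gradient-boosted trees with a small
#' hyperparameter grid tuned by 5-fold cross-validation optimizing AUROC on
#' the (synthetic) training replicate, and (b) a single-hidden-layer
#' feed-forward network with a fixed architecture and weight decay as the
#' overfitting control, no grid search.
#'
#' @param gbm_grid Data.frame of gradient-boosting hyperparameter
#'   combinations (columns `max_depth`, `eta`); kept small by default.
#' @param gbm_nrounds Boosting rounds.
#' @param cv_folds Cross-validation folds for the boosted-tree grid.
#' @param mlp_size,mlp_decay,mlp_maxit Network width, weight decay, and
#'   optimizer iteration cap.
#' @return A named list of classifier specs (`gbm`, `mlp`), each usable as
#'   the `classifier_spec` of [tstr_auroc()].
#' @export
default_classifiers <- function(gbm_grid = expand.grid(max_depth = c(3L, 6L),
                                                       eta = c(0.1, 0.3)),
                                gbm_nrounds = 100L, cv_folds = 5L,
                                mlp_size = 8L, mlp_decay = 0.1,
                                mlp_maxit = 150L) {
  list(
    gbm = list(id = "gbm", grid = gbm_grid, nrounds = gbm_nrounds,
               cv_folds = cv_folds),
    mlp = list(id = "mlp", size = mlp_size, decay = mlp_decay,
               maxit = mlp_maxit)
  )
}

# Integer-code design matrix for tree boosting; xgboost handles NA natively.
encode_codes <- function(records, meta, predictors) {
  X <- vapply(predictors, function(nm) {
    v <- records[[nm]]
    if (meta[[nm]]$vtype == "categorical")
      as.numeric(factor(as.character(v), levels = meta[[nm]]$categories))
    else as.numeric(v)
  }, numeric(nrow(records)))
  matrix(X, nrow = nrow(records),
         dimnames = list(NULL, predictors))
}

outcome01 <- function(x) {
  m <- x$meta[[outcome_name(x)]]
  as.numeric(as.character(x$records[[outcome_name(x)]]) == m$categories[2])
}

fit_gbm <- function(train, spec, seed) {
  preds <- setdiff(names(train$records), outcome_name(train))
  X <- encode_codes(train$records, train$meta, preds)
  y <- outcome01(train)
  grid <- spec$grid
  best <- 1L
  if (nrow(grid) > 1L) {
    folds <- with_seed(derive_seed(seed, "gbmcv"),
                       sample(rep_len(seq_len(spec$cv_folds), nrow(X))))
    cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
      aucs <- vapply(seq_len(spec$cv_folds), function(f) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2)
          return(NA_real_)
        fit <- xgb_fit(X[tr, , drop = FALSE], y[tr], grid$max_depth[g],
                       grid$eta[g], spec$nrounds)
        auroc(xgb_predict(fit, X[!tr, , drop = FALSE]), y[!tr])
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(cv_auc)
  }
  fit <- xgb_fit(X, y, grid$max_depth[best], grid$eta[best], spec$nrounds)
  list(predict = function(newdata) {
    Xn <- encode_codes(newdata$records, newdata$meta, preds)
    xgb_predict(fit, Xn)
  })
}

# Thin wrappers over xgboost's low-level trainer (API stable across
# xgboost releases); single-threaded for reproducibility.
xgb_fit <- function(X, y, max_depth, eta, nrounds) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   max_depth = max_depth, eta = eta,
                                   nthread = 1),
                     data = dtrain, nrounds = nrounds, verbose = 0)
}

xgb_predict <- function(fit, X)
  predict(fit, xgboost::xgb.DMatrix(X, nthread = 1))

# One-hot + standardized design for the network; missing values imputed with
# the TRAINING median/mode only (the holdout never leaks into training).
mlp_design <- function(records, meta, predictors, stats_env = NULL) {
  cols <- list()
  for (nm in predictors) {
    v <- records[[nm]]
    if (meta[[nm]]$vtype == "categorical") {
      v <- factor(as.character(v), levels = meta[[nm]]$categories)
      if (is.null(stats_env$mode[[nm]])) {
        tb <- table(v)
        stats_env$mode[[nm]] <- if (sum(tb)) names(tb)[which.max(tb)]
          else meta[[nm]]$categories[1]
      }
      v[is.na(v)] <- stats_env$mode[[nm]]
      for (lev in meta[[nm]]$categories[-1])
        cols[[paste0(nm, "=", lev)]] <- as.numeric(v == lev)
    } else {
      v <- as.numeric(v)
      if (is.null(stats_env$med[[nm]])) {
        stats_env$med[[nm]] <- stats::median(v, na.rm = TRUE)
        if (is.na(stats_env$med[[nm]])) stats_env$med[[nm]] <- 0
        v2 <- v; v2[is.na(v2)] <- stats_env$med[[nm]]
        stats_env$mu[[nm]] <- mean(v2)
        stats_env$sig[[nm]] <- max(stats::sd(v2), 1e-8)
      }
      v[is.na(v)] <- stats_env$med[[nm]]
      cols[[nm]] <- (v - stats_env$mu[[nm]]) / stats_env$sig[[nm]]
    }
  }
  do.call(cbind, cols)
}

fit_mlp <- function(train, spec, seed) {
  preds <- setdiff(names(train$records), outcome_name(train))
  st <- new.env(); st$mode <- list(); st$med <- list()
  st$mu <- list(); st$sig <- list()
  X <- mlp_design(train$records, train$meta, preds, st)
  y <- outcome01(train)
  fit <- with_seed(derive_seed(seed, "mlp"),
                   nnet::nnet(X, y, size = spec$size, decay = spec$decay,
                              maxit = spec$maxit, entropy = TRUE,
                              trace = FALSE, MaxNWts = 10000))
  list(predict = function(newdata) {
    Xn <- mlp_design(newdata$records, newdata$meta, preds, st)
    as.numeric(predict(fit, Xn))
  })
}

fit_classifier <- function(train, spec, seed) {
  switch(spec$id,
         gbm = fit_gbm(train, spec, seed),
         mlp = fit_mlp(train, spec, seed),
         stop("unknown classifier id: ", spec$id))
}

#' Train-on-synthetic-test-on-real AUROC
#'
#' For each synthetic replicate, fits the configured probabilistic binary
#' classifier on the replicate's core columns, scores the real holdout, and
#' computes AUROC; the per-replicate values are averaged. A replicate whose
#' synthetic outcome collapses to a single class cannot train a classifier:
#' it is skipped with a warning and recorded as missing. A single-class
#' holdout makes AUROC undefined and is an error.
#'
#' @param ensemble A `synthetic_ensemble`.
#' @param holdout Real holdout [cohort()] (disjoint from training by the
#'   split contract).
#' @param classifier_spec One entry of [default_classifiers()].
#' @param seed Seed for classifier fitting.
#' @param core_only Evaluate on core columns only (the conventional scope)?
#' @return A list of class `tstr_result` with `mean_auroc`,
#'   `per_replicate_auroc`, and `classifier_id`.
#' @export
tstr_auroc <- function(ensemble, holdout, classifier_spec = NULL, seed = 1,
                       core_only = TRUE) {
  if (is.null(classifier_spec)) classifier_spec <- default_classifiers()$gbm
  if (core_only) holdout <- project_core(holdout)
  y_h <- outcome01(holdout)
  if (length(unique(y_h)) < 2)
    stop("holdout outcome contains a single class; AUROC undefined")
  per <- vapply(seq_along(ensemble$replicates), function(r) {
    syn <- ensemble$replicates[[r]]
    if (core_only) syn <- project_core(syn)
    if (length(unique(outcome01(syn))) < 2) {
      warning("replicate ", r, ": synthetic outcome single-class; skipped")
      return(NA_real_)
    }
    clf <- fit_classifier(syn, classifier_spec,
                          derive_seed(seed, "tstr", r))
    auroc(clf$predict(holdout), y_h)
  }, numeric(1))
  structure(list(mean_auroc = mean(per, na.rm = TRUE),
                 per_replicate_auroc = per,
                 classifier_id = classifier_spec$id),
            class = "tstr_result")
}

#' Train-on-real-test-on-real reference AUROC
#'
#' The same classifier protocol applied to the real training data; the
#' natural upper reference for [tstr_auroc()].
#'
#' @param train Real training [cohort()].
#' @param holdout Real holdout [cohort()].
#' @param classifier_spec,seed,core_only As in [tstr_auroc()].
#' @return AUROC (scalar).
#' @export
trtr_auroc <- function(train, holdout, classifier_spec = NULL, seed = 1,
                       core_only = TRUE) {
  if (is.null(classifier_spec)) classifier_spec <- default_classifiers()$gbm
  if (core_only) { train <- project_core(train); holdout <- project_core(holdout) }
  y_h <- outcome01(holdout)
  if (length(unique(y_h)) < 2)
    stop("holdout outcome contains a single class; AUROC undefined")
  clf <- fit_classifier(train, classifier_spec, derive_seed(seed, "trtr"))
  auroc(clf$predict(holdout), y_h)
}
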