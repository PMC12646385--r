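#' @import tree
NULL

MISS_LEVEL <- ".missing"

# ---------------------------------------------------------------------------
# Internal modeling frame
#
# Generators never see NA directly. Categorical columns get an explicit
# ".missing" level; each continuous column with any training missingness is
# paired with a categorical companion flag ("obs"/"miss") placed immediately
# before it in the modeling order, and its missing values are median-imputed
# for modeling. On synthesis the flag re-blanks the value, so missingness
# rates survive into the synthetic output.
# ---------------------------------------------------------------------------

encode_frame <- function(x, visit_order = NULL) {
  nm_all <- names(x$records)
  if (is.null(visit_order)) {
    out_nm <- outcome_name(x)
    visit_order <- c(setdiff(nm_all, out_nm), out_nm)  # outcome last
  }
  if (!setequal(visit_order, nm_all))
    stop("visit_order must be a permutation of the cohort's columns")
  data <- list(); plan <- list()
  for (nm in visit_order) {
    m <- x$meta[[nm]]
    v <- x$records[[nm]]
    if (m$vtype == "categorical") {
      f <- factor(ifelse(is.na(as.character(v)), MISS_LEVEL, as.character(v)),
                  levels = c(m$categories, MISS_LEVEL))
      data[[nm]] <- f
      plan[[nm]] <- list(name = nm, kind = "factor", orig = nm, role = "value")
    } else {
      if (anyNA(v)) {
        fn <- paste0(nm, "__miss")
        data[[fn]] <- factor(ifelse(is.na(v), "miss", "obs"),
                             levels = c("obs", "miss"))
        plan[[fn]] <- list(name = fn, kind = "factor", orig = nm,
                           role = "missflag")
        med <- stats::median(v, na.rm = TRUE)
        v[is.na(v)] <- med
      }
      data[[nm]] <- v
      plan[[nm]] <- list(name = nm, kind = "numeric", orig = nm, role = "value")
    }
  }
  list(data = as.data.frame(data, stringsAsFactors = FALSE), plan = plan)
}

# Invert encode_frame: internal frame -> cohort with the training schema.
decode_frame <- function(data, plan, schema, dataset_id) {
  records <- list()
  for (pl in plan) {
    if (pl$role != "value") next
    v <- data[[pl$name]]
    m <- schema[[pl$orig]]
    if (m$vtype == "categorical") {
      v <- as.character(v)
      v[v == MISS_LEVEL] <- NA
      v <- factor(v, levels = m$categories)
    } else {
      fn <- paste0(pl$orig, "__miss")
      if (!is.null(data[[fn]])) v[data[[fn]] == "miss"] <- NA
    }
    records[[pl$orig]] <- v
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records <- records[, names(schema), drop = FALSE]
  cohort(records, schema, dataset_id)
}

sample_donors <- function(donors, n) donors[sample.int(length(donors), n,
                                                       replace = TRUE)]

# ---------------------------------------------------------------------------
# Sequential decision trees
# ---------------------------------------------------------------------------

#' Fit a sequential-decision-tree generator
#'
#' Synthesizes one variable at a time, conditional on the previously
#' generated ones: the first variable in the visit order is modeled by its
#' empirical marginal; each later variable by a CART tree (classification for
#' categoricals, regression for continuous) on its predecessors. Each leaf
#' stores the donor values of the training rows reaching it, and synthesis
#' samples a donor from the leaf a partial synthetic record lands in — so
#' continuous values stay in the observed support.
#'
#' @param train Training [cohort()] (at least 2 rows).
#' @param visit_order Permutation of column names (default: metadata order
#'   with the outcome last).
#' @param tree_controls List of CART controls: `mincut` (minimum leaf size,
#'   default 5), `mindev` (minimum within-node deviance fraction to attempt a
#'   split, default 0.002).
#' @param seed Fit seed.
#' @return A `fitted_generator` of subclass `st_generator`.
#' @export
fit_sequential_trees <- function(train, visit_order = NULL,
                                 tree_controls = list(), seed = 1) {
  validate_cohort(train)
  if (nrow(train$records) < 2) stop("need at least 2 training rows")
  ctl <- utils::modifyList(list(mincut = 5, mindev = 0.002), tree_controls)
  enc <- encode_frame(train, visit_order)
  cols <- names(enc$data)
  n <- nrow(enc$data)
  models <- vector("list", length(cols))
  names(models) <- cols
  for (j in seq_along(cols)) {
    y <- enc$data[[j]]
    marginal <- y  # donor pool for the no-predecessor / fallback path
    if (j == 1L || is_degenerate(y)) {
      models[[j]] <- list(type = "marginal", donors = marginal)
      next
    }
    df <- enc$data[, seq_len(j), drop = FALSE]
    names(df)[j] <- ".y"
    fit <- tryCatch(
      tree::tree(.y ~ ., data = df,
                 control = tree::tree.control(n, mincut = ctl$mincut,
                                              minsize = 2 * ctl$mincut,
                                              mindev = ctl$mindev)),
      error = function(e) NULL)
    if (is.null(fit) || nrow(fit$frame) == 1L) {
      models[[j]] <- list(type = "marginal", donors = marginal)
    } else {
      leaf <- fit$where
      models[[j]] <- list(type = "tree", fit = strip_tree(fit),
                          pools = split(y, leaf), donors = marginal)
    }
  }
  structure(list(generator_id = "st", schema = train$meta,
                 dataset_id = train$dataset_id, models = models,
                 plan = enc$plan, columns = cols, fit_seed = seed),
            class = c("st_generator", "fitted_generator"))
}

is_degenerate <- function(y) {
  u <- unique(y)
  length(u[!is.na(u)]) < 2L
}

# Drop the stored training data from a tree object; routing only needs the
# frame and split structure.
strip_tree <- function(fit) {
  attr(fit, "where") <- NULL
  fit$y <- NULL
  fit$weights <- NULL
  fit
}

sample_rows <- function(fitted, n, seed) UseMethod("sample_rows")

#' @export
sample_rows.st_generator <- function(fitted, n, seed) {
  with_seed(seed, {
    data <- list()
    for (j in seq_along(fitted$columns)) {
      nm <- fitted$columns[j]
      mod <- fitted$models[[nm]]
      if (mod$type == "marginal") {
        data[[nm]] <- sample_donors(mod$donors, n)
      } else {
        partial <- as.data.frame(data[seq_len(j - 1L)],
                                 stringsAsFactors = FALSE)
        leaf <- predict(mod$fit, newdata = partial, type = "where")
        v <- rep(mod$donors[1], n)
        for (lf in unique(leaf)) {
          rows <- which(leaf == lf)
          pool <- mod$pools[[as.character(lf)]]
          if (is.null(pool) || !length(pool)) pool <- mod$donors
          v[rows] <- sample_donors(pool, length(rows))
        }
        data[[nm]] <- v
      }
    }
    decode_frame(as.data.frame(data, stringsAsFactors = FALSE), fitted$plan,
                 fitted$schema, fitted$dataset_id)
  })
}

# ---------------------------------------------------------------------------
# Chow-Liu Bayesian network
# ---------------------------------------------------------------------------

#' Fit a Bayesian-network generator (Chow-Liu tree)
#'
#' Continuous variables are discretized into equal-frequency bins; the
#' network structure is the maximum spanning tree on pairwise mutual
#' information (Chow-Liu), rooted at the first variable and oriented away
#' from the root to form a DAG. Conditional probability tables use add-alpha
#' smoothing. Sampling is ancestral; sampled bins of continuous variables are
#' re-materialized by a uniform draw within the bin's observed training
#' range.
#'
#' @param train Training [cohort()] (at least 2 rows).
#' @param seed Fit seed.
#' @param max_bins Maximum number of equal-frequency bins per continuous
#'   variable.
#' @param alpha Additive smoothing count for the conditional tables.
#' @return A `fitted_generator` of subclass `bn_generator`.
#' @export
fit_bayesian_network <- function(train, seed = 1, max_bins = 10, alpha = 0.5) {
  validate_cohort(train)
  if (nrow(train$records) < 2) stop("need at least 2 training rows")
  nm_all <- names(train$records)
  disc <- list(); bins <- list()
  for (nm in nm_all) {
    m <- train$meta[[nm]]
    v <- train$records[[nm]]
    if (m$vtype == "categorical") {
      lev <- c(m$categories, MISS_LEVEL)
      # unseen categories are dropped so add-alpha smoothing never
      # hallucinates values absent from the training data
      disc[[nm]] <- droplevels(factor(ifelse(is.na(as.character(v)),
                                             MISS_LEVEL, as.character(v)),
                                      levels = lev))
      bins[[nm]] <- NULL
    } else {
      obs <- v[!is.na(v)]
      k <- max(1L, min(max_bins, length(unique(obs))))
      br <- unique(stats::quantile(obs, probs = seq(0, 1, length.out = k + 1),
                                   names = FALSE))
      if (length(br) < 2) br <- c(br, br + 1e-9)
      idx <- findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
      lab <- paste0("bin", seq_len(length(br) - 1L))
      f <- droplevels(factor(ifelse(is.na(v), MISS_LEVEL, lab[idx]),
                             levels = c(lab, MISS_LEVEL)))
      disc[[nm]] <- f
      # per-bin observed range for re-materialization
      rng <- lapply(seq_along(lab), function(b) {
        vals <- v[!is.na(v) & idx == b]
        if (!length(vals)) c(br[b], br[b + 1]) else range(vals)
      })
      names(rng) <- lab
      bins[[nm]] <- rng
    }
  }
  disc <- as.data.frame(disc, stringsAsFactors = FALSE)

  p <- length(nm_all)
  parent <- rep(NA_integer_, p)
  order_bfs <- 1L
  if (p > 1) {
    miv <- matrix(0, p, p)
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      miv[i, j] <- miv[j, i] <- discrete_mi(disc[[i]], disc[[j]])
    }
    g <- igraph::graph_from_adjacency_matrix(max(miv) + 1 - miv,
                                             mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    mstree <- igraph::mst(g)
    adj <- igraph::as_adj_list(mstree)
    # BFS from node 1, orienting edges away from the root
    visited <- rep(FALSE, p); visited[1] <- TRUE
    queue <- 1L; order_bfs <- 1L
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in as.integer(adj[[u]])) if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- u
        order_bfs <- c(order_bfs, w)
        queue <- c(queue, w)
      }
    }
  }

  cpts <- vector("list", p)
  for (v in order_bfs) {
    lev <- levels(disc[[v]])
    if (is.na(parent[v])) {
      cnt <- table(disc[[v]]) + alpha
      cpts[[v]] <- list(kind = "root", prob = as.numeric(cnt / sum(cnt)),
                        levels = lev)
    } else {
      tab <- table(disc[[parent[v]]], disc[[v]]) + alpha
      prob <- sweep(tab, 1, rowSums(tab), "/")
      cpts[[v]] <- list(kind = "child", prob = unclass(prob), levels = lev)
    }
  }

  structure(list(generator_id = "bn", schema = train$meta,
                 dataset_id = train$dataset_id, columns = nm_all,
                 parent = parent, topo = order_bfs, cpts = cpts, bins = bins,
                 mi_used = if (p > 1) miv else NULL, fit_seed = seed),
            class = c("bn_generator", "fitted_generator"))
}

# Plug-in mutual information of two factors (complete cases, natural log).
discrete_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  if (n == 0) return(0)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
}

#' @export
sample_rows.bn_generator <- function(fitted, n, seed) {
  with_seed(seed, {
    p <- length(fitted$columns)
    cells <- vector("list", p)
    for (v in fitted$topo) {
      cpt <- fitted$cpts[[v]]
      lev <- cpt$levels
      if (cpt$kind == "root") {
        cells[[v]] <- lev[sample.int(length(lev), n, replace = TRUE,
                                     prob = cpt$prob)]
      } else {
        pa <- cells[[fitted$parent[v]]]
        out <- character(n)
        for (pl in unique(pa)) {
          rows <- which(pa == pl)
          pr <- cpt$prob[pl, ]
          out[rows] <- lev[sample.int(length(lev), length(rows),
                                      replace = TRUE, prob = pr)]
        }
        cells[[v]] <- out
      }
    }
    records <- list()
    for (j in seq_len(p)) {
      nm <- fitted$columns[j]
      m <- fitted$schema[[nm]]
      v <- cells[[j]]
      if (m$vtype == "categorical") {
        v[v == MISS_LEVEL] <- NA
        records[[nm]] <- factor(v, levels = m$categories)
      } else {
        out <- rep(NA_real_, n)
        rng <- fitted$bins[[nm]]
        for (b in names(rng)) {
          rows <- which(v == b)
          if (length(rows))
            out[rows] <- stats::runif(length(rows), rng[[b]][1], rng[[b]][2])
        }
        records[[nm]] <- out
      }
    }
    cohort(as.data.frame(records, stringsAsFactors = FALSE), fitted$schema,
           fitted$dataset_id)
  })
}

# ---------------------------------------------------------------------------
# Baselines
# ---------------------------------------------------------------------------

#' Fit an independent-marginals baseline generator
#'
#' Each column is sampled independently from its empirical marginal
#' (including missing values at their training rate), deliberately breaking
#' all joint structure. Useful as a low-fidelity / low-disclosure contrast.
#'
#' @param train Training [cohort()].
#' @param seed Fit seed.
#' @return A `fitted_generator` of subclass `independent_generator`.
#' @export
fit_independent_marginals <- function(train, seed = 1) {
  validate_cohort(train)
  structure(list(generator_id = "independent", schema = train$meta,
                 dataset_id = train$dataset_id,
                 donors = as.list(train$records), fit_seed = seed),
            class = c("independent_generator", "fitted_generator"))
}

#' @export
sample_rows.independent_generator <- function(fitted, n, seed) {
  with_seed(seed, {
    records <- lapply(fitted$donors, function(col)
      col[sample.int(length(col), n, replace = TRUE)])
    cohort(as.data.frame(records, stringsAsFactors = FALSE), fitted$schema,
           fitted$dataset_id)
  })
}

#' Fit a copy ("bootstrap of training rows") generator
#'
#' Emits bootstrap resamples of the actual training records. This is a test
#' harness, not a synthesizer: it maximizes membership-disclosure
#' vulnerability and provides the reference point against which real
#' generators must look safer, and its train-on-synthetic performance matches
#' train-on-real by construction.
#'
#' @param train Training [cohort()].
#' @param seed Fit seed.
#' @return A `fitted_generator` of subclass `copy_generator`.
#' @export
fit_copy_generator <- function(train, seed = 1) {
  validate_cohort(train)
  structure(list(generator_id = "copy", schema = train$meta,
                 dataset_id = train$dataset_id, rows = train$records,
                 fit_seed = seed),
            class = c("copy_generator", "fitted_generator"))
}

#' @export
sample_rows.copy_generator <- function(fitted, n, seed) {
  with_seed(seed, {
    idx <- sample.int(nrow(fitted$rows), n, replace = TRUE)
    rec <- fitted$rows[idx, , drop = FALSE]
    rownames(rec) <- NULL
    cohort(rec, fitted$schema, fitted$dataset_id)
  })
}

#' Wrap an external generative model as a plugin generator
#'
#' Deep tabular models (GANs, VAEs, normalizing flows, adversarial random
#' forests, ...) are not reimplemented here; they plug in through this
#' contract: a `fit_fn(train, seed)` returning any state object, and a
#' `sample_fn(state, n, seed)` returning a data.frame with the training
#' schema. The wrapper enforces the schema guarantee on every sample.
#'
#' @param generator_id Identifier used in metric tables.
#' @param fit_fn Function `(train, seed) -> state`.
#' @param sample_fn Function `(state, n, seed) -> data.frame`.
#' @return A generator factory; call `$fit(train, seed)` to obtain a
#'   `fitted_generator` of subclass `plugin_generator`.
#' @export
plugin_generator <- function(generator_id, fit_fn, sample_fn) {
  list(generator_id = generator_id,
       fit = function(train, seed = 1) {
         validate_cohort(train)
         structure(list(generator_id = generator_id, schema = train$meta,
                        dataset_id = train$dataset_id,
                        state = fit_fn(train, seed), sample_fn = sample_fn,
                        fit_seed = seed),
                   class = c("plugin_generator", "fitted_generator"))
       })
}

#' @export
sample_rows.plugin_generator <- function(fitted, n, seed) {
  rec <- fitted$sample_fn(fitted$state, n, seed)
  cohort(rec, fitted$schema, fitted$dataset_id)
}

# ---------------------------------------------------------------------------
# Ensemble generation
# ---------------------------------------------------------------------------

#' Generate a synthetic ensemble
#'
#' Draws `n_replicates` independent synthetic cohorts of `n_rows` each from a
#' fitted generator (default: 10 replicates of training size — the standard
#' practice of generating several synthetic datasets per trained model to
#' account for the stochasticity of synthesis). Each replicate uses its own
#' derived child seed, so replicates differ from each other but the whole
#' ensemble is reproducible from the master seed.
#'
#' @param fitted A `fitted_generator`.
#' @param n_rows Rows per replicate (default: training size stored in the
#'   generator where available, else 10000).
#' @param n_replicates Number of replicates (default 10).
#' @param seed Master seed for generation.
#' @return A `synthetic_ensemble`: list of cohorts plus provenance fields.
#' @export
generate <- function(fitted, n_rows = NULL, n_replicates = 10, seed = 1) {
  stopifnot(inherits(fitted, "fitted_generator"))
  if (is.null(n_rows)) {
    n_rows <- if (!is.null(fitted$rows)) nrow(fitted$rows)
      else if (!is.null(fitted$donors)) length(fitted$donors[[1]])
      else 10000
  }
  if (n_rows <= 0) stop("n_rows must be positive")
  reps <- lapply(seq_len(n_replicates), function(r)
    sample_rows(fitted, n_rows,
                derive_seed(seed, "generate", fitted$generator_id,
                            fitted$dataset_id, r)))
  structure(list(replicates = reps, generator_id = fitted$generator_id,
                 dataset_id = fitted$dataset_id, generation_seed = seed),
            class = "synthetic_ensemble")
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat("<synthetic_ensemble> ", length(x$replicates), " replicates of ",
      nrow(x$replicates[[1]]$records), " rows from generator '",
      x$generator_id, "'\n", sep = "")
  invisible(x)
}
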