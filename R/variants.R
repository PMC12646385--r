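#' Population variants: core set plus one adjunct subset
#'
#' A variant identifies one training population: the fixed core variables plus
#' one particular subset of the adjunct pool (possibly empty). Variants are the
#' unit along which the number of task-irrelevant variables is varied.
#'
#' @param dataset_id Dataset identifier.
#' @param core Character vector of core variable names (ordered).
#' @param adjunct_subset Character vector (possibly empty) of adjunct names.
#' @return A `variant_spec` list with fields `dataset_id`, `core_names`,
#'   `adjunct_subset`, `k_adjunct`, and a stable `variant_id`.
#' @export
variant_spec <- function(dataset_id, core, adjunct_subset = character(0)) {
  core <- as.character(core)
  adjunct_subset <- sort(as.character(adjunct_subset))
  if (length(intersect(core, adjunct_subset)))
    stop("adjunct subset overlaps the core set")
  structure(list(dataset_id = dataset_id, core_names = core,
                 adjunct_subset = adjunct_subset,
                 k_adjunct = length(adjunct_subset),
                 variant_id = paste0("k", length(adjunct_subset), "_",
                                     if (length(adjunct_subset))
                                       paste(adjunct_subset, collapse = "+")
                                     else "core")),
            class = "variant_spec")
}

#' Enumerate all adjunct-subset variants
#'
#' For small adjunct pools the whole combinatorial space is covered: all
#' `2^m` subsets of the pool, including the empty (core-only) subset. A pool
#' of 4 yields 16 variants, a pool of 5 yields 32. Output order is
#' deterministic: by subset size `k`, then lexicographic.
#'
#' @param core Character vector of core names.
#' @param pool Character vector of adjunct pool names.
#' @param dataset_id Dataset identifier attached to each variant.
#' @param enumerate_cap Refuse enumeration above this pool size (use
#'   [sample_variants()] instead).
#' @return List of [variant_spec()]s, length `2^m`.
#' @export
enumerate_variants <- function(core, pool, dataset_id = "cohort",
                               enumerate_cap = 14) {
  m <- length(pool)
  if (m > enumerate_cap)
    stop("pool size ", m, " exceeds the enumeration cap (", enumerate_cap,
         "); use sample_variants()")
  pool <- as.character(pool)
  out <- list(variant_spec(dataset_id, core))
  for (k in seq_len(m)) {
    combs <- utils::combn(sort(pool), k, simplify = FALSE)
    keys <- vapply(combs, paste, character(1), collapse = "+")
    for (s in combs[order(keys)])
      out[[length(out) + 1L]] <- variant_spec(dataset_id, core, s)
  }
  out
}

# Radical-inverse (van der Corput) digit reversal in the given base; the
# d-dimensional Halton sequence pairs one prime base per dimension.
radical_inverse <- function(i, base) {
  r <- 0; f <- 1 / base
  while (i > 0) {
    r <- r + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  r
}

halton_point <- function(i, bases)
  vapply(bases, function(b) radical_inverse(i, b), numeric(1))

first_primes <- function(d) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
              59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107, 109, 113,
              127, 131, 137, 139, 149, 151, 157, 163, 167, 173)
  if (d > length(primes)) stop("Halton sampling supports at most 40 dimensions")
  primes[seq_len(d)]
}

#' Sample adjunct-subset variants from a large pool
#'
#' When full enumeration is infeasible, subsets are sampled per size `k`:
#' for each `k` in `1..m-1` the number of distinct subsets equals
#' `min(max(per_k_target(k), min_per_k), choose(m, k))`; exactly one variant
#' at `k = m` (there is only one full-pool combination) and exactly one at
#' `k = 0` (the core-only population). Sampling is deterministic given the
#' seed and never produces duplicate subsets.
#'
#' The default per-k target scales with `log choose(m, k)`, allocating more
#' variants where the combinatorial space is larger, floored at `min_per_k`.
#'
#' @param core,pool,dataset_id As in [enumerate_variants()].
#' @param per_k_target Function of `k` giving the desired number of subsets
#'   of size `k`, or a single number used for all `k`.
#' @param min_per_k Lower bound on the number of variants per size.
#' @param seed Seed for subset sampling.
#' @param method `"random"` (uniform sampling without replacement) or
#'   `"halton"` (low-discrepancy coverage of the subset space via a Halton
#'   sequence: each point in `[0,1]^m` selects the k adjuncts with the
#'   largest coordinates).
#' @return List of [variant_spec()]s, sorted by `k` then lexicographically.
#' @export
sample_variants <- function(core, pool, per_k_target = NULL, min_per_k = 5,
                            seed = 1, dataset_id = "cohort",
                            method = c("random", "halton")) {
  method <- match.arg(method)
  m <- length(pool)
  if (m < 1) stop("pool must contain at least one adjunct variable")
  pool <- sort(as.character(pool))
  if (is.null(per_k_target)) {
    per_k_target <- function(k)
      max(min_per_k, ceiling(5 * log(choose(m, k))))
  } else if (is.numeric(per_k_target)) {
    tgt <- per_k_target
    per_k_target <- function(k) tgt
  }
  if (!is.function(per_k_target))
    stop("per_k_target must be a function of k (or a single number)")

  out <- list(variant_spec(dataset_id, core))       # k = 0
  for (k in seq_len(m)) {
    n_comb <- choose(m, k)
    n_take <- if (k == m) 1L
      else min(max(per_k_target(k), min_per_k), n_comb)
    if (n_comb <= 10000) {
      combs <- utils::combn(pool, k, simplify = FALSE)
      keys <- vapply(combs, paste, character(1), collapse = "+")
      combs <- combs[order(keys)]
      if (n_take >= n_comb) picked <- combs
      else if (method == "random") {
        picked <- with_seed(derive_seed(seed, "variants", dataset_id, k),
                            combs[sort(sample.int(n_comb, n_take))])
      } else {
        picked <- halton_subsets(pool, k, n_take, offset = k)
      }
    } else {
      picked <- if (method == "random")
        with_seed(derive_seed(seed, "variants", dataset_id, k),
                  reject_sample_subsets(pool, k, n_take))
      else halton_subsets(pool, k, n_take, offset = k)
    }
    for (s in picked) out[[length(out) + 1L]] <- variant_spec(dataset_id, core, s)
  }
  out
}

# Rejection-sample `n_take` distinct k-subsets uniformly.
reject_sample_subsets <- function(pool, k, n_take) {
  seen <- new.env(hash = TRUE)
  out <- vector("list", n_take)
  got <- 0L
  while (got < n_take) {
    s <- sort(sample(pool, k))
    key <- paste(s, collapse = "+")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      out[[got]] <- s
    }
  }
  out[order(vapply(out, paste, character(1), collapse = "+"))]
}

# Deterministic low-discrepancy k-subsets: consecutive Halton points in
# [0,1]^m, taking the k largest coordinates; duplicates skipped.
halton_subsets <- function(pool, k, n_take, offset = 0) {
  m <- length(pool)
  bases <- first_primes(m)
  out <- list(); seen <- new.env(hash = TRUE)
  i <- 1L + offset
  while (length(out) < n_take) {
    u <- halton_point(i, bases)
    s <- sort(pool[order(u, decreasing = TRUE)[seq_len(k)]])
    key <- paste(s, collapse = "+")
    if (is.null(seen[[key]])) { seen[[key]] <- TRUE; out[[length(out) + 1L]] <- s }
    i <- i + 1L
    if (i > 100000L + offset) break  # combinatorial space exhausted
  }
  out[order(vapply(out, paste, character(1), collapse = "+"))]
}

#' Project a cohort onto one variant's column set
#'
#' Restricts the cohort to the variant's core and adjunct columns plus the
#' outcome, preserving row count and row order. Projection is how the
#' evaluation subset is obtained from a wider synthetic table — the model is
#' never retrained on the subset.
#'
#' @param x A [cohort()].
#' @param variant A [variant_spec()].
#' @return A [cohort()] with columns `core` then `adjunct_subset` then the
#'   outcome.
#' @export
project_variant <- function(x, variant) {
  stopifnot(inherits(variant, "variant_spec"))
  cols <- c(variant$core_names, variant$adjunct_subset, outcome_name(x))
  select_cohort(x, cols)
}

#' Project a cohort onto its core columns
#'
#' @param x A [cohort()].
#' @return The cohort restricted to core predictors plus outcome.
#' @export
project_core <- function(x) {
  select_cohort(x, c(core_names(x), outcome_name(x)))
}
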