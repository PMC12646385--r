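#' Configure a membership-disclosure attack
#'
#' The attack emulates an adversary who knows a target's quasi-identifier
#' values (or, in the all-variables mode, the entire record) and predicts
#' that the target was in the generator's training data whenever some
#' synthetic record matches it closely enough.
#'
#' @param qi_names Quasi-identifier column names (ignored in all-variables
#'   mode).
#' @param attack_sample_size Number of attack records `a`.
#' @param member_fraction Expected fraction `p` of attack records drawn from
#'   the training set (default 0.5, giving the naive baseline
#'   `f1 = 2p/(1+p) = 2/3`).
#' @param match_hamming_threshold Maximum number of mismatching compared
#'   variables for a synthetic record to count as a match (default 0 =
#'   exact agreement on all compared variables).
#' @param continuous_tolerance Relative half-width for continuous matches, as
#'   a multiple of the variable's pooled standard deviation.
#' @param seed Seed for the attack-sample draw.
#' @return An `attack_config` list.
#' @export
attack_config <- function(qi_names = NULL, attack_sample_size = NULL,
                          member_fraction = 0.5,
                          match_hamming_threshold = 0,
                          continuous_tolerance = 0.1, seed = 1) {
  stopifnot(member_fraction > 0, member_fraction < 1,
            match_hamming_threshold >= 0, continuous_tolerance >= 0)
  structure(list(qi_names = qi_names,
                 attack_sample_size = attack_sample_size,
                 member_fraction = member_fraction,
                 match_hamming_threshold = match_hamming_threshold,
                 continuous_tolerance = continuous_tolerance, seed = seed),
            class = "attack_config")
}

# Columns compared by the attack in a given mode/scope.
attack_columns <- function(population, config, mode, scope_cols = NULL) {
  cols <- if (mode == "qi_only") {
    qs <- if (!is.null(config$qi_names)) config$qi_names
      else qi_names(population)
    if (!length(qs)) stop("no quasi-identifiers declared for qi_only mode")
    qs
  } else setdiff(names(population$records), outcome_name(population))
  if (!is.null(scope_cols)) cols <- intersect(cols, scope_cols)
  cols
}

#' Membership-disclosure attack on one synthetic dataset
#'
#' Draws an attack sample of `a` records — `ceiling(p * a)` from the training
#' set, the rest from the population outside it — and predicts "member" for
#' each attack record iff some synthetic record matches it on the compared
#' variables with at most `h` mismatches (categoricals by equality with
#' missing treated as its own category; continuous within
#' `tolerance * pooled sd`). Precision, recall and F1 are computed against
#' true membership and compared to the naive adversary who predicts every
#' record is a member (`precision = p`, `recall = 1`,
#' `f1_naive = 2p / (1 + p)`); the headline number is
#' `relative_f1 = max(0, f1 - f1_naive)`, with 0.2 the conventional
#' literature threshold for acceptable residual risk.
#'
#' @param population Population [cohort()] (the sampling frame).
#' @param train_ids Row indices of the training records within `population`.
#' @param synthetic Synthetic [cohort()] under attack.
#' @param config An [attack_config()].
#' @param mode `"qi_only"` or `"all_variables"`.
#' @param scope_cols Optional column whitelist (e.g. core-only scope).
#' @return A `membership_attack_result` with `precision`, `recall`, `f1`,
#'   `f1_naive`, `relative_f1`, `mode`, and `n_attack`.
#' @export
membership_attack <- function(population, train_ids, synthetic, config,
                              mode = c("qi_only", "all_variables"),
                              scope_cols = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "attack_config"))
  n_pop <- nrow(population$records)
  if (max(train_ids) > n_pop || min(train_ids) < 1)
    stop("train_ids out of population range")
  cols <- attack_columns(population, config, mode, scope_cols)
  if (!length(cols))
    stop("no compared variables left after applying the column scope")
  missing_cols <- setdiff(cols, names(synthetic$records))
  if (length(missing_cols))
    stop("synthetic data lacks compared column(s): ",
         paste(missing_cols, collapse = ", "))

  a <- config$attack_sample_size
  if (is.null(a)) a <- min(1000L, max(1L, n_pop %/% 10L))
  n_mem <- ceiling(config$member_fraction * a)
  n_non <- a - n_mem
  non_ids <- setdiff(seq_len(n_pop), train_ids)
  if (n_mem > length(train_ids) || n_non > length(non_ids))
    stop("attack sample size exceeds available records")
  idx <- with_seed(derive_seed(config$seed, "attack", population$dataset_id,
                               mode, length(cols)), {
    c(sample(train_ids, n_mem), sample(non_ids, n_non))
  })
  truth <- c(rep(TRUE, n_mem), rep(FALSE, n_non))

  predicted <- match_members(population$records[idx, cols, drop = FALSE],
                             synthetic$records[, cols, drop = FALSE],
                             population$meta[cols], config)

  tp <- sum(predicted & truth)
  precision <- if (sum(predicted)) tp / sum(predicted) else 0
  recall <- tp / sum(truth)
  f1 <- if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  p <- config$member_fraction
  f1_naive <- 2 * p / (1 + p)
  structure(list(precision = precision, recall = recall, f1 = f1,
                 f1_naive = f1_naive,
                 relative_f1 = max(0, f1 - f1_naive), mode = mode,
                 n_attack = a),
            class = "membership_attack_result")
}

# Decide, for every attack record, whether some synthetic record matches it
# within the Hamming threshold. Hash join when all compared variables are
# categorical and h = 0; otherwise a vectorized mismatch scan per attack
# record (attack samples are small by construction).
match_members <- function(attack, synthetic, meta, config) {
  h <- config$match_hamming_threshold
  is_cat <- vapply(meta, function(m) m$vtype == "categorical", logical(1))
  if (all(is_cat) && h == 0) {
    key <- function(df) do.call(paste, c(lapply(df, function(v) {
      v <- as.character(v); v[is.na(v)] <- "\r.NA"; v
    }), sep = "\r"))
    return(key(attack) %in% unique(key(synthetic)))
  }
  tol <- lapply(names(meta), function(nm) {
    if (is_cat[[nm]]) return(NULL)
    s <- stats::sd(c(as.numeric(attack[[nm]]), as.numeric(synthetic[[nm]])),
                   na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    config$continuous_tolerance * s
  })
  names(tol) <- names(meta)
  syn_cols <- lapply(names(meta), function(nm) {
    v <- synthetic[[nm]]
    if (is_cat[[nm]]) as.character(v) else as.numeric(v)
  })
  names(syn_cols) <- names(meta)
  n_syn <- nrow(synthetic)
  vapply(seq_len(nrow(attack)), function(i) {
    mism <- integer(n_syn)
    for (nm in names(meta)) {
      av <- attack[[nm]][i]
      sv <- syn_cols[[nm]]
      if (is_cat[[nm]]) {
        av <- as.character(av)
        same <- if (is.na(av)) is.na(sv) else !is.na(sv) & sv == av
      } else {
        av <- as.numeric(av)
        same <- if (is.na(av)) is.na(sv)
          else !is.na(sv) & abs(sv - av) <= tol[[nm]]
      }
      mism <- mism + !same
      if (all(mism > h)) return(FALSE)  # early exit
    }
    any(mism <= h)
  }, logical(1))
}

#' Membership vulnerability of an ensemble, both modes and scopes
#'
#' Runs [membership_attack()] for every synthetic replicate in both adversary
#' modes (quasi-identifiers only; all variables) and both column scopes (the
#' core subset; the full core+adjunct table), reporting replicate means. The
#' four resulting metric names follow the
#' `membership_{qi,all}_{core,full}` convention.
#'
#' @param population Population [cohort()].
#' @param train_ids Training row indices.
#' @param ensemble A `synthetic_ensemble`.
#' @param config An [attack_config()].
#' @param core_cols Core column names (default: the population's core
#'   predictors plus outcome).
#' @return Named list of mean relative F1 per metric, plus `per_replicate`.
#' @export
vulnerability_pair <- function(population, train_ids, ensemble, config,
                               core_cols = NULL) {
  if (is.null(core_cols))
    core_cols <- c(core_names(population), outcome_name(population))
  # "full" scope = every column the synthetic table actually carries
  # (core + the variant's adjunct subset)
  scopes <- list(core = core_cols,
                 full = names(ensemble$replicates[[1]]$records))
  modes <- c(qi = "qi_only", all = "all_variables")
  out <- list(); per <- list()
  for (mo in names(modes)) for (sc in names(scopes)) {
    nm <- paste0("membership_", mo, "_", sc)
    vals <- vapply(ensemble$replicates, function(syn) {
      membership_attack(population, train_ids, syn, config,
                        mode = modes[[mo]],
                        scope_cols = scopes[[sc]])$relative_f1
    }, numeric(1))
    out[[nm]] <- mean(vals)
    per[[nm]] <- vals
  }
  out$per_replicate <- per
  out
}
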