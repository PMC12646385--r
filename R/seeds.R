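#' Derive a reproducible child seed
#'
#' Every source of randomness in the pipeline draws its seed from one master
#' seed through this function, keyed by a path of string/integer tags (module,
#' dataset, variant, replicate, ...). Two calls with the same master seed and
#' tags always return the same child seed; distinct tag paths decouple the
#' random streams of different pipeline stages, so re-ordering or skipping
#' stages never perturbs another stage's draws.
#'
#' The derivation is a Horner-scheme polynomial hash of the UTF-8 bytes of the
#' tag path, folded into the master seed, reduced modulo 2^31 - 1 (seeds stay
#' inside R's integer range).
#'
#' @param master Integer master seed.
#' @param ... Tags (strings or numbers) identifying the consumer.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' derive_seed(42, "split", "cohort_A")
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L)
  tags <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                       character(1)), collapse = "")
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(master) %% m
  for (b in utf8ToInt(tags)) h <- (h * 131 + b) %% m
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
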