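# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. All exported stochastic
# functions take an explicit seed and route through this, so package
# calls never perturb the user's RNG stream.
with_seed_ <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed (< 2^31) from a parent seed and a stream label,
# so that independent stages of a pipeline get distinct, reproducible
# seeds from one user-facing seed. Hash-based so that nearby parent
# seeds or consecutive stream labels give well-separated RNG streams.
child_seed_ <- function(seed, stream) {
  h <- rlang::hash(list(as.integer(seed), as.character(stream)))
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Condition columns defining the design cells of a dataset: the
# WM-load x LTM-load crossing where the design manipulates loads
# (E1/E2), otherwise set size x pair type (E3/E4).
detect_keys_ <- function(data) {
  has <- function(k) k %in% names(data) && !all(is.na(data[[k]]))
  if (has("wm_load") && has("ltm_load")) c("wm_load", "ltm_load")
  else intersect(c("set_size", "pair_type"), names(data)[
    vapply(names(data), has, TRUE)])
}
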