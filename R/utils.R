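# Internal helpers shared across modules.

# Geometric mean; x must be strictly positive.
geo_mean <- function(x) exp(mean(log(x)))

# Dense ranks (1 = smallest), ties share a rank. `...` are additional
# numeric/character keys consulted only to order rows, never to split ties
# into distinct ranks unless they differ.
dense_rank_keys <- function(primary, ...) {
  keys <- list(primary, ...)
  key_str <- do.call(paste, c(keys, sep = "\r"))
  ord <- do.call(order, keys)
  ranks <- integer(length(primary))
  ranks[ord] <- cumsum(!duplicated(key_str[ord]))
  ranks
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

# Deterministic RNG scope: runs `code` under `seed` and restores the caller's
# RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
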