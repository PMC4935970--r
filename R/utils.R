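# Internal helpers: deterministic RNG substreams, matrix utilities, input checks.

# Derive a reproducible sub-seed from a master seed and a string key, so each
# component (tree, abundances, sampling, environment, per-sample rarefaction)
# draws from its own stream and is insensitive to the order in which other
# components consume random numbers. Polynomial string hash mod a prime < 2^31.
tdv_subseed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  p <- 2147483629
  h <- as.double(seed %% p)
  for (cp in utf8ToInt(as.character(key))) {
    h <- (h * 131 + cp) %% p
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_tdv_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# Strict upper-triangle (i < j) of a square matrix as a vector, column-major.
upper_tri_vec <- function(m) {
  m[upper.tri(m)]
}

# Index pairs (i, j), i < j, matching upper_tri_vec() ordering.
upper_tri_pairs <- function(n) {
  j <- rep(seq_len(n), times = seq_len(n) - 1L)
  i <- unlist(lapply(seq_len(n), function(k) seq_len(k - 1L)), use.names = FALSE)
  cbind(i = i, j = j)
}

assert_counts <- function(x, what = "counts") {
  if (length(x) == 0 || !is.numeric(x)) {
    stop(what, " must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    stop(what, " must be nonnegative integers", call. = FALSE)
  }
  if (sum(x) == 0) {
    stop(what, " are all zero: diversity is undefined", call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
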