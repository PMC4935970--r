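# Shared fixtures and independent oracles for the test suite. Everything here
# is deliberately naive (double loops, recursion, enumeration) so it stays
# independent of the package's own code paths.

# A tiny labelled count matrix wrapped as an otu_table.
tiny_table <- function() {
  m <- matrix(
    c(
      1, 0, 2,
      2, 3, 0,
      0, 1, 1
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("otuA", "otuB", "otuC"), c("s1", "s2", "s3"))
  )
  otu_table(m, site_of = c(s1 = "X", s2 = "X", s3 = "Y"))
}

# All permutations of 1..n as a list (independent of the package's all_perms).
enum_perms <- function(n) {
  if (n == 1) {
    return(list(1L))
  }
  out <- list()
  for (sub in enum_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# All positive-integer count vectors of length k with given total (ordered
# compositions).
enum_compositions <- function(total, k) {
  if (k == 1) {
    return(list(total))
  }
  out <- list()
  for (first in 1:(total - k + 1)) {
    for (rest in enum_compositions(total - first, k - 1)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

# Naive Bray-Curtis between columns of a count matrix.
brute_bray <- function(m) {
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(abs(m[, i] - m[, j])) / sum(m[, i] + m[, j])
    }
  }
  d
}

# Naive abundance-weighted MPD with off-diagonal weight normalisation.
brute_mpd <- function(d, x) {
  num <- 0
  den <- 0
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      if (i != j && x[i] > 0 && x[j] > 0) {
        num <- num + d[i, j] * x[i] * x[j]
        den <- den + x[i] * x[j]
      }
    }
  }
  num / den
}

# Upper-triangle vector in column-major order (matches dist() ordering after
# as.matrix round trips used in the package).
ut <- function(m) m[upper.tri(m)]

# A random labelled distance matrix built from points in the plane, so it is
# a genuine metric.
random_dist <- function(n, labels = sprintf("u%02d", seq_len(n))) {
  pts <- matrix(rnorm(2 * n), n, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(labels, labels)
  d
}

# Seeded 15-unit random distance matrix (independent draws for calibration
# studies).
with_seed_matrix <- function(seed, n = 15) {
  set.seed(seed)
  random_dist(n)
}
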