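test_that("Bray-Curtis matches the definition and the naive double loop", {
  m <- matrix(c(1, 1, 0, 0, 1, 1), 3, 2,
    dimnames = list(paste0("o", 1:3), c("u", "v"))
  )
  d <- bray_curtis(otu_table(m))
  expect_equal(d["u", "v"], 0.5)

  same <- matrix(c(3, 1, 3, 1), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(bray_curtis(otu_table(same))["x", "y"], 0)

  disjoint <- matrix(c(3, 0, 0, 2), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(bray_curtis(otu_table(disjoint))["x", "y"], 1)

  set.seed(12)
  mm <- matrix(rpois(40, 6), 8, 5,
    dimnames = list(paste0("o", 1:8), paste0("s", 1:5))
  )
  mm[1, 1] <- mm[1, 1] + 1 # guard against an all-zero column
  expect_equal(bray_curtis(otu_table(mm)), brute_bray(mm), tolerance = 1e-12)

  zero <- matrix(c(1, 0, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(bray_curtis(otu_table(zero)), "x|y")
})

test_that("environmental distance is Euclidean on z-scores", {
  meta <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    v1 = c(1, 2, 3), v2 = c(10, 10, 13), v3 = c(5, 5, 5)
  )
  d <- env_distance(meta, c("v1", "v2"))
  z <- scale(cbind(meta$v1, meta$v2))
  ref <- as.matrix(dist(z))
  expect_equal(unname(d), unname(ref))
  # single variable: |z1 - z2|
  d1 <- env_distance(meta, "v1")
  z1 <- as.numeric(scale(meta$v1))
  expect_equal(d1["a", "b"], abs(z1[1] - z1[2]))
  expect_error(env_distance(meta, "v3"), "constant")
  expect_error(env_distance(meta, "nope"), "nope")
  # duplicated rows are at distance zero
  meta2 <- tibble::tibble(sample_id = c("a", "b", "c"), v1 = c(1, 1, 4))
  expect_equal(env_distance(meta2, "v1")["a", "b"], 0)
})

test_that("Mantel r is the upper-triangle Pearson correlation, invariant to scaling", {
  set.seed(2)
  d1 <- random_dist(8)
  res <- mantel_test(d1, 2 * d1, n_perm = 99, seed = 1)
  expect_equal(res$r_m, 1)
  expect_equal(res$p, 1 / 100) # minimal p with the +1 estimator

  d2 <- random_dist(8, labels = rownames(d1))
  ours <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 99)
  expect_equal(ours$r_m, unname(ref$statistic), tolerance = 1e-12)

  expect_error(
    mantel_test(d1, random_dist(8, labels = paste0("v", 1:8)), seed = 1),
    "different unit labels"
  )
})

test_that("exact Mantel p-value matches independent enumeration at n = 4", {
  set.seed(9)
  for (rep in 1:5) {
    d1 <- random_dist(4)
    d2 <- random_dist(4, labels = rownames(d1))
    res <- mantel_test(d1, d2, exact = TRUE)
    v2 <- ut(d2)
    r_obs <- cor(ut(d1), v2)
    r_all <- vapply(enum_perms(4), function(p) {
      cor(ut(d1[p, p]), v2)
    }, numeric(1))
    expect_equal(res$p, mean(r_all >= r_obs - 1e-12))
    expect_equal(res$n_perm, 24L)
    # Monte Carlo p converges to the exact value
    mc <- mantel_test(d1, d2, n_perm = 9999, seed = rep)
    expect_lt(abs(mc$p - res$p), 0.03)
  }
})

test_that("partial Mantel reduces to simple Mantel under an orthogonal control", {
  # build control whose upper triangle is orthogonal to both d1's and d2's
  set.seed(21)
  d1 <- random_dist(7)
  d2 <- random_dist(7, labels = rownames(d1))
  v1 <- ut(d1)
  v2 <- ut(d2)
  base <- cbind(1, v1, v2)
  raw <- rnorm(length(v1))
  orth <- raw - base %*% solve(crossprod(base), crossprod(base, raw))
  orth <- orth - min(orth) # keep nonnegative
  dc <- matrix(0, 7, 7, dimnames = dimnames(d1))
  dc[upper.tri(dc)] <- orth
  dc <- dc + t(dc)
  simple <- mantel_test(d1, d2, n_perm = 99, seed = 3)
  partial <- partial_mantel(d1, d2, list(ctrl = dc), n_perm = 99, seed = 3)
  expect_equal(partial$r_m, simple$r_m, tolerance = 1e-10)
  expect_equal(partial$controlled, "ctrl")

  # controlling for d2 itself wipes out the correlation
  self <- partial_mantel(d1, d2, list(d2), n_perm = 99, seed = 3)
  expect_lt(abs(self$r_m), 1e-10)

  expect_error(partial_mantel(d1, d2, list()), "at least one control")
  expect_error(
    partial_mantel(d1, d2, list(a = dc, b = dc), n_perm = 9, seed = 1),
    "collinear"
  )
})

test_that("partial Mantel equals the closed-form partial correlation on a hand case", {
  set.seed(14)
  d1 <- random_dist(5)
  d2 <- random_dist(5, labels = rownames(d1))
  dc <- random_dist(5, labels = rownames(d1))
  v1 <- ut(d1)
  v2 <- ut(d2)
  vc <- ut(dc)
  r12 <- cor(v1, v2)
  r1c <- cor(v1, vc)
  r2c <- cor(v2, vc)
  closed <- (r12 - r1c * r2c) / sqrt((1 - r1c^2) * (1 - r2c^2))
  res <- partial_mantel(d1, d2, list(dc), n_perm = 9, seed = 1)
  expect_equal(res$r_m, closed, tolerance = 1e-10)
})

test_that("BioENV searches all subsets and agrees with brute force", {
  set.seed(31)
  n <- 6
  meta <- tibble::tibble(
    sample_id = sprintf("u%02d", 1:n),
    a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n)
  )
  comm <- random_dist(n, labels = meta$sample_id)
  res <- bioenv_best(comm, meta, c("a", "b", "c"))
  expect_equal(nrow(res$ranking), 7) # 2^3 - 1

  # a community matrix built from one variable selects it with rho = 1
  comm_v <- env_distance(meta, "b")
  res_v <- bioenv_best(comm_v, meta, c("a", "b", "c"))
  expect_equal(res_v$best, "b")
  expect_equal(res_v$rho, 1)

  # brute-force oracle over random instances, 4 variables
  for (rep in 1:5) {
    meta_r <- tibble::tibble(
      sample_id = sprintf("u%02d", 1:n),
      a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n)
    )
    comm_r <- random_dist(n, labels = meta_r$sample_id)
    vars <- c("a", "b", "c", "d")
    got <- bioenv_best(comm_r, meta_r, vars)
    best_rho <- -Inf
    best_set <- NULL
    for (size in 1:4) {
      for (s in combn(vars, size, simplify = FALSE)) {
        dv <- as.matrix(dist(scale(as.matrix(meta_r[, s]))))
        rho <- cor(dv[upper.tri(dv)], comm_r[upper.tri(comm_r)], method = "spearman")
        if (rho > best_rho + 1e-12) {
          best_rho <- rho
          best_set <- s
        }
      }
    }
    expect_equal(sort(got$best), sort(best_set))
    expect_equal(got$rho, best_rho, tolerance = 1e-12)
  }

  # invariance to variable ordering
  res_fwd <- bioenv_best(comm, meta, c("a", "b", "c", "d"))
  res_rev <- bioenv_best(comm, meta, c("d", "c", "b", "a"))
  expect_equal(sort(res_fwd$best), sort(res_rev$best))
  expect_equal(res_fwd$rho, res_rev$rho)

  expect_error(bioenv_best(comm, meta, letters[1:16]), "15")
})

test_that("pearson_test matches cor.test and handles the perfect case", {
  set.seed(41)
  x <- rnorm(12)
  y <- 0.5 * x + rnorm(12)
  ours <- pearson_test(x, y)
  ref <- cor.test(x, y)
  expect_equal(ours$r, unname(ref$estimate))
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)

  # n = 5 hand case against the closed form
  x5 <- c(1, 2, 3, 4, 5)
  y5 <- c(2, 1, 4, 3, 6)
  r5 <- cor(x5, y5)
  t5 <- r5 * sqrt(3 / (1 - r5^2))
  h <- pearson_test(x5, y5)
  expect_equal(h$t, t5)
  expect_equal(h$p, 2 * pt(abs(t5), 3, lower.tail = FALSE))

  perfect <- pearson_test(x, x)
  expect_true(perfect$perfect)
  expect_equal(perfect$p, 0)
  expect_error(pearson_test(rep(1, 5), rnorm(5)), "constant")
})

test_that("distance outputs always satisfy the distance-matrix contract", {
  set.seed(55)
  for (rep in 1:10) {
    m <- matrix(rpois(60, 5) + 1, 10, 6,
      dimnames = list(paste0("o", 1:10), paste0("s", 1:6))
    )
    d <- bray_curtis(otu_table(m))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
  }
})
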