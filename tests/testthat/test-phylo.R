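test_that("newick reading enforces labels and branch lengths", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", p)
  tr <- read_newick(p)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(sum(tr$edge.length), 5)

  writeLines("((A:1,A:1):1,C:2);", p)
  expect_error(read_newick(p), "duplicate")

  writeLines("((A,B),C);", p)
  expect_error(read_newick(p), "branch length")

  # round trip preserves cophenetic distances
  p2 <- withr::local_tempfile(fileext = ".nwk")
  tr0 <- generate_tree(7, seed = 2)
  ape::write.tree(tr0, p2)
  tr1 <- read_newick(p2)
  d0 <- cophenetic_dist(tr0)
  d1 <- cophenetic_dist(tr1)
  expect_equal(d1[rownames(d0), colnames(d0)], d0, tolerance = 1e-9)
})

test_that("cophenetic distances are path sums on the tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d <- cophenetic_dist(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)

  star <- ape::read.tree(text = "(A:3,B:3,C:3,D:3);")
  ds <- cophenetic_dist(star)
  expect_true(all(ds[upper.tri(ds)] == 6))

  # Floyd-Warshall over the full tree graph agrees on random trees
  set.seed(30)
  for (rep in 1:5) {
    tr8 <- generate_tree(8, seed = rep)
    n_node <- max(tr8$edge)
    g <- matrix(Inf, n_node, n_node)
    diag(g) <- 0
    for (e in seq_len(nrow(tr8$edge))) {
      a <- tr8$edge[e, 1]
      b <- tr8$edge[e, 2]
      g[a, b] <- g[b, a] <- tr8$edge.length[e]
    }
    for (k in seq_len(n_node)) {
      for (i in seq_len(n_node)) {
        for (j in seq_len(n_node)) {
          if (g[i, k] + g[k, j] < g[i, j]) g[i, j] <- g[i, k] + g[k, j]
        }
      }
    }
    fw <- g[seq_len(8), seq_len(8)]
    dimnames(fw) <- list(tr8$tip.label, tr8$tip.label)
    d8 <- cophenetic_dist(tr8)
    expect_equal(d8, fw[rownames(d8), colnames(d8)], tolerance = 1e-9)
  }
})

test_that("faith_pd follows the rooted convention and is monotone in the tip set", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(faith_pd(tr, c("A", "B", "C")), 5)
  expect_equal(faith_pd(tr, c("A", "B")), 3) # two unit tips + shared stem
  expect_error(faith_pd(tr, character(0)), "empty")
  expect_error(faith_pd(tr, c("A", "Z")), "Z")

  # enumeration over all subsets of random 6-tip trees: monotone, matches picante
  for (rep in 1:3) {
    tr6 <- generate_tree(6, seed = 100 + rep)
    tips <- tr6$tip.label
    pd_of <- function(set) faith_pd(tr6, set)
    for (size in 1:5) {
      sets <- combn(tips, size, simplify = FALSE)
      for (s in sets) {
        base_pd <- pd_of(s)
        for (extra in setdiff(tips, s)) {
          expect_gte(pd_of(c(s, extra)), base_pd - 1e-12)
        }
      }
    }
    expect_equal(pd_of(tips), sum(tr6$edge.length))
    # independent cross-check against picante on a few subsets
    samp <- rbind(
      as.integer(tips %in% tips[1:2]),
      as.integer(tips %in% tips[1:4]),
      rep(1L, 6)
    )
    colnames(samp) <- tips
    ref <- picante::pd(samp, tr6, include.root = TRUE)$PD
    ours <- c(pd_of(tips[1:2]), pd_of(tips[1:4]), pd_of(tips))
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("weighted MPD matches the double-loop definition", {
  # constant off-diagonal distances give MPD equal to that constant
  d <- matrix(3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  expect_equal(mpd_weighted(d, c(0.7, 0.1, 0.1, 0.1)), 3)

  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  dc <- cophenetic_dist(tr)
  expect_equal(mpd_weighted(dc, setNames(rep(1 / 3, 3), c("A", "B", "C"))), 10 / 3)

  set.seed(77)
  for (rep in 1:10) {
    n <- 10
    dm <- random_dist(n)
    x <- runif(n)
    x <- x / sum(x)
    expect_equal(mpd_weighted(dm, x), brute_mpd(dm, x), tolerance = 1e-12)
  }
  expect_error(mpd_weighted(d, c(1, 0, 0, 0)), "fewer than two")

  # unnormalized variant is the raw weighted sum
  x <- c(0.5, 0.3, 0.1, 0.1)
  w <- tcrossprod(x)
  diag(w) <- 0
  expect_equal(mpd_weighted(d, x, normalize = FALSE), sum(d * w))
})

test_that("NRI null moments match exhaustive tip-label permutation", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:1.5,D:0.5):2);")
  d <- cophenetic_dist(tr)[tr$tip.label, tr$tip.label]
  ab <- c(A = 3, B = 1) # two occupied tips
  x <- c(0.75, 0.25)
  vals <- vapply(enum_perms(4), function(p) {
    # after shuffling, taxon 1 sits at tip p[1], taxon 2 at tip p[2]
    brute_mpd(d[c(p[1], p[2]), c(p[1], p[2])], x)
  }, numeric(1))
  mu <- mean(vals)
  sigma <- sd(vals) # population over the 24 equally likely relabelings
  res <- nri(tr, ab, n_null = 20000, seed = 99, keep_null = TRUE)
  se <- sigma / sqrt(20000)
  expect_lt(abs(res$null_mean - mu), 3 * se)
  expect_equal(res$null_sd, sigma, tolerance = 0.05)
  expect_equal(res$mpd_obs, brute_mpd(d[c("A", "B"), c("A", "B")], x))
  expect_equal(res$nri, -(res$mpd_obs - res$null_mean) / res$null_sd)
})

test_that("NRI is flagged undefined when the null has no spread", {
  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2);")
  res <- nri(star, c(A = 1, B = 1), n_null = 50, seed = 4)
  expect_true(res$undefined)
  expect_true(is.na(res$nri))
  expect_equal(res$mpd_obs, 4)
})

test_that("communities confined to one clade of a split tree show clustering", {
  tr <- ape::read.tree(text = paste0(
    "(((a:1,b:1):1,(c:1,d:1):1):10,",
    "((e:1,f:1):1,(g:1,h:1):1):10);"
  ))
  hits <- vapply(1:30, function(s) {
    res <- nri(tr, c(a = 2, b = 1, c = 1, d = 3), n_null = 200, seed = s)
    res$nri > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("nri_profile is reproducible and independent of unit order", {
  sim <- generate_dataset(sim_config(
    n_sites = 2, temps_c = c(5, 20),
    samples_per_site = 2, depth = 300,
    intercept_a = 13, seed = 6
  ))
  a <- nri_profile(sim$table, sim$tree, n_null = 60, seed = 5)
  b <- nri_profile(sim$table, sim$tree, n_null = 60, seed = 5)
  expect_identical(a, b)
  # reversing sample order leaves each unit's result unchanged
  rev_tab <- otu_table(as.matrix(sim$table)[, rev(colnames(as.matrix(sim$table)))],
    site_of = sim$table$site_of
  )
  c_rev <- nri_profile(rev_tab, sim$tree, n_null = 60, seed = 5)
  merged <- merge(as.data.frame(a), as.data.frame(c_rev), by = "unit")
  expect_equal(merged$nri.x, merged$nri.y)
})
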