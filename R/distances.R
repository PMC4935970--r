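# Distance matrices are plain labelled numeric matrices: symmetric,
# nonnegative, zero diagonal. check_dist() enforces that contract at entry.

check_dist <- function(d, what = "distance matrix") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop(what, " must be square", call. = FALSE)
  if (is.null(rownames(d))) stop(what, " must be labelled", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12))) {
    stop(what, " must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(d)) > 1e-12)) stop(what, " must have a zero diagonal", call. = FALSE)
  if (any(d < 0)) stop(what, " must be nonnegative", call. = FALSE)
  d
}

# Align d2 (and friends) onto d1's labels.
align_dist <- function(d1, d2, what = "matrices") {
  if (!setequal(rownames(d1), rownames(d2))) {
    stop(what, " are over different unit labels", call. = FALSE)
  }
  d2[rownames(d1), rownames(d1), drop = FALSE]
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{BC(u, v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)}, in `[0, 1]`,
#' the standard community dissimilarity for OTU count data. Computed on the
#' counts as given (raw by default; pass a rarefied table to work at equal
#' depth).
#'
#' @param x An [otu_table()].
#' @return Labelled symmetric matrix of pairwise dissimilarities.
#' @export
bray_curtis <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  counts <- x$counts
  if (ncol(counts) < 2) stop("need at least two samples", call. = FALSE)
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  }
  d <- as.matrix(vegan::vegdist(t(counts), method = "bray"))
  dimnames(d) <- list(colnames(counts), colnames(counts))
  d
}

#' Euclidean distance on z-scored environmental variables
#'
#' Each requested variable is standardised to zero mean and unit standard
#' deviation over the included units, then pairwise Euclidean distances are
#' taken — the convention for building environmental distance matrices to
#' test against community dissimilarity.
#'
#' @param meta Metadata tibble (sample- or site-level).
#' @param variables Character vector of numeric columns of `meta` to use.
#' @param unit Name of the column holding unit labels (default `"sample_id"`).
#' @return Labelled symmetric distance matrix.
#' @export
env_distance <- function(meta, variables, unit = "sample_id") {
  missing_vars <- setdiff(variables, names(meta))
  if (length(missing_vars)) {
    stop("variables not in metadata: ", paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  if (!unit %in% names(meta)) stop("no unit column '", unit, "'", call. = FALSE)
  m <- as.matrix(meta[, variables, drop = FALSE])
  if (anyNA(m)) stop("missing values in selected variables", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s): ", paste(variables[sds == 0], collapse = ", "), call. = FALSE)
  }
  z <- scale(m)
  d <- as.matrix(stats::dist(z, method = "euclidean"))
  dimnames(d) <- list(meta[[unit]], meta[[unit]])
  d
}

# All permutations of 1..n (n! rows); used for exact Mantel p-values.
all_perms <- function(n) {
  if (n == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# Gather the upper-triangle vector of d under a row/column relabelling p.
permuted_ut <- function(d, p, pairs) {
  d[cbind(p[pairs[, "i"]], p[pairs[, "j"]])]
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation \eqn{r_M} of the upper-triangle entries, with
#' significance from joint row/column permutations of the first matrix.
#' The p-value uses the permutation-inclusive estimator
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})}, so it is never
#' zero. One-tailed ("greater", positive association) by default, the
#' ecological convention; `alternative = "two.sided"` compares `|r|`.
#' With `exact = TRUE` (only sensible for very small n) all `n!` relabelings
#' are enumerated and the p-value is the exact fraction with
#' \eqn{r_{perm} \ge r_{obs}}.
#'
#' @param d1,d2 Labelled distance matrices over the same units (n >= 3).
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed (mandatory unless `exact = TRUE`).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param exact Enumerate all permutations instead of sampling (requires
#'   n <= 8).
#' @return One-row tibble: `r_m`, `p`, `n_perm`, `alternative`, `controlled`
#'   (empty string), `seed`, `exact`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL,
                        alternative = c("greater", "two.sided"), exact = FALSE) {
  alternative <- match.arg(alternative)
  d1 <- check_dist(d1, "d1")
  d2 <- check_dist(d2, "d2")
  d2 <- align_dist(d1, d2)
  n <- nrow(d1)
  if (n < 3) stop("need at least 3 units", call. = FALSE)
  pairs <- upper_tri_pairs(n)
  v1 <- upper_tri_vec(d1)
  v2 <- upper_tri_vec(d2)
  r_obs <- stats::cor(v1, v2)
  # A joint row/column relabelling permutes the upper-triangle multiset of d1,
  # so its mean and sum of squares are permutation-invariant and each permuted
  # correlation is a single inner product with the centred d2 vector.
  v2c <- v2 - mean(v2)
  denom <- sqrt(sum((v1 - mean(v1))^2) * sum(v2c^2))
  r_of <- function(p) sum(permuted_ut(d1, p, pairs) * v2c) / denom
  stat <- function(r) if (alternative == "greater") r else abs(r)
  if (exact) {
    if (n > 8) stop("exact enumeration limited to n <= 8", call. = FALSE)
    perms <- all_perms(n)
    r_all <- apply(perms, 1, r_of)
    p_val <- mean(stat(r_all) >= stat(r_obs) - 1e-12)
    n_eff <- nrow(perms)
  } else {
    if (is.null(seed)) stop("mantel_test() requires a seed (or exact = TRUE)", call. = FALSE)
    r_perm <- with_tdv_seed(seed, {
      vapply(seq_len(n_perm), function(b) r_of(sample.int(n)), numeric(1))
    })
    p_val <- (1 + sum(stat(r_perm) >= stat(r_obs) - 1e-12)) / (1 + n_perm)
    n_eff <- n_perm
  }
  tibble::tibble(
    r_m = r_obs, p = p_val, n_perm = as.integer(n_eff),
    alternative = alternative, controlled = "",
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    exact = exact
  )
}

#' Partial Mantel test
#'
#' Correlation between two distance matrices after linearly removing the
#' effect of one or more control matrices: both upper-triangle vectors are
#' residualised on the controls (plus intercept) by least squares and the
#' residuals are correlated. Significance comes from jointly permuting the
#' rows/columns of `d1`, residualising the permuted vector against the fixed
#' controls and re-correlating (residual-permutation scheme; one of several
#' published choices, documented as such).
#'
#' @param d1,d2 Labelled distance matrices over the same units.
#' @param controls Non-empty list of control distance matrices (named, if the
#'   report should say what was controlled for).
#' @inheritParams mantel_test
#' @return One-row tibble as in [mantel_test()], with `controlled` listing the
#'   control names.
#' @export
partial_mantel <- function(d1, d2, controls, n_perm = 999, seed = NULL,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (missing(controls) || length(controls) == 0) {
    stop("partial_mantel() needs at least one control matrix; use mantel_test() otherwise",
      call. = FALSE
    )
  }
  if (!is.list(controls)) controls <- list(controls)
  d1 <- check_dist(d1, "d1")
  d2 <- align_dist(d1, check_dist(d2, "d2"))
  controls <- lapply(controls, function(dc) align_dist(d1, check_dist(dc, "control")))
  n <- nrow(d1)
  if (n < 4) stop("need at least 4 units", call. = FALSE)
  pairs <- upper_tri_pairs(n)
  v1 <- upper_tri_vec(d1)
  v2 <- upper_tri_vec(d2)
  cm <- cbind(1, do.call(cbind, lapply(controls, upper_tri_vec)))
  qr_c <- qr(cm)
  if (qr_c$rank < ncol(cm)) {
    stop("collinear controls (design rank ", qr_c$rank, " < ", ncol(cm),
      "; condition number ", format(kappa(cm), digits = 3), ")",
      call. = FALSE
    )
  }
  res1 <- stats::resid(stats::lm.fit(cm, v1))
  res2 <- stats::resid(stats::lm.fit(cm, v2))
  # A matrix fully explained by the controls leaves a numerically-zero
  # residual; its correlation with anything is defined as 0.
  safe_cor <- function(a, b) {
    if (sqrt(mean(a^2)) < 1e-10 * stats::sd(v1) ||
      sqrt(mean(b^2)) < 1e-10 * stats::sd(v2)) {
      return(0)
    }
    stats::cor(a, b)
  }
  r_obs <- safe_cor(res1, res2)
  stat <- function(r) if (alternative == "greater") r else abs(r)
  if (is.null(seed)) stop("partial_mantel() requires a seed", call. = FALSE)
  r_perm <- with_tdv_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      p <- sample.int(n)
      rp <- stats::resid(stats::lm.fit(cm, permuted_ut(d1, p, pairs)))
      safe_cor(rp, res2)
    }, numeric(1))
  })
  p_val <- (1 + sum(stat(r_perm) >= stat(r_obs) - 1e-12)) / (1 + n_perm)
  ctrl_names <- names(controls) %||% rep("", length(controls))
  ctrl_names[!nzchar(ctrl_names)] <- paste0("control", which(!nzchar(ctrl_names)))
  tibble::tibble(
    r_m = r_obs, p = p_val, n_perm = as.integer(n_perm),
    alternative = alternative,
    controlled = paste(ctrl_names, collapse = ", "),
    seed = as.integer(seed), exact = FALSE
  )
}

#' BioENV: best environmental-variable subset
#'
#' Exhaustively evaluates every nonempty subset of the candidate variables:
#' for each subset the z-scored Euclidean distance matrix is built and its
#' upper triangle is rank-correlated (Spearman, average ranks on ties) with
#' the community distance matrix. Returns the maximising subset and the full
#' ranking. Limited to 15 variables (2^15 - 1 subsets); pre-select beyond
#' that.
#'
#' @param community Labelled community distance matrix (e.g. [bray_curtis()]).
#' @param meta Metadata tibble covering the same units.
#' @param variables Candidate variable names (numeric columns of `meta`).
#' @param unit Unit-label column of `meta`.
#' @return List with `best` (character vector of variable names), `rho`
#'   (its Spearman correlation), and `ranking`, a tibble of all subsets with
#'   columns `variables`, `size`, `rho`, sorted by decreasing `rho`.
#' @export
bioenv_best <- function(community, meta, variables, unit = "sample_id") {
  if (length(variables) > 15) {
    stop("more than 15 variables (", length(variables),
      "): exhaustive search infeasible, pre-select candidates",
      call. = FALSE
    )
  }
  community <- check_dist(community, "community")
  meta <- meta[match(rownames(community), meta[[unit]]), , drop = FALSE]
  if (anyNA(meta[[unit]])) stop("metadata lacks some community units", call. = FALSE)
  vc <- upper_tri_vec(community)
  # Per-variable squared z-difference vectors; a subset's Euclidean distance
  # is the root of the subset sum, so each subset costs one sqrt + one cor.
  sq_diffs <- lapply(variables, function(v) {
    z <- as.numeric(scale(meta[[v]]))
    if (anyNA(z)) stop("variable '", v, "' is constant or has missing values", call. = FALSE)
    outer(z, z, function(a, b) (a - b)^2)[upper.tri(diag(length(z)))]
  })
  names(sq_diffs) <- variables
  n_var <- length(variables)
  subset_rows <- purrr::map(seq_len(2^n_var - 1), function(mask) {
    in_set <- as.logical(bitwAnd(mask, bitwShiftL(1L, seq_len(n_var) - 1L)))
    dvec <- sqrt(Reduce(`+`, sq_diffs[in_set]))
    tibble::tibble(
      variables = paste(sort(variables[in_set]), collapse = ", "),
      size = sum(in_set),
      rho = stats::cor(dvec, vc, method = "spearman")
    )
  })
  ranking <- dplyr::bind_rows(subset_rows) |>
    dplyr::arrange(dplyr::desc(.data$rho), .data$size)
  best <- strsplit(ranking$variables[1], ", ", fixed = TRUE)[[1]]
  list(best = best, rho = ranking$rho[1], ranking = ranking)
}

#' Pearson correlation with t-distribution inference
#'
#' \eqn{t = r \sqrt{(n - 2) / (1 - r^2)}} referred to a Student t distribution
#' with `n - 2` degrees of freedom, two-tailed. A perfect correlation gives
#' infinite `t`; it is reported as `p = 0` with `perfect = TRUE`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, both non-constant.
#' @return One-row tibble: `r`, `t`, `df`, `p`, `n`, `perfect`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector", call. = FALSE)
  r <- stats::cor(x, y)
  perfect <- abs(r) >= 1 - 1e-15
  t_stat <- if (perfect) sign(r) * Inf else r * sqrt((n - 2) / (1 - r^2))
  p <- if (perfect) 0 else 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  tibble::tibble(r = r, t = t_stat, df = n - 2, p = p, n = n, perfect = perfect)
}
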