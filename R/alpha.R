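#' Chao1 richness estimator
#'
#' Nonparametric estimate of total richness from an abundance vector,
#' extrapolating the number of unseen species from singletons and doubletons:
#' \deqn{\hat S = S_{obs} + f_1^2 / (2 f_2)}
#' where \eqn{S_{obs}} is the number of observed species and \eqn{f_1},
#' \eqn{f_2} are the numbers of species seen exactly once and exactly twice.
#' When no doubletons are present the bias-corrected form
#' \eqn{S_{obs} + f_1 (f_1 - 1) / (2 (f_2 + 1))} is used, which avoids the
#' division by zero and reduces to \eqn{S_{obs}} when \eqn{f_1 \le 1}.
#'
#' @param counts Nonnegative integer vector of per-species abundances; zeros
#'   are ignored (absent species are not species).
#' @return Estimated richness, always `>=` the observed richness.
#' @examples
#' chao1(c(10, 3, 1, 1, 2)) # 5 observed + 2^2/(2*1) = 7
#' @export
chao1 <- function(counts) {
  assert_counts(counts)
  pos <- counts[counts > 0]
  s_obs <- length(pos)
  f1 <- sum(pos == 1)
  f2 <- sum(pos == 2)
  if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  }
}

#' Shannon diversity (natural log)
#'
#' \eqn{H = -\sum_i p_i \ln p_i} with \eqn{p_i} the proportion of species `i`
#' in the community. Reported in nats; users comparing against log2-based
#' outputs must convert.
#'
#' @inheritParams chao1
#' @return Shannon index in nats, between 0 and `ln(S_obs)`.
#' @examples
#' shannon(c(1, 1, 1, 1)) # log(4)
#' @export
shannon <- function(counts) {
  assert_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Inverse Simpson diversity
#'
#' \eqn{1 / \sum_i p_i^2}, the effective number of equally abundant species.
#'
#' @inheritParams chao1
#' @return Effective species number, between 1 and `S_obs`.
#' @examples
#' inv_simpson(c(2, 2, 2)) # 3
#' @export
inv_simpson <- function(counts) {
  assert_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  1 / sum(p^2)
}

#' Alpha-diversity profile of an OTU table
#'
#' Computes, for every sample (or every site after pooling), the observed
#' richness, singleton and doubleton counts, Chao1, Shannon and inverse
#' Simpson indices, and - when a phylogeny is supplied - Faith's phylogenetic
#' diversity. Net relatedness (NRI) needs a null-model loop and lives in
#' [nri_profile()].
#'
#' @param x An [otu_table()].
#' @param level `"sample"` (default) or `"site"`; site level pools replicate
#'   samples with [pool_by_site()] before estimating.
#' @param tree Optional `ape::phylo` tree whose tip labels cover the OTU ids;
#'   adds a `faith_pd` column.
#' @return A tibble with one row per unit and columns `unit`, `level`,
#'   `total_count`, `s_obs`, `f1`, `f2`, `chao1`, `shannon`, `inv_simpson`
#'   and optionally `faith_pd`.
#' @export
alpha_profile <- function(x, level = c("sample", "site"), tree = NULL) {
  stopifnot(inherits(x, "otu_table"))
  level <- match.arg(level)
  tab <- if (level == "site") pool_by_site(x) else x
  counts <- tab$counts
  units <- colnames(counts)
  rows <- purrr::map(units, function(u) {
    v <- counts[, u]
    pos <- v[v > 0]
    tibble::tibble(
      unit = u,
      level = level,
      total_count = sum(v),
      s_obs = length(pos),
      f1 = sum(pos == 1),
      f2 = sum(pos == 2),
      chao1 = chao1(v),
      shannon = shannon(v),
      inv_simpson = inv_simpson(v)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(tree)) {
    out$faith_pd <- vapply(units, function(u) {
      present <- rownames(counts)[counts[, u] > 0]
      faith_pd(tree, present)
    }, numeric(1))
  }
  out
}
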