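#' Read a rooted phylogeny with branch lengths
#'
#' Thin wrapper over [ape::read.tree()] that enforces what downstream
#' computations need: unique tip labels and a branch length on every edge.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path), error = function(e) {
    stop("cannot parse Newick in '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  if (is.null(tree)) stop("cannot parse Newick in '", path, "'", call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree must have a branch length on every edge", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
      paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
      call. = FALSE
    )
  }
  tree
}

#' Cophenetic (patristic) distance matrix of a tree
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return Symmetric matrix of path-length distances between tips, zero on
#'   the diagonal, labelled by tip.
#' @export
cophenetic_dist <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::cophenetic.phylo(tree)
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths spanned by a set of present OTUs, using the
#' rooted convention: the union of root-to-tip paths of all present tips, so
#' the stem to the root is included. PD is monotone nondecreasing as tips are
#' added and equals the total tree length when all tips are present.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param present Character vector of present tip labels (nonempty, all known).
#' @return PD in branch-length units.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' faith_pd(tr, c("A", "B")) # 3: both unit tips plus their shared stem
#' @export
faith_pd <- function(tree, present) {
  stopifnot(inherits(tree, "phylo"))
  if (length(present) == 0) stop("present set is empty: PD undefined", call. = FALSE)
  idx <- match(present, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown OTU id(s): ", paste(present[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  # Walk each present tip up to the root, marking edges on the way; PD is the
  # length sum of the marked edge union.
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of_child <- integer(max(tree$edge))
  edge_of_child[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  on_path <- logical(nrow(tree$edge))
  for (tip in idx) {
    node <- tip
    while (parent_of[node] != 0L) {
      e <- edge_of_child[node]
      if (on_path[e]) break # rest of the path already marked
      on_path[e] <- TRUE
      node <- parent_of[node]
    }
  }
  sum(tree$edge.length[on_path])
}

#' Abundance-weighted mean pairwise phylogenetic distance
#'
#' \deqn{MPD = \sum_{i \ne j} d_{ij} x_i x_j / \sum_{i \ne j} x_i x_j}
#' with \eqn{d_{ij}} the cophenetic distance between taxa and \eqn{x_i} their
#' relative abundances. The denominator normalises by total off-diagonal
#' weight (the Phylocom abundance-weighted convention); set
#' `normalize = FALSE` for the raw weighted sum, useful for sensitivity
#' checks.
#'
#' @param d Square symmetric distance matrix over taxa (labels required).
#' @param x Relative-abundance vector, either named by taxa or aligned with
#'   the rows of `d`; must have at least two positive entries.
#' @param normalize Divide by total off-diagonal weight (default `TRUE`).
#' @return MPD in branch-length units.
#' @export
mpd_weighted <- function(d, x, normalize = TRUE) {
  d <- as.matrix(d)
  if (!is.null(names(x))) {
    if (!all(names(x) %in% rownames(d))) {
      stop("abundance names not all present in the distance matrix", call. = FALSE)
    }
    d <- d[names(x), names(x), drop = FALSE]
  }
  if (length(x) != nrow(d)) stop("abundance vector does not match matrix size", call. = FALSE)
  keep <- x > 0
  if (sum(keep) < 2) stop("MPD undefined with fewer than two present taxa", call. = FALSE)
  x <- x[keep]
  d <- d[keep, keep, drop = FALSE]
  w <- tcrossprod(x)
  diag(w) <- 0
  num <- sum(d * w)
  if (normalize) num / sum(w) else num
}

#' Net relatedness index with phylogeny-shuffle nulls
#'
#' Compares the observed abundance-weighted MPD of a community against a null
#' distribution in which tip labels are permuted uniformly at random across
#' the whole phylogeny (the "phylogeny shuffle": the species pool is the
#' tree), holding abundances fixed. Because the observed taxa land on a
#' uniformly random subset of tip positions under a full-label permutation,
#' each null replicate is drawn by sampling, without replacement, as many tip
#' positions as there are present taxa.
#'
#' \deqn{NRI = -(MPD_{obs} - \overline{MPD}_{null}) / sd(MPD_{null})}
#' so positive values indicate phylogenetic clustering. Null moments are
#' accumulated in a single pass; the full null vector is only retained on
#' request.
#'
#' @param tree An `ape::phylo` tree; its tips define the species pool.
#' @param abundances Named nonnegative count (or weight) vector over tip
#'   labels; at least two positive entries.
#' @param n_null Number of null communities (default 1000).
#' @param seed Integer seed (mandatory: permutations must be reproducible).
#' @param keep_null If `TRUE`, attach the vector of null MPDs as attribute
#'   `"null"` of the returned tibble.
#' @return One-row tibble: `mpd_obs`, `null_mean`, `null_sd`, `nri`,
#'   `undefined` (TRUE when the null has zero spread, e.g. on a star tree),
#'   `n_null`, `seed`.
#' @export
nri <- function(tree, abundances, n_null = 1000, seed, keep_null = FALSE) {
  stopifnot(inherits(tree, "phylo"), n_null >= 1)
  if (missing(seed)) stop("nri() requires an explicit seed", call. = FALSE)
  if (is.null(names(abundances))) stop("abundances must be named by tip label", call. = FALSE)
  unknown <- setdiff(names(abundances), tree$tip.label)
  if (length(unknown)) {
    stop("abundances name unknown tips: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  x <- abundances[abundances > 0]
  if (length(x) < 2) stop("NRI undefined with fewer than two present taxa", call. = FALSE)
  d_all <- cophenetic_dist(tree)
  n_tip <- nrow(d_all)
  x_rel <- x / sum(x)
  mpd_obs <- mpd_weighted(d_all[names(x), names(x)], as.numeric(x_rel))
  m <- length(x)
  # Welford single-pass moments over null replicates.
  mean_acc <- 0
  m2_acc <- 0
  null_vals <- if (keep_null) numeric(n_null) else NULL
  with_tdv_seed(seed, {
    for (b in seq_len(n_null)) {
      slots <- sample.int(n_tip, m)
      v <- mpd_weighted(d_all[slots, slots, drop = FALSE], as.numeric(x_rel))
      if (keep_null) null_vals[b] <- v
      delta <- v - mean_acc
      mean_acc <- mean_acc + delta / b
      m2_acc <- m2_acc + delta * (v - mean_acc)
    }
  })
  null_sd <- if (n_null > 1) sqrt(m2_acc / (n_null - 1)) else NA_real_
  undefined <- !is.na(null_sd) && null_sd < 1e-12
  out <- tibble::tibble(
    mpd_obs = mpd_obs,
    null_mean = mean_acc,
    null_sd = null_sd,
    nri = if (isTRUE(undefined) || is.na(null_sd)) NA_real_ else -(mpd_obs - mean_acc) / null_sd,
    undefined = isTRUE(undefined),
    n_null = as.integer(n_null),
    seed = as.integer(seed)
  )
  if (keep_null) attr(out, "null") <- null_vals
  out
}

#' NRI for every sample (or site) of an OTU table
#'
#' @param x An [otu_table()].
#' @param tree Tree over the OTU pool (tip labels cover the table's OTU ids).
#' @param level `"sample"` or `"site"`.
#' @param n_null Null communities per unit (default 1000).
#' @param seed Master seed; each unit gets its own substream so unit order
#'   does not matter.
#' @return Tibble with one row per unit: `unit`, `level`, plus the [nri()]
#'   columns.
#' @export
nri_profile <- function(x, tree, level = c("sample", "site"), n_null = 1000, seed) {
  stopifnot(inherits(x, "otu_table"))
  level <- match.arg(level)
  if (missing(seed)) stop("nri_profile() requires an explicit seed", call. = FALSE)
  tab <- if (level == "site") pool_by_site(x) else x
  counts <- tab$counts
  purrr::map(colnames(counts), function(u) {
    ab <- counts[, u]
    names(ab) <- rownames(counts)
    res <- nri(tree, ab, n_null = n_null, seed = tdv_subseed(seed, paste0("nri:", u)))
    dplyr::bind_cols(tibble::tibble(unit = u, level = level), res)
  }) |>
    dplyr::bind_rows()
}
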