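#' OTU count tables
#'
#' An `otu_table` holds a nonnegative integer count matrix with OTUs as rows
#' and samples as columns, plus an optional sample-to-site mapping. It is the
#' entry point for every downstream computation: alpha diversity, rarefaction,
#' community distances and Arrhenius fits.
#'
#' @param counts Integer matrix, OTUs x samples, with unique dimnames.
#' @param site_of Optional named character vector mapping sample id -> site id.
#'   Required by site-level operations such as [pool_by_site()].
#'
#' @return An object of class `otu_table`.
#' @examples
#' m <- matrix(c(1, 0, 2, 3), 2, 2,
#'   dimnames = list(c("otu1", "otu2"), c("s1", "s2"))
#' )
#' otu_table(m, site_of = c(s1 = "A", s2 = "A"))
#' @export
otu_table <- function(counts, site_of = NULL) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix without missing values", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
    (is.null(colnames(counts)) && ncol(counts) > 0)) {
    stop("counts must have OTU row names and sample column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate OTU ids: ", paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids: ", paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
      call. = FALSE
    )
  }
  storage.mode(counts) <- "double" # counts can exceed .Machine$integer.max when pooled
  if (!is.null(site_of)) {
    site_of <- site_of[colnames(counts)]
    if (anyNA(site_of)) {
      stop("site_of lacks a site for sample(s): ",
        paste(colnames(counts)[is.na(site_of)], collapse = ", "),
        call. = FALSE
      )
    }
  }
  structure(list(counts = counts, site_of = site_of), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(
    "<otu_table> ", nrow(x$counts), " OTUs x ", ncol(x$counts), " samples",
    if (!is.null(x$site_of)) paste0(" (", length(unique(x$site_of)), " sites)"), "\n",
    sep = ""
  )
  cat("total count: ", format(sum(x$counts), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.otu_table <- function(x, ...) x$counts

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Tidy view of an OTU table
#'
#' @param x An [otu_table()].
#' @param ... Unused.
#' @return A tibble with columns `otu_id`, `sample_id`, `count` and (when a
#'   site mapping is present) `site_id`; zero cells are kept so the long table
#'   round-trips to the matrix.
#' @export
as_tibble.otu_table <- function(x, ...) {
  out <- tibble::tibble(
    otu_id = rep(rownames(x$counts), times = ncol(x$counts)),
    sample_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.vector(x$counts)
  )
  if (!is.null(x$site_of)) {
    out$site_id <- unname(x$site_of[out$sample_id])
  }
  out
}

#' Read an OTU table from TSV
#'
#' Expects a tab-separated file whose first row holds sample ids (the first
#' cell of the header is ignored) and whose first column holds OTU ids; all
#' remaining cells must be nonnegative integers.
#'
#' @param path Path to a TSV file.
#' @param site_of Optional named character vector mapping sample id -> site id,
#'   typically `site map` from [read_sample_metadata()].
#' @return An [otu_table()] with labels in file order.
#' @export
read_otu_table <- function(path, site_of = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("OTU table is empty or has no data rows: ", path, call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  otu_ids <- vapply(rows, `[[`, character(1), 1L)
  counts <- matrix(NA_real_, length(rows), length(sample_ids),
    dimnames = list(otu_ids, sample_ids)
  )
  for (r in seq_along(rows)) {
    cells <- rows[[r]][-1]
    if (length(cells) != length(sample_ids)) {
      stop("row '", otu_ids[r], "' has ", length(cells), " cells, expected ",
        length(sample_ids),
        call. = FALSE
      )
    }
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      stop("cell at OTU '", otu_ids[r], "', sample '", sample_ids[bad],
        "' is not a number: '", cells[bad], "'",
        call. = FALSE
      )
    }
    counts[r, ] <- vals
  }
  otu_table(counts, site_of = site_of)
}

#' Write an OTU table to TSV
#'
#' @param x An [otu_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  header <- paste(c("otu_id", colnames(x$counts)), collapse = "\t")
  body <- vapply(seq_len(nrow(x$counts)), function(r) {
    paste(c(rownames(x$counts)[r], format(x$counts[r, ], scientific = FALSE, trim = TRUE)),
      collapse = "\t"
    )
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Pool samples into site-level communities
#'
#' Sums each OTU's counts over all samples belonging to a site, mirroring the
#' pooling of within-site replicates before site-level richness estimation.
#' The grand total of the table is conserved.
#'
#' @param x An [otu_table()].
#' @param site_of Optional sample -> site map; defaults to the one stored in `x`.
#' @return An [otu_table()] whose columns are site ids.
#' @export
pool_by_site <- function(x, site_of = NULL) {
  stopifnot(inherits(x, "otu_table"))
  site_of <- site_of %||% x$site_of
  if (is.null(site_of)) stop("no sample-to-site mapping available", call. = FALSE)
  site_of <- site_of[colnames(x$counts)]
  if (anyNA(site_of)) {
    stop("site mapping missing for sample(s): ",
      paste(colnames(x$counts)[is.na(site_of)], collapse = ", "),
      call. = FALSE
    )
  }
  sites <- unique(unname(site_of))
  pooled <- vapply(sites, function(s) {
    rowSums(x$counts[, site_of == s, drop = FALSE])
  }, numeric(nrow(x$counts)))
  pooled <- matrix(pooled,
    nrow = nrow(x$counts),
    dimnames = list(rownames(x$counts), sites)
  )
  otu_table(pooled)
}

#' Standard rarefaction depths
#'
#' Named subsampling depths commonly used for the three marker genes: the
#' smallest per-sample read count in each data set (16S rRNA, fungal ITS and
#' nifH) so that all samples are compared at equal sequencing effort.
#'
#' @format Named integer vector.
#' @export
rarefaction_depths <- c("16S" = 25901L, "ITS" = 13688L, "nifH" = 16000L)

#' Rarefy an OTU table to equal depth
#'
#' Subsamples each sample's reads without replacement down to `depth`, the
#' standard device for comparing observed richness across samples of unequal
#' sequencing depth. Each column uses its own RNG substream derived from
#' `seed` and the sample id, so results do not depend on column order.
#'
#' @param x An [otu_table()].
#' @param depth Target reads per sample; a positive integer or a name of
#'   [rarefaction_depths].
#' @param seed Integer seed; required for reproducibility.
#' @param drop_small If `TRUE`, samples shallower than `depth` are dropped with
#'   a warning instead of raising an error.
#' @return An [otu_table()] whose columns each sum to `depth`.
#' @examples
#' m <- matrix(c(8, 2, 5, 5), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
#' rarefy(otu_table(m), depth = 5, seed = 1)
#' @export
rarefy <- function(x, depth, seed, drop_small = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  if (is.character(depth)) {
    if (!depth %in% names(rarefaction_depths)) {
      stop("unknown depth preset '", depth, "'; available: ",
        paste(names(rarefaction_depths), collapse = ", "),
        call. = FALSE
      )
    }
    depth <- rarefaction_depths[[depth]]
  }
  stopifnot(is.numeric(depth), length(depth) == 1, depth >= 1, depth == round(depth))
  if (missing(seed)) stop("rarefy() requires an explicit seed", call. = FALSE)
  totals <- colSums(x$counts)
  shallow <- totals < depth
  if (any(shallow)) {
    if (!drop_small) {
      stop("depth ", depth, " exceeds the total count of sample(s): ",
        paste(colnames(x$counts)[shallow], collapse = ", "),
        call. = FALSE
      )
    }
    warning(
      "dropping ", sum(shallow), " sample(s) below depth ", depth, ": ",
      paste(colnames(x$counts)[shallow], collapse = ", ")
    )
  }
  keep <- which(!shallow)
  out <- matrix(0, nrow(x$counts), length(keep),
    dimnames = list(rownames(x$counts), colnames(x$counts)[keep])
  )
  for (k in seq_along(keep)) {
    j <- keep[k]
    out[, k] <- rarefy_column(x$counts[, j], depth, tdv_subseed(seed, colnames(x$counts)[j]))
  }
  otu_table(out, site_of = if (!is.null(x$site_of)) x$site_of[colnames(out)])
}

# Draw `depth` reads without replacement from one sample's read multiset:
# a multivariate hypergeometric draw implemented by sampling read positions
# and mapping them back to OTUs through the cumulative counts.
rarefy_column <- function(counts, depth, seed) {
  total <- sum(counts)
  if (total == depth) {
    return(counts)
  }
  with_tdv_seed(seed, {
    pos <- sample.int(total, depth)
    idx <- findInterval(pos, cumsum(counts), left.open = TRUE) + 1L
    tabulate(idx, nbins = length(counts))
  })
}

#' Merge sister OTUs to emulate a coarser clustering cutoff
#'
#' Collapses every cherry of the phylogeny (a pair of tips that are mutual
#' sisters) into a single OTU by summing their counts, mimicking the effect of
#' re-clustering sequences at a lower similarity cutoff (for example 95%
#' instead of 97%). Used to study how apparent activation energies change with
#' taxonomic resolution.
#'
#' @param x An [otu_table()] whose OTU ids appear among the tree's tip labels.
#' @param tree An `ape::phylo` tree over the OTU pool.
#' @return A list with the coarsened `table` (an [otu_table()]), the pruned
#'   `tree`, and `merged`, a tibble mapping each absorbed OTU to the OTU that
#'   kept the merged counts.
#' @export
merge_sister_otus <- function(x, tree) {
  stopifnot(inherits(x, "otu_table"), inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  tip_edges <- tree$edge[, 2] <= n_tip
  parents <- tree$edge[tip_edges, 1]
  children <- tree$edge[tip_edges, 2]
  cherries <- split(children, parents)
  cherries <- cherries[lengths(cherries) == 2]
  if (length(cherries) == 0) {
    return(list(
      table = x, tree = tree,
      merged = tibble::tibble(absorbed = character(), into = character())
    ))
  }
  counts <- x$counts
  drop <- character(0)
  absorbed <- character(0)
  into <- character(0)
  for (pair in cherries) {
    keep_lab <- tree$tip.label[pair[1]]
    drop_lab <- tree$tip.label[pair[2]]
    if (!keep_lab %in% rownames(counts) || !drop_lab %in% rownames(counts)) next
    counts[keep_lab, ] <- counts[keep_lab, ] + counts[drop_lab, ]
    drop <- c(drop, drop_lab)
    absorbed <- c(absorbed, drop_lab)
    into <- c(into, keep_lab)
  }
  counts <- counts[setdiff(rownames(counts), drop), , drop = FALSE]
  pruned <- if (length(drop)) ape::drop.tip(tree, drop) else tree
  list(
    table = otu_table(counts, site_of = x$site_of),
    tree = pruned,
    merged = tibble::tibble(absorbed = absorbed, into = into)
  )
}
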