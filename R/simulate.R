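#' Configuration for the synthetic multi-site metacommunity
#'
#' Defines the study conditions the generator emulates: six forest sites
#' spanning mean annual temperatures 2.5-25.7 degrees C, 21 replicate soil
#' samples per site, site-level true richness following the Boltzmann
#' relationship \eqn{\ln S = a - E_a/(kT)}, a lognormal species-abundance
#' distribution whose rare tail produces the singleton-rich samples on which
#' Chao1 exceeds observed richness, per-sample sequencing depths in the tens
#' of thousands, a random phylogeny over the OTU pool, and environmental
#' covariates correlated with temperature.
#'
#' @param n_sites Number of sites (default 6).
#' @param temps_c Site mean annual temperatures, degrees C, strictly
#'   increasing (default `c(2.5, 7, 12, 17, 21, 25.7)`).
#' @param samples_per_site Replicate samples per site (default 21).
#' @param true_ea True activation energy in eV (default 0.25, in the range
#'   observed for soil microbial taxa).
#' @param intercept_a Intercept of `ln S = a - Ea/(kT)` (default 16, giving a
#'   few hundred OTUs per site at the default `true_ea`; pass a smaller value,
#'   around 6, when `true_ea = 0` to keep richness at the same scale).
#' @param depth Reads per sample (default 20000).
#' @param sad_meanlog,sad_sdlog Lognormal species-abundance parameters
#'   (defaults 0 and 1.5: a heavy rare tail without making coverage collapse).
#' @param env_noise Covariate noise, as a multiple of each covariate's
#'   temperature-driven standard deviation (default 0.5; 0 makes covariates
#'   perfectly collinear with temperature).
#' @param pools `"nested"` (warmer sites add species to the colder sites'
#'   pool; default) or `"disjoint"` (each site has its own species, maximising
#'   between-site turnover).
#' @param seed Master seed; all randomness flows from it through named
#'   substreams (tree, abundances, sampling, environment).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 6,
                       temps_c = c(2.5, 7, 12, 17, 21, 25.7),
                       samples_per_site = 21,
                       true_ea = 0.25,
                       intercept_a = 16,
                       depth = 20000,
                       sad_meanlog = 0,
                       sad_sdlog = 1.5,
                       env_noise = 0.5,
                       pools = c("nested", "disjoint"),
                       seed = 1) {
  pools <- match.arg(pools)
  if (length(temps_c) != n_sites) stop("temps_c must have n_sites values", call. = FALSE)
  if (any(diff(temps_c) <= 0)) stop("temps_c must be strictly increasing", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (true_ea < 0) stop("true_ea must be >= 0", call. = FALSE)
  structure(
    list(
      n_sites = n_sites, temps_c = temps_c, samples_per_site = samples_per_site,
      true_ea = true_ea, intercept_a = intercept_a, depth = depth,
      sad_meanlog = sad_meanlog, sad_sdlog = sad_sdlog,
      env_noise = env_noise, pools = pools, seed = seed
    ),
    class = "sim_config"
  )
}

#' True site richness implied by a simulation configuration
#'
#' \eqn{S = \mathrm{round}(\exp(a - E_a/(kT)))}: richness on the exact
#' Boltzmann line, rounded to integers, so before rounding `ln S` against
#' `1/(kT)` is exactly linear with slope `-true_ea`.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with `site_id`, `temperature_c`, `s_true`.
#' @export
site_richness <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tk <- cfg$temps_c + 273.15
  s <- round(exp(cfg$intercept_a - cfg$true_ea / (boltzmann_ev * tk)))
  if (any(s < 2)) {
    stop("configuration implies site richness < 2; increase intercept_a", call. = FALSE)
  }
  tibble::tibble(
    site_id = sprintf("site%02d", seq_len(cfg$n_sites)),
    temperature_c = cfg$temps_c,
    s_true = as.numeric(s)
  )
}

#' Random phylogeny over an OTU pool
#'
#' Builds a rooted binary topology by iteratively joining random pairs of
#' subtrees, with independent exponential branch lengths, and returns it as an
#' `ape::phylo` object. Tip labels are `otu0001, otu0002, ...` unless given.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @param labels Optional tip labels (length `n_tips`).
#' @param rate Rate of the exponential branch lengths (default 1).
#' @return An `ape::phylo` tree.
#' @export
generate_tree <- function(n_tips, seed, labels = NULL, rate = 1) {
  stopifnot(n_tips >= 2)
  if (is.null(labels)) labels <- sprintf("otu%04d", seq_len(n_tips))
  stopifnot(length(labels) == n_tips)
  newick <- with_tdv_seed(seed, {
    nodes <- as.list(labels)
    while (length(nodes) > 1) {
      pick <- sample.int(length(nodes), 2)
      bl <- stats::rexp(2, rate = rate)
      joined <- sprintf(
        "(%s:%.10f,%s:%.10f)",
        nodes[[pick[1]]], bl[1], nodes[[pick[2]]], bl[2]
      )
      nodes[[pick[1]]] <- joined
      nodes[[pick[2]]] <- NULL
    }
    paste0(nodes[[1]], ";")
  })
  ape::read.tree(text = newick)
}

#' Generate a synthetic multi-site OTU data set
#'
#' Draws, per site, the `s_true` species (from a global pool, nested across
#' sites by default) with lognormal relative abundances, then draws each
#' sample's reads multinomially from the site's abundance vector, so typical
#' configurations yield singletons and doubletons and Chao1 exceeds observed
#' richness at the sample level. Environmental covariates (precipitation, pH,
#' moisture, total C, total N, plant richness) are linear functions of site
#' temperature plus Gaussian noise scaled by `env_noise`. Fully deterministic
#' given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `table` (an [otu_table()] with sample-to-site mapping),
#'   `tree` (phylogeny over the OTU pool), `metadata` (tibble, one row per
#'   sample) and `truth` (list: `true_ea`, `intercept_a`, `site_richness`).
#' @examples
#' sim <- generate_dataset(sim_config(samples_per_site = 3, depth = 500, seed = 7))
#' dim(sim$table)
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sr <- site_richness(cfg)
  n_pool <- if (cfg$pools == "nested") max(sr$s_true) else sum(sr$s_true)
  otu_ids <- sprintf("otu%04d", seq_len(n_pool))
  tree <- generate_tree(n_pool, seed = tdv_subseed(cfg$seed, "tree"), labels = otu_ids)
  # Global lognormal abundance weights and the pool ordering that defines
  # which species each site holds.
  sad <- with_tdv_seed(tdv_subseed(cfg$seed, "sad"), {
    list(
      w = stats::rlnorm(n_pool, cfg$sad_meanlog, cfg$sad_sdlog),
      order = sample.int(n_pool)
    )
  })
  site_species <- vector("list", cfg$n_sites)
  offset <- 0
  for (k in seq_len(cfg$n_sites)) {
    s_k <- sr$s_true[k]
    site_species[[k]] <- if (cfg$pools == "nested") {
      sad$order[seq_len(s_k)]
    } else {
      sad$order[offset + seq_len(s_k)]
    }
    offset <- offset + s_k
  }
  sample_ids <- character(0)
  site_of <- character(0)
  counts <- matrix(0, n_pool, cfg$n_sites * cfg$samples_per_site,
    dimnames = list(otu_ids, NULL)
  )
  col <- 0
  for (k in seq_len(cfg$n_sites)) {
    sp <- site_species[[k]]
    p <- sad$w[sp] / sum(sad$w[sp])
    for (r in seq_len(cfg$samples_per_site)) {
      col <- col + 1
      sid <- sprintf("%s_s%02d", sr$site_id[k], r)
      sample_ids[col] <- sid
      site_of[col] <- sr$site_id[k]
      counts[sp, col] <- with_tdv_seed(
        tdv_subseed(cfg$seed, paste0("sample:", sid)),
        as.numeric(stats::rmultinom(1, cfg$depth, p))
      )
    }
  }
  colnames(counts) <- sample_ids
  names(site_of) <- sample_ids
  metadata <- simulate_metadata(cfg, sr, sample_ids, site_of)
  list(
    table = otu_table(counts, site_of = site_of),
    tree = tree,
    metadata = metadata,
    truth = list(
      true_ea = cfg$true_ea, intercept_a = cfg$intercept_a,
      site_richness = sr
    )
  )
}

# Covariates as linear functions of site temperature plus Gaussian noise.
# Noise sd = env_noise * |slope| * sd(site temps), so env_noise is the
# noise-to-signal ratio and env_noise = 0 gives perfect collinearity.
simulate_metadata <- function(cfg, sr, sample_ids, site_of) {
  t_site <- stats::setNames(sr$temperature_c, sr$site_id)
  t_sd <- stats::sd(sr$temperature_c)
  lin <- list(
    # variable       intercept  slope   scope
    precipitation_mm = c(700, 90, 0), # site-level
    plant_richness = c(12, 3.4, 0), # site-level
    ph = c(7.8, -0.10, 1), # per-sample
    moisture_pct = c(18, 0.9, 1),
    total_c = c(2.2, 0.16, 1),
    total_n = c(0.16, 0.010, 1)
  )
  meta <- tibble::tibble(
    sample_id = sample_ids,
    site_id = unname(site_of),
    temperature_c = unname(t_site[site_of])
  )
  with_tdv_seed(tdv_subseed(cfg$seed, "env"), {
    for (v in names(lin)) {
      a <- lin[[v]][1]
      b <- lin[[v]][2]
      per_sample <- lin[[v]][3] == 1
      noise_sd <- cfg$env_noise * abs(b) * t_sd
      if (per_sample) {
        vals <- a + b * meta$temperature_c + stats::rnorm(nrow(meta), 0, noise_sd)
      } else {
        site_vals <- a + b * t_site + stats::rnorm(length(t_site), 0, noise_sd)
        vals <- unname(site_vals[meta$site_id])
      }
      meta[[v]] <- vals
    }
  })
  meta$plant_richness <- round(pmax(meta$plant_richness, 1))
  meta
}

#' Write a simulated data set to plain-text files
#'
#' Writes `table.tsv` (OTU table), `tree.nwk`, `meta.tsv` and `truth.json`
#' into a directory, the on-disk layout the pipeline reads.
#'
#' @param sim Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(sim$table, file.path(dir, "table.tsv"))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  write_sample_metadata(sim$metadata, file.path(dir, "meta.tsv"))
  jsonlite::write_json(
    list(
      true_ea = sim$truth$true_ea,
      intercept_a = sim$truth$intercept_a,
      site_richness = sim$truth$site_richness
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
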