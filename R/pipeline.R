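#' Run the full diversity-temperature analysis from a YAML config
#'
#' Orchestrates the whole pipeline on an OTU table, sample metadata and
#' (optionally) a phylogeny: optional rarefaction, per-sample and per-site
#' alpha diversity (with Faith PD and NRI when a tree is given), Bray-Curtis
#' community distance, BioENV variable selection, a partial-Mantel panel
#' (each factor tested against the community matrix controlling for the
#' others), and Boltzmann-Arrhenius fits of Chao1 richness against
#' temperature at both sample and site level with AIC model selection.
#'
#' The YAML config names the inputs and seeds; all paths are resolved
#' relative to the config file. Recognised keys:
#' \preformatted{
#' table: table.tsv          # required
#' metadata: meta.tsv        # required
#' tree: tree.nwk            # optional; omitting skips Faith PD and NRI
#' seed: 1                   # master seed (required)
#' rarefy_depth: 20000       # optional; omit to analyse raw counts
#' n_perm: 999               # Mantel permutations
#' n_null: 1000              # NRI null communities
#' models: [linear, quadratic, piecewise]
#' bioenv_variables: [temperature_c, precipitation_mm, ph, total_c, total_n]
#' panel:                    # partial-Mantel factors; each entry is a factor
#'   - [temperature_c]       # tested controlling for all other factors
#'   - [precipitation_mm]
#'   - [ph]
#'   - [total_n, total_c]
#' }
#'
#' @param config_path Path to the YAML configuration.
#' @param out_dir Optional directory; when given, all result tables are
#'   written as TSV plus a JSON report and a log file.
#' @return A `thermodiv_report` list: `alpha_sample`, `alpha_site`,
#'   `nri_sample` (or NULL), `bioenv`, `mantel_panel`, `arrhenius`,
#'   `model_selection`, `provenance`.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(normalizePath(config_path))
  resolve <- function(p) if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log_con <- file(file.path(out_dir, "log.txt"), open = "wt")
    on.exit(close(log_con), add = TRUE)
  }
  log_msg <- function(stage, ...) {
    line <- paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] [", stage, "] ", ...)
    message(line)
    if (!is.null(log_con)) writeLines(line, log_con)
  }
  stage <- function(name, expr) {
    log_msg(name, "start")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (is.null(cfg$seed)) stop("config must set a seed", call. = FALSE)
  seed <- as.integer(cfg$seed)
  n_perm <- cfg$n_perm %||% 999
  n_null <- cfg$n_null %||% 1000
  models <- unlist(cfg$models %||% c("linear", "quadratic", "piecewise"))
  bioenv_vars <- unlist(cfg$bioenv_variables %||%
    c("temperature_c", "precipitation_mm", "ph", "total_c", "total_n"))
  panel <- cfg$panel %||% list(
    "temperature_c", "precipitation_mm", "ph",
    c("total_n", "total_c")
  )
  panel <- lapply(panel, unlist)

  meta <- stage("read", {
    if (is.null(cfg$table) || is.null(cfg$metadata)) {
      stop("config must name 'table' and 'metadata'")
    }
    read_sample_metadata(resolve(cfg$metadata))
  })
  tab <- stage("read", read_otu_table(resolve(cfg$table), site_of = site_map(meta)))
  tree <- NULL
  if (!is.null(cfg$tree)) {
    tree <- stage("read", read_newick(resolve(cfg$tree)))
  } else {
    log_msg("read", "no tree in config: skipping Faith PD and NRI")
  }

  if (!is.null(cfg$rarefy_depth)) {
    tab <- stage("rarefy", rarefy(tab, cfg$rarefy_depth, seed = tdv_subseed(seed, "rarefy")))
    log_msg("rarefy", "rarefied to depth ", cfg$rarefy_depth)
  }

  alpha_sample <- stage("alpha", alpha_profile(tab, "sample", tree = tree))
  alpha_site <- stage("alpha", alpha_profile(tab, "site", tree = tree))

  nri_sample <- NULL
  if (!is.null(tree)) {
    nri_sample <- stage("nri", nri_profile(tab, tree,
      level = "sample",
      n_null = n_null, seed = tdv_subseed(seed, "nri")
    ))
  }

  comm_d <- stage("distance", bray_curtis(tab))
  bioenv_res <- stage("bioenv", bioenv_best(comm_d, meta, bioenv_vars))
  log_msg(
    "bioenv", "best subset: ", paste(bioenv_res$best, collapse = ", "),
    " (rho = ", format(bioenv_res$rho, digits = 3), ")"
  )

  mantel_panel <- stage("mantel", {
    purrr::map(seq_along(panel), function(i) {
      fac <- panel[[i]]
      others <- panel[-i]
      d_fac <- env_distance(meta, fac)
      controls <- lapply(others, function(v) env_distance(meta, v))
      names(controls) <- vapply(others, paste, character(1), collapse = ", ")
      res <- partial_mantel(comm_d, d_fac, controls,
        n_perm = n_perm,
        seed = tdv_subseed(seed, paste0("mantel:", paste(fac, collapse = "+")))
      )
      dplyr::bind_cols(
        tibble::tibble(factor = paste(fac, collapse = ", ")),
        res
      )
    }) |> dplyr::bind_rows()
  })

  site_meta <- site_metadata(meta)
  arrhenius <- stage("mte", {
    purrr::map(c("sample", "site"), function(lev) {
      alpha <- if (lev == "sample") alpha_sample else alpha_site
      temp <- if (lev == "sample") {
        meta$temperature_c[match(alpha$unit, meta$sample_id)]
      } else {
        site_meta$temperature_c[match(alpha$unit, site_meta$site_id)]
      }
      pts <- arrhenius_points(
        dplyr::mutate(alpha, temperature_c = temp),
        .data$chao1, .data$temperature_c,
        unit = .data$unit
      )
      fits <- lapply(models, function(m) fit_arrhenius(pts, m))
      sel <- if (length(fits) >= 2) select_model(fits) else NULL
      list(level = lev, points = pts, fits = fits, selection = sel)
    })
  })
  fit_table <- purrr::map(arrhenius, function(a) {
    dplyr::bind_rows(lapply(a$fits, glance.mte_fit)) |>
      dplyr::mutate(level = a$level, .before = 1)
  }) |> dplyr::bind_rows()
  selection_table <- purrr::map(arrhenius, function(a) {
    if (is.null(a$selection)) {
      return(NULL)
    }
    dplyr::mutate(a$selection, level = a$level, .before = 1)
  }) |> dplyr::bind_rows()

  provenance <- list(
    package_version = as.character(utils::packageVersion("thermodiv")),
    config = normalizePath(config_path),
    config_md5 = unname(tools::md5sum(config_path)),
    seed = seed, n_perm = n_perm, n_null = n_null, models = models
  )

  report <- structure(
    list(
      alpha_sample = alpha_sample, alpha_site = alpha_site,
      nri_sample = nri_sample, bioenv = bioenv_res,
      mantel_panel = mantel_panel,
      arrhenius = fit_table, model_selection = selection_table,
      provenance = provenance
    ),
    class = "thermodiv_report"
  )

  if (!is.null(out_dir)) {
    stage("write", {
      wt <- function(df, name) {
        utils::write.table(df, file.path(out_dir, name),
          sep = "\t",
          quote = FALSE, row.names = FALSE
        )
      }
      wt(alpha_sample, "alpha_sample.tsv")
      wt(alpha_site, "alpha_site.tsv")
      if (!is.null(nri_sample)) wt(nri_sample, "nri_sample.tsv")
      wt(mantel_panel, "mantel_panel.tsv")
      wt(bioenv_res$ranking, "bioenv_ranking.tsv")
      wt(fit_table, "mte_fits.tsv")
      wt(selection_table, "model_selection.tsv")
      jsonlite::write_json(
        list(
          provenance = provenance,
          bioenv_best = bioenv_res$best,
          mantel_panel = mantel_panel,
          mte_fits = fit_table,
          model_selection = selection_table
        ),
        file.path(out_dir, "report.json"),
        auto_unbox = TRUE, digits = NA
      )
    })
    log_msg("write", "report written to ", out_dir)
  }
  report
}

#' @export
print.thermodiv_report <- function(x, ...) {
  cat("<thermodiv_report>\n")
  cat("  alpha: ", nrow(x$alpha_sample), " samples, ", nrow(x$alpha_site), " sites\n", sep = "")
  cat("  bioenv best: ", paste(x$bioenv$best, collapse = ", "), "\n", sep = "")
  cat("  mantel panel:\n")
  print(x$mantel_panel[, c("factor", "r_m", "p")])
  cat("  arrhenius fits:\n")
  print(x$arrhenius[, c("level", "form", "ea", "r2", "aic")])
  invisible(x)
}
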