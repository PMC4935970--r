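#' Read sample metadata from TSV
#'
#' The metadata table has one row per sample with columns `sample_id`,
#' `site_id`, `temperature_c` (mean annual temperature, degrees Celsius),
#' `precipitation_mm`, `ph`, `moisture_pct`, `total_c`, `total_n` and
#' `plant_richness`; empty cells are read as missing. Temperatures stay in
#' Celsius throughout the package and are converted to kelvin only inside the
#' Arrhenius machinery.
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path,
    sep = "\t", header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, na.strings = c("", "NA")
  )
  if (!all(c("sample_id", "site_id") %in% names(df))) {
    stop("metadata must contain sample_id and site_id columns", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in metadata", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write sample metadata to TSV
#'
#' @param meta A metadata tibble as returned by [read_sample_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    na = ""
  )
  invisible(path)
}

#' Sample -> site map from a metadata table
#'
#' @param meta Metadata tibble with `sample_id` and `site_id` columns.
#' @return Named character vector mapping sample id to site id.
#' @export
site_map <- function(meta) {
  stats::setNames(as.character(meta$site_id), meta$sample_id)
}

#' Aggregate sample metadata to site level
#'
#' Variables measured once per site (temperature, precipitation, plant
#' richness) are carried through unchanged; variables measured per sample
#' (pH, moisture, total C, total N, ...) are averaged arithmetically across a
#' site's samples, the convention used when site-level covariates are needed
#' alongside site-level diversity.
#'
#' @param meta Metadata tibble, one row per sample.
#' @return A tibble with one row per site.
#' @export
site_metadata <- function(meta) {
  stopifnot(all(c("sample_id", "site_id") %in% names(meta)))
  num_vars <- setdiff(
    names(meta)[vapply(meta, is.numeric, logical(1))],
    c("sample_id", "site_id")
  )
  meta |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      dplyr::across(dplyr::all_of(num_vars), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
}
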