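#' Read a wide protein quantification table
#'
#' Parses a tab-separated protein-groups style export: one row per protein,
#' one abundance column per (treatment, replicate, temperature) sample
#' channel, as described by `config$sample_map`. Optional `peptide_count`
#' (or `Peptides`) and `contaminant` (or `Potential contaminant`) columns
#' drive the quantification filters: contaminant rows and rows quantified
#' with fewer than `config$min_peptides` peptides are flagged as excluded —
#' never silently dropped.
#'
#' @param path Path to a TSV file with a header row; the first
#'   non-abundance column (or a column named `protein_id`, `Protein IDs` or
#'   `Accession`) identifies the protein.
#' @param config A [screen_config()] whose `sample_map` covers every
#'   abundance column.
#'
#' @return A long tibble with one row per protein, treatment, replicate and
#'   temperature: columns `protein_id`, `treatment`, `replicate`,
#'   `temperature`, `abundance`, `peptide_count`, `contaminant`, `excluded`,
#'   `exclude_reason`. Missing abundances stay `NA`.
#' @export
read_protein_quant <- function(path, config) {
  stopifnot(inherits(config, "screen_config"))
  map <- config$sample_map
  if (is.null(map)) abort("`config` carries no sample map; see `sample_map()`.")
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  quant_from_wide(wide, config)
}

#' Convert an in-memory wide quant table to the canonical long form
#'
#' Same contract as [read_protein_quant()] but starting from a data frame,
#' e.g. one produced by [simulate_experiment()].
#'
#' @param wide Wide data frame of abundances.
#' @param config A [screen_config()] with a sample map.
#' @return A long tibble; see [read_protein_quant()].
#' @export
quant_from_wide <- function(wide, config) {
  map <- check_sample_map(config$sample_map, config$grid)
  wide <- tibble::as_tibble(wide)

  id_col <- intersect(c("protein_id", "Protein IDs", "Accession"), names(wide))[1]
  if (is.na(id_col)) id_col <- setdiff(names(wide), map$column)[1]
  if (is.na(id_col)) abort("no protein identifier column found.")

  missing_cols <- setdiff(map$column, names(wide))
  if (length(missing_cols)) {
    abort(paste0(
      "sample map names column(s) absent from the table: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  known <- c(
    id_col, map$column, "peptide_count", "Peptides",
    "contaminant", "Potential contaminant"
  )
  stray <- setdiff(names(wide), known)
  if (length(stray)) {
    abort(paste0(
      "configuration error: unmapped abundance column(s): ",
      paste(stray, collapse = ", ")
    ))
  }
  if (anyDuplicated(wide[[id_col]])) {
    dup <- unique(wide[[id_col]][duplicated(wide[[id_col]])])
    abort(paste0("duplicate protein_id in table: ", paste(head(dup, 5), collapse = ", ")))
  }

  pep_col <- intersect(c("peptide_count", "Peptides"), names(wide))[1]
  con_col <- intersect(c("contaminant", "Potential contaminant"), names(wide))[1]
  pep <- if (!is.na(pep_col)) as.integer(wide[[pep_col]]) else rep(NA_integer_, nrow(wide))
  con <- if (!is.na(con_col)) contaminant_flag(wide[[con_col]]) else rep(FALSE, nrow(wide))

  reason <- dplyr::case_when(
    con ~ "contaminant",
    !is.na(pep) & pep < config$min_peptides ~ "min_peptides",
    .default = NA_character_
  )
  meta <- tibble::tibble(
    protein_id = as.character(wide[[id_col]]),
    peptide_count = pep,
    contaminant = con,
    excluded = !is.na(reason),
    exclude_reason = reason
  )

  long <- wide[c(id_col, map$column)] |>
    rlang::set_names(c("protein_id", map$column)) |>
    dplyr::mutate(protein_id = as.character(.data$protein_id)) |>
    tidyr::pivot_longer(-"protein_id", names_to = "column", values_to = "abundance") |>
    dplyr::left_join(map, by = "column") |>
    dplyr::select("protein_id", "treatment", "replicate", "temperature", "abundance")
  if (any(long$abundance < 0, na.rm = TRUE)) {
    abort("negative abundances encountered; intensities must be >= 0 or missing.")
  }
  long |>
    dplyr::left_join(meta, by = "protein_id") |>
    dplyr::arrange(.data$protein_id, .data$treatment, .data$replicate, .data$temperature)
}

contaminant_flag <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x <- trimws(as.character(x))
  !is.na(x) & x %in% c("+", "TRUE", "True", "true", "yes", "1")
}

#' Write a candidate-record table to TSV
#'
#' One row per protein; missing values (e.g. the VIP of a protein absent
#' from the OPLS input) are written as empty cells, not zeros. The output
#' round-trips losslessly through [read_results()].
#'
#' @param records Tibble of candidate records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  records <- tibble::as_tibble(records)
  readr::write_tsv(records, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return A tibble; empty cells become `NA`.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE, progress = FALSE)
}
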