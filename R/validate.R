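#' Quality-filter and normalize a phosphopeptide table
#'
#' Keeps peptides passing all three gates — site localization probability
#' strictly above `loc_prob_min`, search-engine score strictly above
#' `score_min` and delta score strictly above `delta_min` — then divides
#' each surviving abundance by the total abundance of its channel
#' (computed over the table before filtering) and log2-transforms.
#'
#' @param records Tibble with `localization_probability`, `score`,
#'   `delta_score` and one abundance column per channel.
#' @param channels Character vector naming the abundance columns; defaults
#'   to every numeric column other than the three gate columns.
#' @param loc_prob_min,score_min,delta_min Gate thresholds (defaults 0.75,
#'   40, 8).
#' @return The filtered tibble with channel abundances replaced by
#'   log2(channel-normalized) values.
#' @export
filter_phosphopeptides <- function(records, channels = NULL,
                                   loc_prob_min = 0.75, score_min = 40,
                                   delta_min = 8) {
  records <- tibble::as_tibble(records)
  gates <- c("localization_probability", "score", "delta_score")
  miss <- setdiff(gates, names(records))
  if (length(miss)) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (any(records$localization_probability < 0 | records$localization_probability > 1,
    na.rm = TRUE
  )) {
    abort("localization probabilities must lie in [0, 1].")
  }
  channels <- channels %||% setdiff(
    names(records)[vapply(records, is.numeric, logical(1))], gates
  )
  if (nrow(records) == 0) return(records)

  totals <- vapply(records[channels], sum, numeric(1), na.rm = TRUE)
  if (any(totals == 0)) {
    abort(paste0(
      "zero total abundance in channel(s): ",
      paste(channels[totals == 0], collapse = ", ")
    ))
  }
  keep <- records$localization_probability > loc_prob_min &
    records$score > score_min &
    records$delta_score > delta_min
  keep[is.na(keep)] <- FALSE
  out <- records[keep, , drop = FALSE]
  for (ch in channels) out[[ch]] <- log2(out[[ch]] / totals[[ch]])
  out
}

#' Normalize a label-free matrix and impute missing values
#'
#' Intensities are divided by each sample's total, log2-transformed,
#' proteins with more than `max_missing` missing values are excluded, and
#' the remaining missing cells are drawn from a down-shifted normal
#' distribution: per sample, Normal(mean - `shift` * SD, (`width` * SD)^2)
#' of that sample's observed log2 distribution (`width_mode = "absolute"`
#' uses `width` directly as the SD). Observed cells are never altered;
#' exclusion precedes imputation.
#'
#' @param matrix Tibble with `protein_id` and one positive-intensity
#'   column per sample (`NA` = missing).
#' @param seed Integer seed for the imputation draws.
#' @param max_missing Maximum missing values per protein (default 4, of a
#'   typical 8-sample layout).
#' @param shift Downshift in sample SDs (default 1.8).
#' @param width Imputation width (default 0.25).
#' @param width_mode `"sd_fraction"` (width times sample SD, default) or
#'   `"absolute"`.
#' @param log_transform Apply log2 after total normalization (default
#'   `TRUE`; set `FALSE` if the input is already log scale).
#' @return The normalized, filtered, imputed tibble; attribute
#'   `"excluded"` lists the dropped proteins.
#' @export
normalize_and_impute_lfq <- function(matrix, seed, max_missing = 4,
                                     shift = 1.8, width = 0.25,
                                     width_mode = c("sd_fraction", "absolute"),
                                     log_transform = TRUE) {
  width_mode <- match.arg(width_mode)
  matrix <- tibble::as_tibble(matrix)
  samples <- setdiff(names(matrix), "protein_id")
  vals <- as.matrix(matrix[samples])
  if (any(vals <= 0, na.rm = TRUE) && log_transform) {
    abort("intensities must be positive where present.")
  }
  if (any(colSums(!is.na(vals)) == 0)) abort("a sample has no observed values.")

  if (log_transform) {
    totals <- colSums(vals, na.rm = TRUE)
    vals <- log2(sweep(vals, 2, totals, "/"))
  }

  n_miss <- rowSums(is.na(vals))
  keep <- n_miss <= max_missing
  excluded <- matrix$protein_id[!keep]
  vals <- vals[keep, , drop = FALSE]

  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  for (j in seq_along(samples)) {
    col <- vals[, j]
    nas <- which(is.na(col))
    if (!length(nas)) next
    m <- mean(col, na.rm = TRUE)
    s <- sd(col, na.rm = TRUE)
    w <- if (width_mode == "sd_fraction") width * s else width
    vals[nas, j] <- rnorm(length(nas), m - shift * s, w)
  }
  out <- tibble::tibble(protein_id = matrix$protein_id[keep]) |>
    dplyr::bind_cols(tibble::as_tibble(vals))
  attr(out, "excluded") <- excluded
  out
}

#' Select enriched proteins from a pulldown contrast
#'
#' On a normalized, imputed log2 matrix: proteins whose mean log2 fold
#' change (group A minus group B) is at least `lfc_min` and whose
#' two-sided t-test p-value (pooled or Welch by F-test) is below `p_max`.
#'
#' @param matrix Tibble from [normalize_and_impute_lfq()].
#' @param group_a,group_b Character vectors of sample column names.
#' @param lfc_min Minimum log2 fold change (default 0.5).
#' @param p_max p-value threshold (default 0.05).
#' @param f_alpha F-test level for the variance-equality gate.
#' @return Tibble of enriched proteins: `protein_id`, `log2_fc`,
#'   `p_value`, `variance_mode`.
#' @export
select_enriched_pulldown <- function(matrix, group_a, group_b,
                                     lfc_min = 0.5, p_max = 0.05,
                                     f_alpha = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 samples.")
  }
  A <- as.matrix(matrix[group_a])
  B <- as.matrix(matrix[group_b])
  res <- row_ttest(A, B, f_alpha)
  tibble::tibble(
    protein_id = matrix$protein_id,
    log2_fc = res$delta,
    p_value = res$p,
    variance_mode = res$variance_mode
  ) |>
    dplyr::filter(.data$log2_fc >= lfc_min, .data$p_value < p_max)
}
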