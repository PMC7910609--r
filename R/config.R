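#' Default temperature gradient
#'
#' The ten-point heating gradient used throughout: 37, 41, 44, 47, 50, 53,
#' 56, 59, 63 and 67 degrees Celsius. The first (lowest) temperature is the
#' reference point at which the soluble fraction is defined to be 1.
#'
#' @return Numeric vector of temperatures in degrees Celsius.
#' @export
#' @examples
#' default_grid()
default_grid <- function() {
  c(37, 41, 44, 47, 50, 53, 56, 59, 63, 67)
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 4) {
    abort("`grid` must be a numeric vector of at least 4 temperatures (degrees C).")
  }
  if (any(diff(grid) <= 0)) {
    abort("`grid` temperatures must be strictly increasing.")
  }
  as.numeric(grid)
}

#' Build a screening configuration
#'
#' Collects every tunable threshold of the screen in one validated object.
#' Defaults follow the standard selection criteria of this screen design: fits are kept when
#' R2 > 0.7, replicate melting temperatures must agree to within an SD of
#' 2.5 degrees C, contrasts require p < 0.05 (primary) and p < 0.1
#' (secondary, substrates only), and the minimum absolute melting-point
#' shift is 1 degree C.
#'
#' @param grid Temperature gradient in degrees C (see [default_grid()]).
#' @param sample_map Optional tibble mapping quant-table columns to samples;
#'   see [sample_map()].
#' @param r2_min Minimum coefficient of determination of the sigmoid fit.
#' @param sd_max Maximum replicate standard deviation of Tm (degrees C).
#' @param p_primary Primary p-value threshold.
#' @param p_secondary Secondary (relaxed) p-value threshold; must be
#'   >= `p_primary`.
#' @param dtm_min Minimum absolute mean Tm shift in degrees C.
#' @param pl_max Fitted high-temperature plateau at or above which a protein
#'   is flagged as non-melting.
#' @param f_alpha Two-sided significance level of the variance-ratio F-test
#'   that switches between the pooled and Welch t-test.
#' @param min_peptides Minimum peptides per protein for quantification.
#' @param n_perm Default number of permutation rounds for FDR estimation.
#' @param norm_min_shared Minimum number of jointly detected, well-behaved
#'   proteins required for curve normalization.
#' @param norm_spearman_max Upper bound on the Spearman correlation between
#'   temperature and soluble fraction for a protein to enter the
#'   normalization set (melting curves decrease, so this is negative).
#' @param norm_top_fraction_max Maximum soluble fraction at the top
#'   temperature for normalization-set proteins.
#' @param slope_times_t If `TRUE` (default) the sigmoid exponent is
#'   (T - Tm) / (b * T); if `FALSE` the exponent is (T - Tm) / b.
#' @param require_sign_concordance Require the two substrate contrasts to
#'   shift in the same direction.
#' @param permute_qc If `TRUE` (default) the replicate-SD QC gate is
#'   re-evaluated inside each permutation round.
#' @param seed Optional integer seed recorded with the configuration.
#'
#' @return A `screen_config` list.
#' @export
#' @examples
#' cfg <- screen_config()
#' cfg$dtm_min
screen_config <- function(grid = default_grid(),
                          sample_map = NULL,
                          r2_min = 0.7,
                          sd_max = 2.5,
                          p_primary = 0.05,
                          p_secondary = 0.1,
                          dtm_min = 1.0,
                          pl_max = 0.5,
                          f_alpha = 0.05,
                          min_peptides = 2,
                          n_perm = 100,
                          norm_min_shared = 20,
                          norm_spearman_max = -0.8,
                          norm_top_fraction_max = 0.3,
                          slope_times_t = TRUE,
                          require_sign_concordance = TRUE,
                          permute_qc = TRUE,
                          seed = NULL) {
  grid <- check_grid(grid)
  num <- c(
    r2_min = r2_min, sd_max = sd_max, p_primary = p_primary,
    p_secondary = p_secondary, dtm_min = dtm_min, pl_max = pl_max,
    f_alpha = f_alpha
  )
  if (any(!is.finite(num)) || any(num <= 0)) {
    abort("All thresholds must be positive finite numbers.")
  }
  if (p_primary > p_secondary) {
    abort("`p_primary` must be <= `p_secondary`.")
  }
  if (!is.null(sample_map)) sample_map <- check_sample_map(sample_map, grid)
  structure(
    list(
      grid = grid, sample_map = sample_map,
      r2_min = r2_min, sd_max = sd_max,
      p_primary = p_primary, p_secondary = p_secondary,
      dtm_min = dtm_min, pl_max = pl_max, f_alpha = f_alpha,
      min_peptides = min_peptides, n_perm = n_perm,
      norm_min_shared = norm_min_shared,
      norm_spearman_max = norm_spearman_max,
      norm_top_fraction_max = norm_top_fraction_max,
      slope_times_t = slope_times_t,
      require_sign_concordance = require_sign_concordance,
      permute_qc = permute_qc,
      seed = seed
    ),
    class = "screen_config"
  )
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen_config>\n")
  cat("  grid:        ", paste(x$grid, collapse = ", "), " degC\n", sep = "")
  cat(sprintf(
    "  QC:          R2 > %g, replicate SD < %g degC, plateau < %g\n",
    x$r2_min, x$sd_max, x$pl_max
  ))
  cat(sprintf(
    "  selection:   p < %g (primary), p < %g (secondary), |dTm| > %g degC\n",
    x$p_primary, x$p_secondary, x$dtm_min
  ))
  cat(sprintf("  permutation: %d rounds\n", x$n_perm))
  if (!is.null(x$sample_map)) {
    cat(sprintf("  sample map:  %d columns\n", nrow(x$sample_map)))
  }
  invisible(x)
}

#' Describe how quant-table columns map to samples
#'
#' Each abundance column of a wide quantification table carries one
#' (treatment, replicate, temperature) combination. The map is engine
#' agnostic: any column naming works as long as every abundance column is
#' listed here.
#'
#' @param column Character vector of column names in the quant table.
#' @param treatment Treatment arm per column; one of `"vehicle"`,
#'   `"cosubstrate"`, `"enzyme"`, `"both"`.
#' @param replicate Positive integer replicate id per column.
#' @param temperature Temperature (degrees C) per column.
#'
#' @return A tibble with one row per abundance column.
#' @export
sample_map <- function(column, treatment, replicate, temperature) {
  out <- tibble::tibble(
    column = as.character(column),
    treatment = as.character(treatment),
    replicate = as.integer(replicate),
    temperature = as.numeric(temperature)
  )
  check_sample_map(out)
}

check_sample_map <- function(map, grid = NULL) {
  map <- tibble::as_tibble(map)
  need <- c("column", "treatment", "replicate", "temperature")
  miss <- setdiff(need, names(map))
  if (length(miss)) {
    abort(paste0("sample map lacks column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(map$treatment), TREATMENTS)
  if (length(bad)) {
    abort(paste0(
      "unknown treatment(s) in sample map: ", paste(bad, collapse = ", "),
      " (expected ", paste(TREATMENTS, collapse = "/"), ")"
    ))
  }
  if (anyDuplicated(map[c("treatment", "replicate", "temperature")])) {
    abort("sample map assigns the same (treatment, replicate, temperature) twice.")
  }
  if (!is.null(grid) && !all(map$temperature %in% grid)) {
    abort("sample map contains temperatures absent from the grid.")
  }
  map
}

#' Convenience sample map for reporter-style column names
#'
#' Builds a [sample_map()] for tables whose abundance columns follow the
#' common search-engine export pattern
#' `"<prefix> <channel index> <sample label>"`, with channels numbered from
#' 0 along the temperature gradient, e.g.
#' `"Reporter intensity corrected 0 vehicle_1"`.
#'
#' @param treatments Treatment arms present (default all four).
#' @param replicates Replicate ids per treatment.
#' @param grid Temperature gradient; channel i maps to `grid[i + 1]`.
#' @param prefix Column-name prefix.
#' @param sep Separator between treatment and replicate in the sample label.
#'
#' @return A [sample_map()] tibble.
#' @export
#' @examples
#' reporter_sample_map(replicates = 1:2)
reporter_sample_map <- function(treatments = TREATMENTS,
                                replicates = 1:2,
                                grid = default_grid(),
                                prefix = "Reporter intensity corrected",
                                sep = "_") {
  grid <- check_grid(grid)
  combos <- tidyr::expand_grid(
    treatment = treatments, replicate = as.integer(replicates),
    channel = seq_along(grid) - 1L
  )
  sample_map(
    column = paste0(
      prefix, " ", combos$channel, " ",
      combos$treatment, sep, combos$replicate
    ),
    treatment = combos$treatment,
    replicate = combos$replicate,
    temperature = grid[combos$channel + 1L]
  )
}

#' Load a screening configuration from a YAML file
#'
#' The file may set any argument of [screen_config()] under top-level keys,
#' plus an optional `sample_map` list of records with `column`, `treatment`,
#' `replicate` and `temperature` fields. Absent thresholds fall back to the
#' standard defaults (0.7, 2.5, 0.05, 0.1, 1.0).
#'
#' @param path Path to a YAML file.
#' @return A `screen_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) abort(paste0("malformed config file: ", conditionMessage(e)))
  )
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("malformed config file: top level must be a mapping.")
  known <- names(formals(screen_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$sample_map)) {
    raw$sample_map <- dplyr::bind_rows(lapply(raw$sample_map, tibble::as_tibble))
  }
  do.call(screen_config, raw)
}

#' Write a configuration to YAML
#'
#' @param config A `screen_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1))]
  if (!is.null(out$sample_map)) {
    out$sample_map <- purrr::transpose(as.list(out$sample_map))
  }
  yaml::write_yaml(out, path)
  invisible(path)
}
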