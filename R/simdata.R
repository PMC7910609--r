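#' Configure a synthetic four-arm thermal-profiling experiment
#'
#' Defaults describe a realistic lysate screen: 1000 proteins on the
#' ten-point 37-67 degrees C gradient, four treatment arms (vehicle,
#' cosubstrate, enzyme, both) in duplicate, baseline melting temperatures
#' around 50 degrees C, replicate Tm noise of 0.5 degrees C (matching the
#' replicate variation observed in real screens), mild multiplicative
#' reporter noise and per-temperature sample distortions (what curve
#' normalization removes). Planted effect classes act on the Tm parameter
#' only: binders shift in the cosubstrate and both arms, substrates only in
#' the both arm, interactors in the enzyme and both arms.
#'
#' @param n_proteins Number of proteins.
#' @param grid Temperature gradient (degrees C).
#' @param n_replicates Replicates per treatment arm.
#' @param tm_mean,tm_sd Baseline Tm distribution (degrees C).
#' @param b_mean,b_sd Slope-parameter distribution (truncated below at
#'   0.005).
#' @param pl_min,pl_max Uniform plateau range for melters.
#' @param frac_binder,frac_substrate,frac_interactor Planted class
#'   fractions (the remainder is null).
#' @param frac_non_melter Fraction of proteins given a high plateau
#'   (0.55-0.75) and no measurable transition.
#' @param dtm_mean,dtm_sd Planted |dTm| distribution (degrees C).
#' @param prop_destabilized Probability that a planted shift is negative;
#'   0.5 is symmetric, larger values mimic reductive (destabilizing)
#'   systems.
#' @param tm_noise_sd Replicate-level Tm noise SD (degrees C).
#' @param abundance_sdlog Log-normal multiplicative reporter noise (sdlog).
#' @param distortion_sdlog Log-normal per-sample, per-temperature
#'   distortion applied above the reference temperature (sdlog).
#' @param missing_rate Probability that a protein is entirely missing from
#'   one replicate sample.
#' @param ref_meanlog,ref_sdlog Log-normal reference-intensity
#'   distribution.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 1000,
                       grid = default_grid(),
                       n_replicates = 2,
                       tm_mean = 50, tm_sd = 4,
                       b_mean = 0.03, b_sd = 0.005,
                       pl_min = 0, pl_max = 0.15,
                       frac_binder = 0.03,
                       frac_substrate = 0.05,
                       frac_interactor = 0.03,
                       frac_non_melter = 0.01,
                       dtm_mean = 2.5, dtm_sd = 0.5,
                       prop_destabilized = 0.5,
                       tm_noise_sd = 0.5,
                       abundance_sdlog = 0.05,
                       distortion_sdlog = 0.05,
                       missing_rate = 0,
                       ref_meanlog = log(1e7), ref_sdlog = 1,
                       seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory for reproducibility.")
  fr <- c(frac_binder, frac_substrate, frac_interactor, frac_non_melter)
  if (any(fr < 0) || sum(fr) > 1) abort("class fractions must be >= 0 and sum to <= 1.")
  sds <- c(tm_sd, b_sd, dtm_sd, tm_noise_sd, abundance_sdlog, distortion_sdlog)
  if (any(sds < 0)) abort("all SDs must be >= 0.")
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1).")
  structure(
    list(
      n_proteins = n_proteins, grid = check_grid(grid),
      n_replicates = as.integer(n_replicates),
      tm_mean = tm_mean, tm_sd = tm_sd, b_mean = b_mean, b_sd = b_sd,
      pl_min = pl_min, pl_max = pl_max,
      frac_binder = frac_binder, frac_substrate = frac_substrate,
      frac_interactor = frac_interactor, frac_non_melter = frac_non_melter,
      dtm_mean = dtm_mean, dtm_sd = dtm_sd,
      prop_destabilized = prop_destabilized,
      tm_noise_sd = tm_noise_sd, abundance_sdlog = abundance_sdlog,
      distortion_sdlog = distortion_sdlog, missing_rate = missing_rate,
      ref_meanlog = ref_meanlog, ref_sdlog = ref_sdlog,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

## which treatment arms a planted class shifts in
CLASS_ARMS <- list(
  cosubstrate_binder = c("cosubstrate", "both"),
  substrate = "both",
  enzyme_interactor = c("enzyme", "both"),
  null = character(),
  non_melter = character()
)

#' Simulate a complete four-arm experiment with planted ground truth
#'
#' For every protein and sample the true sigmoid is evaluated on the grid
#' with a replicate-specific Tm (true treatment Tm plus noise), scaled to a
#' random reference intensity, multiplied by log-normal reporter noise and
#' the sample's per-temperature distortion, and optionally blanked by
#' missingness. Identical seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return A list:
#'   \describe{
#'     \item{wide}{wide quant tibble in the TSV dialect the reader accepts
#'       (`protein_id`, `peptide_count`, `contaminant`, one column per
#'       sample channel);}
#'     \item{screen_config}{a [screen_config()] whose sample map matches
#'       `wide`;}
#'     \item{quant}{the canonical long table
#'       (`quant_from_wide(wide, screen_config)`);}
#'     \item{truth}{per-protein class, true parameters and planted shift.}
#'   }
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(.restore_seed(old), add = TRUE)

  n <- config$n_proteins
  grid <- config$grid
  reps <- seq_len(config$n_replicates)

  classes <- c(
    "cosubstrate_binder", "substrate", "enzyme_interactor",
    "non_melter", "null"
  )
  counts <- c(
    round(n * config$frac_binder), round(n * config$frac_substrate),
    round(n * config$frac_interactor), round(n * config$frac_non_melter)
  )
  counts <- c(counts, n - sum(counts))
  class_vec <- sample(rep(classes, counts))

  truth <- tibble::tibble(
    protein_id = sprintf("SIM%04d", seq_len(n)),
    class = class_vec,
    tm_base = rnorm(n, config$tm_mean, config$tm_sd),
    b = pmax(rnorm(n, config$b_mean, config$b_sd), 0.005),
    pl = runif(n, config$pl_min, config$pl_max),
    dtm = ifelse(
      class_vec %in% c("null", "non_melter"), 0,
      pmax(rnorm(n, config$dtm_mean, config$dtm_sd), 0.1) *
        ifelse(runif(n) < config$prop_destabilized, -1, 1)
    )
  )
  truth$pl[truth$class == "non_melter"] <- runif(sum(truth$class == "non_melter"), 0.55, 0.75)
  for (tr in TREATMENTS) {
    shift <- ifelse(
      purrr::map_lgl(truth$class, ~ tr %in% CLASS_ARMS[[.x]]),
      truth$dtm, 0
    )
    truth[[paste0("tm_", tr)]] <- truth$tm_base + shift
  }

  ## per-sample, per-temperature distortions (1 at the reference point)
  samples <- tidyr::expand_grid(treatment = TREATMENTS, replicate = reps)
  distort <- tidyr::expand_grid(samples, temperature = grid) |>
    dplyr::mutate(
      distortion = dplyr::if_else(
        .data$temperature == grid[1], 1,
        rlnorm(dplyr::n(), 0, config$distortion_sdlog)
      )
    )

  per_sample <- tidyr::expand_grid(
    protein_id = truth$protein_id, samples
  ) |>
    dplyr::left_join(
      tidyr::pivot_longer(
        truth[c("protein_id", paste0("tm_", TREATMENTS))],
        -"protein_id",
        names_to = "treatment", names_prefix = "tm_", values_to = "tm_true"
      ),
      by = c("protein_id", "treatment")
    ) |>
    dplyr::mutate(
      tm_sample = .data$tm_true + rnorm(dplyr::n(), 0, config$tm_noise_sd),
      ref_intensity = rlnorm(dplyr::n(), config$ref_meanlog, config$ref_sdlog),
      missing = runif(dplyr::n()) < config$missing_rate
    )

  long <- tidyr::expand_grid(per_sample, temperature = grid) |>
    dplyr::left_join(truth[c("protein_id", "b", "pl")], by = "protein_id") |>
    dplyr::left_join(distort, by = c("treatment", "replicate", "temperature")) |>
    dplyr::mutate(
      abundance = .data$ref_intensity *
        melt_sigmoid(.data$temperature, .data$tm_sample, .data$b, .data$pl) *
        rlnorm(dplyr::n(), 0, config$abundance_sdlog) *
        .data$distortion,
      abundance = dplyr::if_else(.data$missing, NA_real_, .data$abundance),
      column = paste0(.data$treatment, "_", .data$replicate, "_T", .data$temperature)
    )

  map <- sample_map(
    column = paste0(
      rep(samples$treatment, each = length(grid)), "_",
      rep(samples$replicate, each = length(grid)), "_T",
      rep(grid, times = nrow(samples))
    ),
    treatment = rep(samples$treatment, each = length(grid)),
    replicate = rep(samples$replicate, each = length(grid)),
    temperature = rep(grid, times = nrow(samples))
  )
  wide <- long |>
    dplyr::select("protein_id", "column", "abundance") |>
    tidyr::pivot_wider(names_from = "column", values_from = "abundance") |>
    dplyr::mutate(peptide_count = 2L + stats::rpois(n, 8), contaminant = FALSE, .after = 1)

  scfg <- screen_config(grid = grid, sample_map = map, seed = config$seed)
  list(
    wide = wide,
    screen_config = scfg,
    quant = quant_from_wide(wide, scfg),
    truth = truth,
    config = config
  )
}

#' Write a simulated experiment to disk
#'
#' Writes the wide quant table (`quant.tsv`), the ground truth
#' (`truth.tsv`) and a YAML screen configuration with the matching sample
#' map (`config.yml`) into `dir`, i.e. exactly the artifact set the reader
#' side consumes.
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sim$wide, file.path(dir, "quant.tsv"), na = "", progress = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  write_config(sim$screen_config, file.path(dir, "config.yml"))
  invisible(dir)
}

#' Score a candidate list against the planted truth
#'
#' @param candidates Tibble from [select_candidates()].
#' @param truth Truth tibble from [simulate_experiment()].
#' @param mode Candidate class being evaluated (defaults to the class of
#'   the records).
#' @return One-row tibble: planted and selected counts, true/false
#'   positives, `sensitivity` and empirical `fdr`.
#' @export
evaluate_against_truth <- function(candidates, truth, mode = NULL) {
  mode <- mode %||% unique(candidates$class)
  if (length(mode) != 1) abort("candidates must carry exactly one class.")
  if (!all(candidates$protein_id %in% truth$protein_id)) {
    abort("candidate proteins absent from the truth table (mismatched simulation?).")
  }
  positives <- truth$protein_id[truth$class == mode]
  sel <- candidates$protein_id
  tp <- length(intersect(sel, positives))
  fp <- length(sel) - tp
  tibble::tibble(
    class = mode,
    n_planted = length(positives),
    n_selected = length(sel),
    true_positives = tp,
    false_positives = fp,
    sensitivity = if (length(positives) > 0) tp / length(positives) else NA_real_,
    fdr = if (length(sel) > 0) fp / length(sel) else NA_real_
  )
}
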