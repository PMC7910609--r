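#' Run the full screening pipeline
#'
#' Executes every stage in order: fold-change scaling, bulk-proteome curve
#' normalization, sigmoid fitting, QC, treatment contrasts, candidate
#' selection in all three modes, permutation FDR, OPLS-DA fitting and VIP
#' ranking of the substrate candidates. Input is either a quant table
#' (long tibble from [read_protein_quant()]) or a [sim_config()] to
#' simulate one. All randomness (permutations, simulation) derives from
#' `seed`.
#'
#' @param config A [screen_config()].
#' @param quant Long quant tibble; mutually exclusive with `sim`.
#' @param sim A [sim_config()]; the experiment is simulated first.
#' @param out_dir Optional directory: all stage TSVs plus a YAML run
#'   manifest are written there.
#' @param seed Integer seed.
#' @param n_perm Permutation rounds for the FDR stage.
#' @param normalize Apply curve normalization (default `TRUE`).
#' @param n_ortho Orthogonal components of the OPLS-DA stage.
#' @param input_path Optional path of the quant file, recorded (with its
#'   MD5 digest) in the manifest.
#' @return A `screen_run` list: `curves`, `normalization`, `fits`,
#'   `tm_table`, `replicate_variation`, `contrasts`, `candidates` (one
#'   tibble per mode), `fdr` (one `permutation_fdr` per mode), `opls`,
#'   `ranked` (substrate candidates with VIP ranks), `shift_summary`,
#'   `truth` (when simulated) and `manifest`.
#' @export
run_pipeline <- function(config = screen_config(), quant = NULL, sim = NULL,
                         out_dir = NULL, seed = 1L, n_perm = config$n_perm,
                         normalize = TRUE, n_ortho = 1, input_path = NULL) {
  stopifnot(inherits(config, "screen_config"))
  if (is.null(quant) == is.null(sim)) {
    abort("provide exactly one of `quant` or `sim`.")
  }
  truth <- NULL
  if (!is.null(sim)) {
    sim_res <- simulate_experiment(sim)
    quant <- sim_res$quant
    truth <- sim_res$truth
    config$grid <- sim_res$screen_config$grid
    config$sample_map <- sim_res$screen_config$sample_map
  }

  curves <- scale_fold_changes(quant)
  normalization <- NULL
  if (normalize) {
    norm <- normalize_to_reference(curves, config)
    curves <- norm$curves
    normalization <- norm$normalization
  }
  fits <- fit_melting_curves(curves, config)
  tm_table <- qc_fits(fits, config)
  rep_var <- replicate_variation_summary(tm_table)

  contrasts <- dplyr::bind_rows(
    compare_groups(tm_table, "cosubstrate", "vehicle", config),
    compare_groups(tm_table, "enzyme", "vehicle", config),
    compare_groups(tm_table, "both", "enzyme", config),
    compare_groups(tm_table, "both", "cosubstrate", config)
  )

  modes <- names(MODE_CONTRASTS)
  candidates <- purrr::map(
    rlang::set_names(modes),
    ~ select_candidates(tm_table, config, .x)
  )
  fdr <- purrr::map(
    rlang::set_names(modes),
    ~ estimate_fdr_permutation(tm_table, config, .x, n_perm = n_perm, seed = seed)
  )

  opls <- tryCatch(
    fit_oplsda(tm_table,
      class_a = "both", class_b = c("enzyme", "cosubstrate"),
      n_ortho = n_ortho
    ),
    error = function(e) {
      warn(paste0("OPLS-DA stage skipped: ", conditionMessage(e)))
      NULL
    }
  )
  ranked <- if (!is.null(opls)) {
    rank_candidates(candidates$substrate, opls)
  } else {
    candidates$substrate |> dplyr::mutate(vip = NA_real_, in_model = FALSE)
  }
  shift_summary <- summarize_shifts(candidates$substrate)

  manifest <- list(
    tool = paste0("meltscreen ", as.character(utils::packageVersion("meltscreen"))),
    seed = as.integer(seed),
    n_perm = as.integer(n_perm),
    input = if (!is.null(input_path)) {
      list(path = input_path, md5 = unname(tools::md5sum(input_path)))
    } else if (!is.null(sim)) {
      list(simulated = TRUE, sim_seed = sim$seed)
    } else {
      list(in_memory = TRUE)
    },
    thresholds = config[c(
      "r2_min", "sd_max", "p_primary", "p_secondary", "dtm_min", "pl_max"
    )],
    stage_counts = list(
      proteins_in = dplyr::n_distinct(quant$protein_id),
      curves = dplyr::n_distinct(paste(curves$protein_id, curves$treatment, curves$replicate)),
      fits_converged = sum(fits$converged),
      tm_values = sum(!is.na(tm_table$tm)),
      contrasts_tested = sum(!is.na(contrasts$p_value)),
      candidates = purrr::map_int(candidates, nrow)
    )
  )

  run <- structure(
    list(
      curves = curves, normalization = normalization, fits = fits,
      tm_table = tm_table, replicate_variation = rep_var,
      contrasts = contrasts, candidates = candidates, fdr = fdr,
      opls = opls, ranked = ranked, shift_summary = shift_summary,
      truth = truth, manifest = manifest, config = config
    ),
    class = "screen_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.screen_run <- function(x, ...) {
  cat("<screen_run>\n")
  sc <- x$manifest$stage_counts
  cat(sprintf(
    "  %d proteins in, %d converged fits, %d Tm values\n",
    sc$proteins_in, sc$fits_converged, sc$tm_values
  ))
  for (m in names(x$candidates)) {
    fdr <- x$fdr[[m]]$fdr
    cat(sprintf(
      "  %-18s %3d candidates (permutation FDR %s)\n", m,
      nrow(x$candidates[[m]]),
      if (is.na(fdr)) "NA" else sprintf("%.1f%%", 100 * fdr)
    ))
  }
  invisible(x)
}

#' Write a pipeline run to a results directory
#'
#' Emits every stage table as TSV (`fits.tsv`, `tm_table.tsv`,
#' `contrasts.tsv`, `candidates_<mode>.tsv`, `ranked_substrates.tsv`,
#' `fdr.tsv`, `replicate_variation.tsv`, optional `normalization.tsv` and
#' `vip.tsv`) plus the YAML `manifest.yml`.
#'
#' @param run A `screen_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, name) write_results(tbl, file.path(dir, name))
  w(run$fits, "fits.tsv")
  w(run$tm_table, "tm_table.tsv")
  w(run$contrasts, "contrasts.tsv")
  w(run$replicate_variation, "replicate_variation.tsv")
  for (m in names(run$candidates)) w(run$candidates[[m]], paste0("candidates_", m, ".tsv"))
  w(run$ranked, "ranked_substrates.tsv")
  fdr_tbl <- purrr::map_dfr(run$fdr, function(f) {
    tibble::tibble(
      mode = f$mode, observed_hits = f$observed_hits,
      mean_permuted_hits = f$mean_permuted_hits, fdr = f$fdr,
      n_permutations = f$n_permutations, seed = f$seed
    )
  })
  w(fdr_tbl, "fdr.tsv")
  if (!is.null(run$normalization)) w(run$normalization, "normalization.tsv")
  if (!is.null(run$opls)) w(tidy(run$opls), "vip.tsv")
  if (!is.null(run$truth)) w(run$truth, "truth.tsv")
  yaml::write_yaml(run$manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}
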