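#' Plot fitted melting curves for selected proteins
#'
#' Observed relative-solubility points and the fitted sigmoid per
#' treatment, faceted by protein — the standard per-candidate diagnostic.
#'
#' @param curves Curve tibble from [scale_fold_changes()] (optionally
#'   normalized).
#' @param fits Fit tibble from [fit_melting_curves()].
#' @param proteins Character vector of protein ids to show.
#' @param config A [screen_config()] (grid and exponent convention).
#' @return A ggplot object.
#' @export
plot_melt_curves <- function(curves, fits, proteins, config = screen_config()) {
  obs <- curves |> dplyr::filter(.data$protein_id %in% proteins)
  ft <- fits |>
    dplyr::filter(.data$protein_id %in% proteins, .data$converged)
  t_seq <- seq(min(config$grid), max(config$grid), length.out = 100)
  lines <- ft |>
    dplyr::mutate(data = purrr::pmap(
      list(.data$tm, .data$b, .data$pl),
      function(tm, b, pl) {
        tibble::tibble(
          temperature = t_seq,
          fraction = melt_sigmoid(t_seq, tm, b, pl, config$slope_times_t)
        )
      }
    )) |>
    dplyr::select("protein_id", "treatment", "replicate", "data") |>
    tidyr::unnest("data")
  ggplot2::ggplot(obs, ggplot2::aes(
    x = .data$temperature, y = .data$fraction,
    color = .data$treatment, group = interaction(.data$treatment, .data$replicate)
  )) +
    ggplot2::geom_point(size = 1.5, alpha = 0.8) +
    ggplot2::geom_line(data = lines, linewidth = 0.4) +
    ggplot2::facet_wrap(~protein_id) +
    ggplot2::labs(
      x = "temperature (°C)", y = "relative solubility", color = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Specificity scatterplot of Tm shifts
#'
#' Plots each protein's shift in the combination arm against the two
#' single-treatment arms (both-enzyme on x, both-cosubstrate on y);
#' substrates — proteins shifting only upon simultaneous addition — fall
#' along the diagonal, outside the +/- `dtm_min` band. Selected candidates
#' are colored.
#'
#' @param candidates Full candidate tibble
#'   (`select_candidates(..., mode = "substrate", keep_all = TRUE)`).
#' @param config A [screen_config()] (for the cutoff band).
#' @return A ggplot object.
#' @export
plot_shift_scatter <- function(candidates, config = screen_config()) {
  need <- c("delta_tm_both_vs_enzyme", "delta_tm_both_vs_cosubstrate")
  if (!all(need %in% names(candidates))) {
    abort("expected substrate-mode candidate records (keep_all = TRUE).")
  }
  ggplot2::ggplot(candidates, ggplot2::aes(
    x = .data$delta_tm_both_vs_enzyme,
    y = .data$delta_tm_both_vs_cosubstrate,
    color = .data$selected
  )) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * config$dtm_min, linetype = 2, color = "grey60") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * config$dtm_min, linetype = 2, color = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::scale_color_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "forestgreen"),
      labels = c(`FALSE` = "other", `TRUE` = "candidate"), name = NULL
    ) +
    ggplot2::labs(
      x = expression(Delta * T[m] ~ "(both - enzyme, °C)"),
      y = expression(Delta * T[m] ~ "(both - cosubstrate, °C)")
    ) +
    ggplot2::theme_minimal()
}
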