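#' Sigmoid melting model
#'
#' Relative soluble fraction as a function of temperature:
#' \deqn{I(T) = \frac{1 - Pl}{1 + \exp((T - T_m)/(b\,T))} + Pl}
#' where `Pl` is the high-temperature plateau, `tm` the melting temperature
#' (the curve passes through `(1 + Pl)/2` at `T = tm`) and `b > 0` the slope
#' parameter. With `slope_times_t = FALSE` the exponent is `(T - tm)/b`
#' instead, i.e. `b` is an absolute width in degrees C.
#'
#' @param temperature Temperatures in degrees C (> 0).
#' @param tm Melting temperature in degrees C.
#' @param b Slope parameter.
#' @param pl High-temperature plateau in `[0, 1)`.
#' @param slope_times_t Whether the slope multiplies T in the exponent.
#' @return Soluble fraction at each temperature.
#' @export
#' @examples
#' melt_sigmoid(50, tm = 50, b = 0.03, pl = 0.1) # (1 + 0.1) / 2
melt_sigmoid <- function(temperature, tm, b, pl, slope_times_t = TRUE) {
  denom <- if (slope_times_t) b * temperature else b
  (1 - pl) / (1 + exp((temperature - tm) / denom)) + pl
}

#' Scale abundances to fold changes over the reference temperature
#'
#' Converts reporter abundances to relative solubility: for every protein
#' and sample, `fraction(T) = abundance(T) / abundance(T_ref)` with `T_ref`
#' the lowest grid temperature. Protein/samples whose reference abundance is
#' missing or zero are excluded with reason `"no_reference"` rather than
#' raising an error; rows already flagged by the reader stay excluded.
#'
#' @param quant Long quant tibble from [read_protein_quant()].
#' @return Tibble `protein_id`, `treatment`, `replicate`, `temperature`,
#'   `fraction`, `excluded`, `exclude_reason`.
#' @export
scale_fold_changes <- function(quant) {
  quant |>
    dplyr::group_by(.data$protein_id, .data$treatment, .data$replicate) |>
    dplyr::mutate(
      .ref = .data$abundance[which.min(.data$temperature)],
      .bad = is.na(.data$.ref) | .data$.ref <= 0,
      fraction = dplyr::if_else(.data$.bad, NA_real_, .data$abundance / .data$.ref),
      excluded = .data$excluded | .data$.bad,
      exclude_reason = dplyr::if_else(
        is.na(.data$exclude_reason) & .data$.bad, "no_reference", .data$exclude_reason
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "protein_id", "treatment", "replicate", "temperature",
      "fraction", "excluded", "exclude_reason"
    )
}

## sample id helper: "treatment.replicate"
sample_id <- function(treatment, replicate) paste(treatment, replicate, sep = ".")

#' Normalize melting curves to the bulk proteome
#'
#' Removes sample-wide, per-temperature distortions (labeling efficiency,
#' loading differences) by forcing the median melting behavior of each
#' sample onto a common fitted median curve. The normalization set contains
#' proteins detected in every sample whose raw curves look like genuine
#' melters: Spearman correlation between temperature and fraction at most
#' `config$norm_spearman_max` and soluble fraction at the top temperature
#' below `config$norm_top_fraction_max`. Per sample, the median fraction of
#' that set is computed at each temperature; the across-sample median of
#' these curves is fitted with the sigmoid model, and each sample's
#' correction factor at temperature T is `fitted(T) / sample_median(T)`.
#' Factors are applied multiplicatively at every temperature above the
#' reference; the reference temperature is untouched (factor 1).
#'
#' @param curves Fold-change tibble from [scale_fold_changes()].
#' @param config A [screen_config()].
#' @return A list with `curves` (normalized tibble, same shape as input)
#'   and `normalization` (tibble of per-sample, per-temperature factors plus
#'   attributes `n_proteins` for the normalization-set size and
#'   `median_fit`, the fitted reference curve parameters).
#' @export
normalize_to_reference <- function(curves, config) {
  grid <- config$grid
  t_ref <- grid[1]
  ok <- curves |>
    dplyr::filter(!.data$excluded) |>
    dplyr::mutate(sample = sample_id(.data$treatment, .data$replicate))
  n_samples <- dplyr::n_distinct(ok$sample)

  stats_tbl <- ok |>
    dplyr::group_by(.data$protein_id, .data$sample) |>
    dplyr::summarise(
      complete = sum(!is.na(.data$fraction)) == length(grid),
      rho = if (sum(!is.na(.data$fraction)) >= 3) {
        suppressWarnings(cor(.data$temperature, .data$fraction,
          method = "spearman", use = "complete.obs"
        ))
      } else NA_real_,
      top = .data$fraction[which.max(.data$temperature)],
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      in_all = dplyr::n() == n_samples && all(.data$complete),
      well_behaved = all(!is.na(.data$rho) & .data$rho <= config$norm_spearman_max) &&
        all(!is.na(.data$top) & .data$top < config$norm_top_fraction_max),
      .groups = "drop"
    )
  norm_set <- stats_tbl$protein_id[stats_tbl$in_all & stats_tbl$well_behaved]
  if (length(norm_set) < config$norm_min_shared) {
    abort(paste0(
      "only ", length(norm_set), " shared well-behaved proteins (need >= ",
      config$norm_min_shared, "); consider skipping normalization."
    ))
  }

  sample_medians <- ok |>
    dplyr::filter(.data$protein_id %in% norm_set) |>
    dplyr::group_by(.data$sample, .data$treatment, .data$replicate, .data$temperature) |>
    dplyr::summarise(med = median(.data$fraction, na.rm = TRUE), .groups = "drop")
  grand <- sample_medians |>
    dplyr::group_by(.data$temperature) |>
    dplyr::summarise(med = median(.data$med), .groups = "drop")
  fit <- fit_melting_curve(grand$temperature, grand$med, config)
  fitted_ref <- melt_sigmoid(
    grid, fit$tm, fit$b, fit$pl,
    slope_times_t = config$slope_times_t
  )
  if (!fit$converged) {
    warn("median-curve fit did not converge; using the raw grand median as reference.")
    fitted_ref <- grand$med[match(grid, grand$temperature)]
  }

  factors <- sample_medians |>
    dplyr::mutate(
      factor = dplyr::if_else(
        .data$temperature == t_ref, 1,
        fitted_ref[match(.data$temperature, grid)] / .data$med
      )
    ) |>
    dplyr::select("sample", "treatment", "replicate", "temperature", "factor")
  if (any(!is.finite(factors$factor) | factors$factor <= 0)) {
    abort("non-positive normalization factor; sample median curve degenerate.")
  }

  out <- curves |>
    dplyr::left_join(
      factors |> dplyr::select(-"sample"),
      by = c("treatment", "replicate", "temperature")
    ) |>
    dplyr::mutate(
      fraction = .data$fraction * dplyr::coalesce(.data$factor, 1)
    ) |>
    dplyr::select(-"factor")
  attr(factors, "n_proteins") <- length(norm_set)
  attr(factors, "median_fit") <- fit
  list(curves = out, normalization = factors)
}

#' Fit the sigmoid melting model to one curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) with a
#' deterministic multi-start on Tm (grid minimum, median and maximum, plus
#' the observed temperature closest to the half-transition, which rescues
#' very steep curves); ties are broken by lowest SSE, then lowest Tm. Bounds: Tm
#' inside the grid range extended by 10 degrees C on both sides, `b` in
#' `[1e-4, 10]`, `Pl` in `[0, 0.999]`. Failure to converge is reported in
#' the `converged` flag, never as an error.
#'
#' @param temperature Temperatures (degrees C).
#' @param fraction Observed relative solubility.
#' @param config A [screen_config()] (uses the grid and exponent flag).
#' @return One-row tibble: `tm`, `b`, `pl`, `r2`, `sse`, `converged`,
#'   `n_points`, `reason`.
#' @export
fit_melting_curve <- function(temperature, fraction, config = screen_config()) {
  ok <- is.finite(temperature) & is.finite(fraction)
  x <- temperature[ok]
  y <- fraction[ok]
  n <- length(x)
  if (n < 4) {
    return(tibble::tibble(
      tm = NA_real_, b = NA_real_, pl = NA_real_, r2 = NA_real_,
      sse = NA_real_, converged = FALSE, n_points = n, reason = "too_few_points"
    ))
  }
  grid <- config$grid
  lower <- c(tm = min(grid) - 10, b = 1e-4, pl = 0)
  upper <- c(tm = max(grid) + 10, b = 10, pl = 0.999)
  stt <- config$slope_times_t

  tm_half <- x[which.min(abs(y - (max(y) + min(y)) / 2))]
  best <- NULL
  for (tm0 in unique(c(min(grid), tm_half, median(grid), max(grid)))) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ melt_sigmoid(x, tm, b, pl, slope_times_t = stt),
        start = list(tm = tm0, b = if (stt) 0.05 else 2, pl = 0.05),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(residuals(fit)^2)
    cf <- coef(fit)
    if (is.null(best) || sse < best$sse - 1e-12 ||
      (abs(sse - best$sse) <= 1e-12 && cf[["tm"]] < best$tm)) {
      best <- list(tm = cf[["tm"]], b = cf[["b"]], pl = cf[["pl"]], sse = sse)
    }
  }
  if (is.null(best)) {
    return(tibble::tibble(
      tm = NA_real_, b = NA_real_, pl = NA_real_, r2 = NA_real_,
      sse = NA_real_, converged = FALSE, n_points = n, reason = "fit_failed"
    ))
  }
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - best$sse / sst else NA_real_
  tibble::tibble(
    tm = best$tm, b = best$b, pl = best$pl, r2 = r2, sse = best$sse,
    converged = TRUE, n_points = n, reason = NA_character_
  )
}

#' Fit melting curves for every protein and sample
#'
#' Applies [fit_melting_curve()] across a curve tibble; curves with fewer
#' than `min_points` non-missing fractions are skipped with reason
#' `"too_few_points"`, and excluded protein/samples with their exclusion
#' reason.
#'
#' @param curves Tibble from [scale_fold_changes()] (optionally normalized).
#' @param config A [screen_config()].
#' @param min_points Minimum usable points per curve.
#' @return Tibble with one row per protein and sample: the fit parameters
#'   plus `protein_id`, `treatment`, `replicate`.
#' @export
fit_melting_curves <- function(curves, config = screen_config(), min_points = 5) {
  nested <- curves |>
    dplyr::group_by(.data$protein_id, .data$treatment, .data$replicate) |>
    dplyr::summarise(
      .excl = any(.data$excluded),
      .reason = dplyr::first(.data$exclude_reason[!is.na(.data$exclude_reason)], default = NA_character_),
      .n = sum(is.finite(.data$fraction)),
      data = list(tibble::tibble(t = temperature, f = fraction)),
      .groups = "drop"
    )
  fits <- purrr::pmap(
    list(nested$data, nested$.excl, nested$.reason, nested$.n),
    function(d, excl, reason, n) {
      if (excl) {
        tibble::tibble(
          tm = NA_real_, b = NA_real_, pl = NA_real_, r2 = NA_real_,
          sse = NA_real_, converged = FALSE, n_points = n,
          reason = reason %||% "excluded"
        )
      } else if (n < min_points) {
        tibble::tibble(
          tm = NA_real_, b = NA_real_, pl = NA_real_, r2 = NA_real_,
          sse = NA_real_, converged = FALSE, n_points = n,
          reason = "too_few_points"
        )
      } else {
        fit_melting_curve(d$t, d$f, config)
      }
    }
  )
  dplyr::bind_cols(
    nested |> dplyr::select("protein_id", "treatment", "replicate"),
    dplyr::bind_rows(fits)
  )
}

#' Annotate fits with quality-control flags and build the Tm table
#'
#' Applies the two standard gates — fit quality (R2 above `config$r2_min`)
#' and replicate consistency (per-treatment SD of Tm below `config$sd_max`
#' degrees C) — and flags non-melting proteins: samples whose fit failed or
#' whose fitted plateau is at or above `config$pl_max` (proteins that stay
#' largely soluble at the top temperature have no measurable Tm).
#'
#' @param fits Tibble from [fit_melting_curves()].
#' @param config A [screen_config()].
#' @return A `tm_table` tibble: one row per protein and sample with `tm`,
#'   `r2`, `converged`, `no_melting`, `fit_ok` (per-sample R2 gate) and the
#'   per-treatment replicate SD `rep_sd` with its gate `rep_sd_ok`.
#' @export
qc_fits <- function(fits, config = screen_config()) {
  fits |>
    dplyr::mutate(
      no_melting = !.data$converged | (.data$converged & .data$pl >= config$pl_max),
      fit_ok = .data$converged & !.data$no_melting & .data$r2 > config$r2_min,
      tm = dplyr::if_else(.data$no_melting, NA_real_, .data$tm)
    ) |>
    dplyr::group_by(.data$protein_id, .data$treatment) |>
    dplyr::mutate(
      rep_sd = if (sum(!is.na(.data$tm)) >= 2) sd(.data$tm, na.rm = TRUE) else NA_real_,
      rep_sd_ok = !is.na(.data$rep_sd) & .data$rep_sd < config$sd_max
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "protein_id", "treatment", "replicate", "tm", "b", "pl", "r2",
      "converged", "no_melting", "fit_ok", "rep_sd", "rep_sd_ok"
    )
}
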