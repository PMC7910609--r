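mini_quant <- function(abund, grid = c(37, 44, 50), id = "P1",
                       treatment = "vehicle", replicate = 1L) {
  tibble::tibble(
    protein_id = id, treatment = treatment, replicate = replicate,
    temperature = grid, abundance = abund,
    peptide_count = 5L, contaminant = FALSE,
    excluded = FALSE, exclude_reason = NA_character_
  )
}

test_that("fold-change scaling divides by the reference-temperature abundance", {
  out <- scale_fold_changes(mini_quant(c(200, 200, 200)))
  expect_equal(out$fraction, c(1, 1, 1))
  out2 <- scale_fold_changes(mini_quant(c(100, 50, 25)))
  expect_equal(out2$fraction, c(1, 0.5, 0.25))
})

test_that("zero or missing reference abundance excludes that protein/sample only", {
  q <- dplyr::bind_rows(
    mini_quant(c(0, 50, 25), id = "PZ"),
    mini_quant(c(100, 50, 25), id = "POK")
  )
  out <- scale_fold_changes(q)
  pz <- dplyr::filter(out, protein_id == "PZ")
  expect_true(all(pz$excluded))
  expect_equal(unique(pz$exclude_reason), "no_reference")
  expect_true(all(is.na(pz$fraction)))
  pok <- dplyr::filter(out, protein_id == "POK")
  expect_false(any(pok$excluded))
  expect_equal(pok$fraction, c(1, 0.5, 0.25))
})

test_that("the sigmoid passes through (1+Pl)/2 at Tm and approaches 1 at low T", {
  expect_equal(melt_sigmoid(52, tm = 52, b = 0.04, pl = 0.2), (1 + 0.2) / 2)
  expect_equal(melt_sigmoid(0.001, tm = 50, b = 0.03, pl = 0.1), 1, tolerance = 1e-6)
})

test_that("exact-model curves are refit essentially perfectly (property over draws)", {
  cfg <- screen_config()
  set.seed(101)
  for (i in 1:25) {
    tm <- runif(1, 42, 62)
    b <- runif(1, 0.015, 0.08)
    pl <- runif(1, 0.02, 0.3)
    y <- melt_sigmoid(cfg$grid, tm, b, pl)
    fit <- fit_melting_curve(cfg$grid, y, cfg)
    expect_true(fit$converged)
    expect_lt(abs(fit$tm - tm) / tm, 1e-4)
    expect_lt(abs(fit$b - b) / b, 1e-4)
    expect_lt(abs(fit$pl - pl) / pl, 1e-4)
    expect_gte(fit$r2, 0.999)
  }
})

test_that("fitting is deterministic and skips short curves with a reason", {
  cfg <- screen_config()
  set.seed(5)
  y <- melt_sigmoid(cfg$grid, 51, 0.04, 0.1) + rnorm(10, 0, 0.03)
  f1 <- fit_melting_curve(cfg$grid, y, cfg)
  f2 <- fit_melting_curve(cfg$grid, y, cfg)
  expect_identical(f1, f2)

  short <- fit_melting_curve(c(37, 44, 50), c(1, 0.6, 0.2), cfg)
  expect_false(short$converged)
  expect_equal(short$reason, "too_few_points")
})

test_that("an alternative exponent convention is honored", {
  cfg <- screen_config(slope_times_t = FALSE)
  y <- melt_sigmoid(cfg$grid, 50, 2, 0.1, slope_times_t = FALSE)
  fit <- fit_melting_curve(cfg$grid, y, cfg)
  expect_equal(fit$tm, 50, tolerance = 1e-5)
  expect_equal(fit$b, 2, tolerance = 1e-4)
})

sim_curves <- function(n = 40, seed = 2, noise = 0.02) {
  cfg <- screen_config()
  set.seed(seed)
  grid <- cfg$grid
  purrr::map_dfr(seq_len(n), function(i) {
    tm <- rnorm(1, 50, 3)
    tidyr::expand_grid(
      treatment = c("vehicle", "cosubstrate", "enzyme", "both"),
      replicate = 1:2
    ) |>
      dplyr::mutate(protein_id = sprintf("P%03d", i)) |>
      tidyr::expand_grid(temperature = grid) |>
      dplyr::mutate(
        fraction = melt_sigmoid(temperature, tm, 0.03, 0.05) *
          exp(rnorm(dplyr::n(), 0, noise)),
        fraction = fraction / fraction[temperature == grid[1]][1],
        excluded = FALSE, exclude_reason = NA_character_
      )
  }) |>
    dplyr::group_by(protein_id, treatment, replicate) |>
    dplyr::mutate(fraction = fraction / fraction[which.min(temperature)]) |>
    dplyr::ungroup()
}

test_that("normalization is a fixed point when samples already agree", {
  curves <- sim_curves(n = 40, noise = 0)
  cfg <- screen_config()
  res <- normalize_to_reference(curves, cfg)
  expect_true(all(abs(res$normalization$factor - 1) < 0.01))
  expect_equal(res$curves$fraction, curves$fraction, tolerance = 0.01)
  expect_gte(attr(res$normalization, "n_proteins"), cfg$norm_min_shared)
})

test_that("a known per-temperature distortion is recovered as its reciprocal", {
  curves <- sim_curves(n = 60, noise = 0.01)
  cfg <- screen_config()
  set.seed(77)
  f <- c(1, exp(rnorm(9, 0, 0.1))) # distortion, 1 at reference
  distorted <- curves |>
    dplyr::mutate(
      fraction = ifelse(
        treatment == "vehicle" & replicate == 1,
        fraction * f[match(temperature, cfg$grid)],
        fraction
      )
    )
  res <- normalize_to_reference(distorted, cfg)
  got <- res$normalization |>
    dplyr::filter(treatment == "vehicle", replicate == 1) |>
    dplyr::arrange(match(temperature, cfg$grid)) |>
    dplyr::pull(factor)
  expect_equal(got[-1], 1 / f[-1], tolerance = 0.01)
  # the reference temperature is untouched everywhere
  ref_rows <- dplyr::filter(res$normalization, temperature == cfg$grid[1])
  expect_true(all(ref_rows$factor == 1))
})

test_that("normalization preserves reference fractions and errors on tiny overlap", {
  curves <- sim_curves(n = 30, noise = 0.02)
  cfg <- screen_config()
  res <- normalize_to_reference(curves, cfg)
  ref <- dplyr::filter(res$curves, temperature == cfg$grid[1])
  expect_true(all(ref$fraction == 1))
  cfg_hi <- screen_config(norm_min_shared = 1000)
  expect_error(normalize_to_reference(curves, cfg_hi), "skip")
})

test_that("QC gates flag marginal fits, inconsistent replicates and non-melters", {
  cfg <- screen_config()
  fits <- tibble::tibble(
    protein_id = rep(c("GOOD", "LOWR2", "WOBBLY", "PLATEAU"), each = 2),
    treatment = "vehicle",
    replicate = rep(1:2, times = 4),
    tm = c(50, 50.5, 50, 50.5, 48, 53, 51, 51.2),
    b = 0.03, pl = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.63, 0.65),
    r2 = c(0.95, 0.96, 0.69, 0.95, 0.9, 0.9, 0.95, 0.95),
    sse = 0.01, converged = TRUE, n_points = 10L, reason = NA_character_
  )
  tm <- qc_fits(fits, cfg)
  good <- dplyr::filter(tm, protein_id == "GOOD")
  expect_true(all(good$fit_ok))
  expect_equal(unique(good$rep_sd), sd(c(50, 50.5)))
  expect_equal(unique(good$rep_sd), 0.3536, tolerance = 1e-3)
  expect_true(all(good$rep_sd_ok))

  lowr2 <- dplyr::filter(tm, protein_id == "LOWR2")
  expect_false(all(lowr2$fit_ok)) # 0.69 is not > 0.7

  wob <- dplyr::filter(tm, protein_id == "WOBBLY")
  expect_false(any(wob$rep_sd_ok)) # SD 3.54 degC >= 2.5

  plat <- dplyr::filter(tm, protein_id == "PLATEAU")
  expect_true(all(plat$no_melting))
  expect_true(all(is.na(plat$tm)))
})

test_that("a protein that stays largely soluble at the top temperature is excluded as non-melting", {
  cfg <- screen_config()
  # high-plateau melter: ~63% residual solubility at 67 degC
  y <- melt_sigmoid(cfg$grid, 50, 0.03, 0.63)
  fits <- fit_melting_curves(
    tibble::tibble(
      protein_id = "TXNLIKE", treatment = "vehicle", replicate = 1L,
      temperature = cfg$grid, fraction = y,
      excluded = FALSE, exclude_reason = NA_character_
    ),
    cfg
  )
  tm <- qc_fits(fits, cfg)
  expect_true(all(tm$no_melting))
})
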