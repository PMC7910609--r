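test_that("the row t-test reproduces a hand-computed pooled example", {
  # {50, 51} vs {47, 48}: delta = 3, sp2 = 0.5, se = sqrt(0.5), t = 4.2426,
  # df = 2, p = 0.0513 (two-sided)
  res <- meltscreen:::row_ttest(
    matrix(c(50, 51), 1), matrix(c(47, 48), 1)
  )
  expect_equal(res$delta, 3)
  expect_equal(res$t, 3 / sqrt(0.5 * (1 / 2 + 1 / 2)), tolerance = 1e-10)
  expect_equal(round(res$t, 4), 4.2426)
  expect_equal(res$df, 2)
  expect_equal(round(res$p, 4), 0.0513)
  expect_equal(res$variance_mode, "student")
  # and agrees with stats::t.test on the same data
  ref <- t.test(c(50, 51), c(47, 48), var.equal = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
})

test_that("the row t-test handles degenerate inputs sanely", {
  # identical groups: delta 0, p = 1
  res <- meltscreen:::row_ttest(matrix(c(50, 50), 1), matrix(c(50, 50), 1))
  expect_equal(res$delta, 0)
  expect_equal(res$p, 1)
  # zero-variance but shifted: p tiny but strictly positive
  res2 <- meltscreen:::row_ttest(matrix(c(53, 53), 1), matrix(c(50, 50), 1))
  expect_gt(res2$p, 0)
  expect_lt(res2$p, 1e-6)
  # the F-gate routes grossly unequal variances to Welch
  res3 <- meltscreen:::row_ttest(
    matrix(rep(c(40, 60), 3), 1), matrix(c(50, 50.0001, 49.9999, 50, 50, 50), 1)
  )
  expect_equal(res3$variance_mode, "welch")
  ref3 <- t.test(rep(c(40, 60), 3), c(50, 50.0001, 49.9999, 50, 50, 50))
  expect_equal(res3$p, ref3$p.value, tolerance = 1e-9)
})

test_that("compare_groups returns tidy per-protein contrasts and flags incompleteness", {
  tm <- dplyr::bind_rows(
    tm_one("HIT", cosubstrate = c(50, 51), vehicle = c(47, 48)),
    tm_one("MISS", cosubstrate = c(50, NA), vehicle = c(47, 48))
  )
  out <- compare_groups(tm, "cosubstrate", "vehicle")
  hit <- dplyr::filter(out, protein_id == "HIT")
  expect_equal(hit$delta_tm, 3)
  expect_equal(round(hit$p_value, 4), 0.0513)
  expect_equal(hit$contrast, "cosubstrate-vehicle")
  miss <- dplyr::filter(out, protein_id == "MISS")
  expect_true(is.na(miss$p_value))
  expect_equal(miss$reason, "incomplete")
})

crafted_table <- function() {
  dplyr::bind_rows(
    # stabilized only with both enzyme and cosubstrate present: a substrate
    tm_one("SUB",
      vehicle = c(50.1, 49.9), cosubstrate = c(49.2, 50.8),
      enzyme = c(49.7, 50.3), both = c(52.5, 53.5)
    ),
    # stabilized whenever cosubstrate is present: a binder, not a substrate
    tm_one("BIND",
      vehicle = c(50, 50.4), cosubstrate = c(53.0, 53.4),
      enzyme = c(50.1, 50.3), both = c(53.1, 53.5)
    ),
    # stabilized whenever the enzyme is present: an interactor
    tm_one("INT",
      vehicle = c(50, 50.4), cosubstrate = c(50.1, 50.3),
      enzyme = c(53.0, 53.4), both = c(53.1, 53.5)
    ),
    # big shift vs enzyme but negligible vs cosubstrate: fails the dual gate
    tm_one("HALF",
      vehicle = c(50, 50.2), cosubstrate = c(52.9, 53.1),
      enzyme = c(50.1, 50.3), both = c(53.2, 53.4)
    ),
    tm_background(20, sd = 0.2, seed = 11)
  )
}

test_that("substrate selection requires both contrasts, with correct class separation", {
  tm <- crafted_table()
  cfg <- screen_config()
  subs <- select_candidates(tm, cfg, mode = "substrate")
  expect_equal(subs$protein_id, "SUB")
  expect_equal(subs$direction, "stabilized")
  expect_equal(subs$delta_tm,
    mean(c(mean(c(52.5, 53.5)) - mean(c(49.7, 50.3)),
           mean(c(52.5, 53.5)) - mean(c(49.2, 50.8)))))
  binders <- select_candidates(tm, cfg, mode = "cosubstrate_binder")
  expect_setequal(binders$protein_id, c("BIND", "HALF"))
  ints <- select_candidates(tm, cfg, mode = "enzyme_interactor")
  expect_equal(ints$protein_id, "INT")
})

test_that("keep_all exposes the per-criterion flags that explain a rejection", {
  tm <- crafted_table()
  all <- select_candidates(tm, screen_config(), mode = "substrate", keep_all = TRUE)
  half <- dplyr::filter(all, protein_id == "HALF")
  expect_false(half$selected)
  expect_false(half$pass_dtm) # both-vs-cosubstrate shift is ~0.3 degC
  expect_gt(abs(half$delta_tm_both_vs_enzyme), 1)
  expect_lt(abs(half$delta_tm_both_vs_cosubstrate), 1)
})

test_that("a shift below the magnitude cutoff is rejected even when significant", {
  tm <- dplyr::bind_rows(
    tm_one("TINY",
      vehicle = c(50, 50.05), cosubstrate = c(50.02, 50.07),
      enzyme = c(50.01, 50.06), both = c(50.41, 50.46)
    )
  )
  all <- select_candidates(tm, screen_config(), mode = "substrate", keep_all = TRUE)
  expect_true(all$pass_p) # +0.4 degC with 0.035 SD is highly significant
  expect_false(all$pass_dtm)
  expect_false(all$selected)
})

test_that("selection is monotone in the thresholds", {
  tm <- crafted_table()
  base <- select_candidates(tm, screen_config(), mode = "substrate")$protein_id
  looser <- select_candidates(
    tm, screen_config(p_primary = 0.1, p_secondary = 0.2, dtm_min = 0.5),
    mode = "substrate"
  )$protein_id
  expect_true(all(base %in% looser))
  tighter <- select_candidates(
    tm, screen_config(p_primary = 0.01, p_secondary = 0.02, dtm_min = 2.5),
    mode = "substrate"
  )$protein_id
  expect_true(all(tighter %in% base))
})

test_that("QC gates remove low-R2 and replicate-inconsistent proteins from selection", {
  tm <- dplyr::bind_rows(
    tm_one("GOODFIT",
      vehicle = c(50, 50.2), cosubstrate = c(50.1, 50.3),
      enzyme = c(50.0, 50.2), both = c(53.0, 53.4)
    ),
    tm_one("BADFIT",
      vehicle = c(50, 50.2), cosubstrate = c(50.1, 50.3),
      enzyme = c(50.0, 50.2), both = c(53.0, 53.4), r2 = 0.5
    ),
    tm_one("WOBBLY",
      vehicle = c(48, 53.5), cosubstrate = c(50.1, 50.3),
      enzyme = c(50.0, 50.2), both = c(53.0, 53.4)
    )
  )
  all <- select_candidates(tm, screen_config(), mode = "substrate", keep_all = TRUE)
  expect_true(dplyr::filter(all, protein_id == "GOODFIT")$selected)
  bad <- dplyr::filter(all, protein_id == "BADFIT")
  expect_false(bad$pass_r2)
  expect_false(bad$selected)
  # WOBBLY's vehicle arm does not enter the substrate contrasts; its own
  # wobble is in vehicle so it is not gated here -- move the wobble in:
  tm2 <- dplyr::bind_rows(
    tm_one("WOB2",
      vehicle = c(50, 50.2), cosubstrate = c(48, 53.5),
      enzyme = c(50.0, 50.2), both = c(53.0, 53.4)
    )
  )
  all2 <- select_candidates(tm2, screen_config(), mode = "substrate", keep_all = TRUE)
  expect_false(all2$pass_rep_sd)
  expect_false(all2$selected)
})

test_that("replicate variation and shift summaries match hand arithmetic", {
  tm <- dplyr::bind_rows(
    tm_one("A", vehicle = c(50, 50 + 0.2 * sqrt(2))),
    tm_one("B", vehicle = c(51, 51 + 0.8 * sqrt(2)))
  )
  rv <- replicate_variation_summary(tm)
  expect_equal(rv$median_sd, 0.5, tolerance = 1e-12)
  expect_equal(rv$mean_sd, 0.5, tolerance = 1e-12)
  expect_equal(rv$n_proteins, 2L)

  cand <- tibble::tibble(
    protein_id = c("X", "Y", "Z"),
    delta_tm = c(2, -3, -1.5),
    direction = c("stabilized", "destabilized", "destabilized")
  )
  s <- summarize_shifts(cand)
  expect_equal(s$n, 3L)
  expect_equal(s$n_stabilized, 1L)
  expect_equal(s$n_destabilized, 2L)
  expect_equal(s$mean_abs_dtm, mean(c(2, 3, 1.5)))
  expect_equal(s$median_abs_dtm, 2)

  empty <- summarize_shifts(cand[0, ])
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean_abs_dtm))
})

test_that("permutation FDR is deterministic in the seed and leaves the RNG alone", {
  tm <- crafted_table()
  cfg <- screen_config()
  set.seed(999)
  before <- .Random.seed
  f1 <- estimate_fdr_permutation(tm, cfg, mode = "substrate", n_perm = 50, seed = 7)
  expect_identical(.Random.seed, before)
  f2 <- estimate_fdr_permutation(tm, cfg, mode = "substrate", n_perm = 50, seed = 7)
  expect_identical(f1$permuted_hits, f2$permuted_hits)
  f3 <- estimate_fdr_permutation(tm, cfg, mode = "substrate", n_perm = 50, seed = 8)
  expect_false(identical(f3$permuted_hits, f1$permuted_hits))
  expect_equal(f1$fdr, f1$mean_permuted_hits / f1$observed_hits)
})

test_that("permuting a table with identical Tm everywhere yields zero hits, and
           no observed hits gives NA with a warning", {
  M <- matrix(50, 10, 8)
  rownames(M) <- sprintf("C%02d", 1:10)
  tm <- tm_table_from_matrix(M)
  expect_warning(
    f <- estimate_fdr_permutation(tm, screen_config(), "substrate",
      n_perm = 10, seed = 1
    ),
    "no observed hits"
  )
  expect_true(is.na(f$fdr))
  expect_equal(f$observed_hits, 0L)
  expect_true(all(f$permuted_hits == 0))
})

test_that("column granularity permutes all proteins with one relabeling", {
  tm <- crafted_table()
  f <- estimate_fdr_permutation(tm, screen_config(), "substrate",
    n_perm = 25, seed = 3, granularity = "column"
  )
  expect_equal(f$granularity, "column")
  expect_equal(length(f$permuted_hits), 25)
  expect_true(all(f$permuted_hits >= 0))
})

test_that("detection degrades monotonically with replicate noise (common random numbers)", {
  sens_at <- function(sigma) {
    set.seed(2024)
    n_hit <- 25
    base <- matrix(rnorm(n_hit * 8, 50, 1e-9), n_hit, 8) # deterministic centers
    noise <- matrix(rnorm(n_hit * 8), n_hit, 8) # shared across sigma levels
    M <- base + sigma * noise
    # plant +3 degC in the 'both' arm
    arms <- rep(ARMS, each = 2)
    M[, arms == "both"] <- M[, arms == "both"] + 3
    rownames(M) <- sprintf("H%03d", seq_len(n_hit))
    tm <- tm_table_from_matrix(M, treatments = arms, replicates = rep(1:2, 4))
    nrow(select_candidates(tm, screen_config(), mode = "substrate")) / n_hit
  }
  s <- vapply(c(0.1, 0.5, 1.5, 3), sens_at, numeric(1))
  expect_equal(s[1], 1)
  expect_true(all(diff(s) <= 0))
  expect_lt(s[4], s[1])
})
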