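## contrasts (group A minus group B) defining each candidate class
MODE_CONTRASTS <- list(
  cosubstrate_binder = list(c("cosubstrate", "vehicle")),
  substrate = list(c("both", "enzyme"), c("both", "cosubstrate")),
  enzyme_interactor = list(c("enzyme", "vehicle"))
)

## Vectorized two-sided t-test per row, pooled vs Welch chosen by a
## two-sided F-test on the variance ratio at level f_alpha.
row_ttest <- function(A, B, f_alpha = 0.05) {
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- apply(A, 1, var); v2 <- apply(B, 1, var)
  delta <- m1 - m2

  ratio <- v1 / v2
  p_f <- 2 * pmin(
    pf(ratio, n1 - 1, n2 - 1),
    pf(ratio, n1 - 1, n2 - 1, lower.tail = FALSE)
  )
  ## degenerate variances (0/0) give NaN: fall back to the pooled test
  equal <- !is.finite(p_f) | p_f >= f_alpha

  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se_s <- sqrt(sp2 * (1 / n1 + 1 / n2))
  df_s <- rep(n1 + n2 - 2, length(delta))
  se_w <- sqrt(v1 / n1 + v2 / n2)
  df_w <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))

  se <- ifelse(equal, se_s, se_w)
  df <- ifelse(equal, df_s, df_w)
  t <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, sign(delta) * Inf))
  p <- ifelse(
    is.finite(t), 2 * pt(-abs(t), df),
    .Machine$double.xmin
  )
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  list(
    delta = unname(delta), t = unname(t), df = unname(df), p = unname(p),
    variance_mode = unname(ifelse(equal, "student", "welch"))
  )
}

## Pivot a tm_table into aligned wide matrices (proteins x samples).
tm_wide <- function(tm_table) {
  tm_table <- tibble::as_tibble(tm_table)
  if (!"r2" %in% names(tm_table)) tm_table$r2 <- NA_real_
  tm_table <- tm_table |>
    dplyr::mutate(sample = sample_id(.data$treatment, .data$replicate))
  cols <- tm_table |>
    dplyr::distinct(.data$sample, .data$treatment, .data$replicate) |>
    dplyr::arrange(.data$treatment, .data$replicate)
  prot <- sort(unique(tm_table$protein_id))
  idx <- cbind(
    match(tm_table$protein_id, prot),
    match(tm_table$sample, cols$sample)
  )
  TM <- matrix(NA_real_, length(prot), nrow(cols),
    dimnames = list(prot, cols$sample)
  )
  R2 <- TM
  TM[idx] <- tm_table$tm
  R2[idx] <- tm_table$r2
  list(tm = TM, r2 = R2, treatment = cols$treatment, proteins = prot)
}

## Selection engine shared by the tidy interface and the permutation loop.
## TM/R2: proteins x samples matrices; treat: treatment per column.
screen_core <- function(TM, R2, treat, config, mode) {
  contrasts <- MODE_CONTRASTS[[mode]]
  if (is.null(contrasts)) {
    abort(paste0(
      "unknown mode: ", mode, " (expected ",
      paste(names(MODE_CONTRASTS), collapse = "/"), ")"
    ))
  }
  relevant <- unique(unlist(contrasts))
  rel_cols <- treat %in% relevant
  TMr <- TM[, rel_cols, drop = FALSE]
  R2r <- R2[, rel_cols, drop = FALSE]
  treat_r <- treat[rel_cols]

  complete <- rowSums(!is.na(TMr)) == ncol(TMr)
  pass_r2 <- rowSums(is.na(R2r) | R2r <= config$r2_min) == 0

  pass_sd <- rep(TRUE, nrow(TMr))
  for (tr in relevant) {
    sub <- TMr[, treat_r == tr, drop = FALSE]
    if (ncol(sub) < 2) abort(paste0("treatment '", tr, "' needs >= 2 replicates."))
    sds <- apply(sub, 1, sd)
    pass_sd <- pass_sd & !is.na(sds) & sds < config$sd_max
  }

  stats <- lapply(contrasts, function(ct) {
    A <- TMr[, treat_r == ct[1], drop = FALSE]
    B <- TMr[, treat_r == ct[2], drop = FALSE]
    row_ttest(A, B, config$f_alpha)
  })

  d <- vapply(stats, `[[`, numeric(nrow(TMr)), "delta")
  p <- vapply(stats, `[[`, numeric(nrow(TMr)), "p")
  if (is.null(dim(d))) { d <- matrix(d, nrow = 1); p <- matrix(p, nrow = 1) }

  if (mode == "substrate") {
    p_min <- pmin(p[, 1], p[, 2])
    p_max <- pmax(p[, 1], p[, 2])
    pass_p <- p_min < config$p_primary & p_max < config$p_secondary
    pass_dtm <- abs(d[, 1]) > config$dtm_min & abs(d[, 2]) > config$dtm_min
    pass_sign <- sign(d[, 1]) == sign(d[, 2])
    if (!config$require_sign_concordance) pass_sign <- rep(TRUE, nrow(d))
    delta <- rowMeans(d)
  } else {
    pass_p <- p[, 1] < config$p_primary
    pass_dtm <- abs(d[, 1]) > config$dtm_min
    pass_sign <- rep(TRUE, nrow(d))
    delta <- d[, 1]
  }
  pass_p[!complete] <- FALSE
  pass_dtm[!complete] <- FALSE
  selected <- complete & pass_r2 & pass_sd & pass_p & pass_dtm & pass_sign

  list(
    complete = complete, pass_r2 = pass_r2, pass_rep_sd = pass_sd,
    pass_p = pass_p, pass_dtm = pass_dtm, pass_sign = pass_sign,
    selected = selected, delta = delta, d = d, p = p,
    variance_mode = stats[[1]]$variance_mode, contrasts = contrasts
  )
}

#' Contrast melting temperatures between two treatments
#'
#' Per protein, the mean Tm difference (group A minus group B) with a
#' two-sided t-test; the pooled-variance (Student) or Welch form is chosen
#' by a two-sided F-test of variance equality at `config$f_alpha`. No
#' multiple-testing adjustment is applied. Only proteins with a Tm in every
#' replicate of both groups (and at least two per group) are tested;
#' incomplete proteins are returned with `reason = "incomplete"` and `NA`
#' statistics.
#'
#' @param tm_table Tibble with `protein_id`, `treatment`, `replicate`, `tm`
#'   (e.g. from [qc_fits()]).
#' @param group_a,group_b Treatment arm names.
#' @param config A [screen_config()].
#' @return Tibble: `protein_id`, `contrast`, `delta_tm`, `t`, `df`,
#'   `p_value`, `variance_mode`, `reason`.
#' @export
#' @examples
#' tm <- tibble::tibble(
#'   protein_id = "P1",
#'   treatment = rep(c("cosubstrate", "vehicle"), each = 2),
#'   replicate = c(1, 2, 1, 2),
#'   tm = c(50, 51, 47, 48)
#' )
#' compare_groups(tm, "cosubstrate", "vehicle")
compare_groups <- function(tm_table, group_a, group_b, config = screen_config()) {
  w <- tm_wide(tm_table)
  A <- w$tm[, w$treatment == group_a, drop = FALSE]
  B <- w$tm[, w$treatment == group_b, drop = FALSE]
  if (ncol(A) < 2 || ncol(B) < 2) {
    abort("each group needs at least 2 replicate samples.")
  }
  complete <- unname(rowSums(is.na(A)) == 0 & rowSums(is.na(B)) == 0)
  res <- row_ttest(A, B, config$f_alpha)
  tibble::tibble(
    protein_id = w$proteins,
    contrast = paste0(group_a, "-", group_b),
    delta_tm = ifelse(complete, res$delta, NA_real_),
    t = ifelse(complete, res$t, NA_real_),
    df = ifelse(complete, res$df, NA_real_),
    p_value = ifelse(complete, res$p, NA_real_),
    variance_mode = ifelse(complete, res$variance_mode, NA_character_),
    reason = ifelse(complete, NA_character_, "incomplete")
  )
}

#' Select candidate proteins under the screen criteria
#'
#' Applies, per protein, the four-part selection for the requested class:
#' \describe{
#'   \item{cosubstrate_binder}{R2 gate in all vehicle/cosubstrate samples,
#'     replicate SD of Tm below `sd_max` in both arms, p < `p_primary` on
#'     the cosubstrate-vehicle contrast, |dTm| > `dtm_min`.}
#'   \item{substrate}{the same gates over the both/enzyme/cosubstrate arms;
#'     the two contrasts both-enzyme and both-cosubstrate must satisfy
#'     min(p) < `p_primary` and max(p) < `p_secondary`, both |dTm| >
#'     `dtm_min`, and (by default) agree in sign.}
#'   \item{enzyme_interactor}{the binder criteria applied to the
#'     enzyme-vehicle contrast.}
#' }
#' Replicate-SD gates are recomputed from the supplied Tm values, so the
#' same function drives permutation rounds.
#'
#' @param tm_table Tibble with `protein_id`, `treatment`, `replicate`,
#'   `tm`, `r2` (from [qc_fits()]).
#' @param config A [screen_config()].
#' @param mode `"cosubstrate_binder"`, `"substrate"` or
#'   `"enzyme_interactor"`.
#' @param keep_all Return every complete-case protein with its per-criterion
#'   flags (`TRUE`) or only the selected candidates (default).
#' @return Tibble of candidate records: contrast effect sizes and p-values,
#'   `class`, `direction` (`"stabilized"`/`"destabilized"`), per-criterion
#'   pass flags and `abs_delta_tm`.
#' @export
select_candidates <- function(tm_table, config = screen_config(),
                              mode = c("substrate", "cosubstrate_binder", "enzyme_interactor"),
                              keep_all = FALSE) {
  mode <- match.arg(mode)
  w <- tm_wide(tm_table)
  core <- screen_core(w$tm, w$r2, w$treatment, config, mode)

  out <- tibble::tibble(
    protein_id = w$proteins,
    class = mode,
    delta_tm = core$delta,
    abs_delta_tm = abs(core$delta),
    direction = ifelse(core$delta >= 0, "stabilized", "destabilized"),
    pass_r2 = core$pass_r2,
    pass_rep_sd = core$pass_rep_sd,
    pass_p = core$pass_p,
    pass_dtm = core$pass_dtm,
    pass_sign = core$pass_sign,
    selected = core$selected
  )
  labels <- vapply(core$contrasts, function(ct) paste0(ct[1], "_vs_", ct[2]), "")
  for (i in seq_along(labels)) {
    out[[paste0("delta_tm_", labels[i])]] <- core$d[, i]
    out[[paste0("p_", labels[i])]] <- core$p[, i]
  }
  out$delta_tm[!core$complete] <- NA_real_
  out$abs_delta_tm[!core$complete] <- NA_real_
  out$direction[!core$complete] <- NA_character_
  if (keep_all) out else dplyr::filter(out, .data$selected)
}

#' Estimate the screen-wide FDR by permutation
#'
#' Destroys the treatment structure while preserving each protein's Tm
#' distribution: per round, every protein's observed (Tm, R2) pairs are
#' reassigned at random among the sample labels where that protein was
#' observed (`granularity = "protein"`), or one common relabeling of the
#' sample columns is applied to all proteins (`granularity = "column"`).
#' The complete selection — including the replicate-SD gate when
#' `config$permute_qc` is `TRUE` — is re-run on each shuffled table, and
#' the FDR is the mean number of permuted hits divided by the observed hit
#' count.
#'
#' @param tm_table Tibble as in [select_candidates()].
#' @param config A [screen_config()].
#' @param mode Candidate class to permute.
#' @param n_perm Number of permutation rounds.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param granularity `"protein"` (default) or `"column"`.
#' @return A `permutation_fdr` list: `observed_hits`,
#'   `mean_permuted_hits`, `fdr` (`NA` with a warning when nothing was
#'   observed), `permuted_hits` per round, `n_permutations`, `seed`.
#' @export
estimate_fdr_permutation <- function(tm_table, config = screen_config(),
                                     mode = "substrate",
                                     n_perm = config$n_perm, seed = 1L,
                                     granularity = c("protein", "column")) {
  granularity <- match.arg(granularity)
  w <- tm_wide(tm_table)
  observed <- sum(screen_core(w$tm, w$r2, w$treatment, config, mode)$selected)

  cfg <- config
  if (!cfg$permute_qc) cfg$sd_max <- Inf

  obs_idx <- lapply(seq_len(nrow(w$tm)), function(i) which(!is.na(w$tm[i, ])))
  hits <- integer(n_perm)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  for (k in seq_len(n_perm)) {
    TMp <- w$tm
    R2p <- w$r2
    if (granularity == "column") {
      perm <- sample(ncol(TMp))
      TMp <- TMp[, perm, drop = FALSE]
      R2p <- R2p[, perm, drop = FALSE]
    } else {
      for (i in seq_len(nrow(TMp))) {
        idx <- obs_idx[[i]]
        if (length(idx) > 1) {
          shuffled <- idx[sample.int(length(idx))]
          TMp[i, idx] <- w$tm[i, shuffled]
          R2p[i, idx] <- w$r2[i, shuffled]
        }
      }
    }
    hits[k] <- sum(screen_core(TMp, R2p, w$treatment, cfg, mode)$selected)
  }
  mean_hits <- mean(hits)
  fdr <- if (observed > 0) mean_hits / observed else NA_real_
  if (observed == 0) warn("no observed hits; permutation FDR is undefined (NA).")
  structure(
    list(
      observed_hits = observed, mean_permuted_hits = mean_hits,
      fdr = fdr, permuted_hits = hits, n_permutations = n_perm,
      seed = seed, mode = mode, granularity = granularity
    ),
    class = "permutation_fdr"
  )
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.permutation_fdr <- function(x, ...) {
  cat("<permutation_fdr>\n")
  cat(sprintf(
    "  mode: %s | observed hits: %d | mean permuted hits: %.2f (%d rounds)\n",
    x$mode, x$observed_hits, x$mean_permuted_hits, x$n_permutations
  ))
  cat(sprintf(
    "  FDR: %s\n",
    if (is.na(x$fdr)) "NA (no observed hits)" else sprintf("%.1f%%", 100 * x$fdr)
  ))
  invisible(x)
}

#' Summarize replicate-to-replicate Tm variation
#'
#' Per treatment, the median and mean of the per-protein standard deviation
#' of Tm across replicates — the quantity that motivates the 1 degree C
#' minimum-shift cutoff.
#'
#' @param tm_table Tibble with `protein_id`, `treatment`, `replicate`, `tm`.
#' @return Tibble: `treatment`, `n_proteins`, `median_sd`, `mean_sd`
#'   (degrees C; `NA` where a treatment has a single replicate).
#' @export
replicate_variation_summary <- function(tm_table) {
  tm_table |>
    dplyr::group_by(.data$protein_id, .data$treatment) |>
    dplyr::summarise(
      rep_sd = if (sum(!is.na(.data$tm)) >= 2) sd(.data$tm, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      n_proteins = sum(!is.na(.data$rep_sd)),
      median_sd = median(.data$rep_sd, na.rm = TRUE),
      mean_sd = mean(.data$rep_sd, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Summarize the shifts of a candidate set
#'
#' @param candidates Candidate tibble from [select_candidates()].
#' @return One-row tibble: `n`, `n_stabilized`, `n_destabilized`,
#'   `mean_abs_dtm`, `median_abs_dtm` (degrees C; `NA` summaries when
#'   empty).
#' @export
summarize_shifts <- function(candidates) {
  if (nrow(candidates) == 0) {
    return(tibble::tibble(
      n = 0L, n_stabilized = 0L, n_destabilized = 0L,
      mean_abs_dtm = NA_real_, median_abs_dtm = NA_real_
    ))
  }
  tibble::tibble(
    n = nrow(candidates),
    n_stabilized = sum(candidates$direction == "stabilized"),
    n_destabilized = sum(candidates$direction == "destabilized"),
    mean_abs_dtm = mean(abs(candidates$delta_tm)),
    median_abs_dtm = median(abs(candidates$delta_tm))
  )
}
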