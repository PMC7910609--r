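# Independent oracles and small builders used across the suite.

# Exhaustive grid-search SSE minimizer for the melting sigmoid.
# For fixed (tm, b) the model I = s + pl * (1 - s), s = 1/(1 + exp((T-tm)/(bT))),
# is linear in pl, so pl is solved in closed form and clipped to [0, 0.999].
# Completely independent of the package's optimizer.
sigmoid_grid_oracle <- function(x, y,
                                tm_seq = seq(35, 70, by = 0.02),
                                b_seq = exp(seq(log(0.005), log(0.2), length.out = 150))) {
  Y <- matrix(y, nrow = length(tm_seq), ncol = length(x), byrow = TRUE)
  best_sse <- Inf
  best_tm <- NA_real_
  for (b in b_seq) {
    E <- outer(tm_seq, x, function(tm, t) (t - tm) / (b * t))
    S <- 1 / (1 + exp(E))
    G <- 1 - S
    pl <- rowSums((Y - S) * G) / rowSums(G^2)
    pl <- pmin(pmax(pl, 0), 0.999)
    R <- Y - S - pl * G
    sse <- rowSums(R^2)
    i <- which.min(sse)
    if (sse[i] < best_sse - 1e-15 ||
      (abs(sse[i] - best_sse) <= 1e-15 && tm_seq[i] < best_tm)) {
      best_sse <- sse[i]
      best_tm <- tm_seq[i]
    }
  }
  list(tm = best_tm, sse = best_sse)
}

# Independently coded one-component NIPALS PLS1 on a pre-scaled X and
# centered y.
nipals_pls1 <- function(X, y) {
  w <- drop(crossprod(X, y))
  w <- w / sqrt(sum(w^2))
  t <- drop(X %*% w)
  p <- drop(crossprod(X, t)) / sum(t^2)
  cc <- sum(y * t) / sum(t^2)
  list(w = w, t = t, p = p, c = cc, y_hat = t * cc)
}

ARMS <- c("vehicle", "cosubstrate", "enzyme", "both")

# Long tm_table from a proteins x samples matrix (two replicates per arm by
# default, columns ordered arm-major).
tm_table_from_matrix <- function(M, treatments = rep(ARMS, each = 2),
                                 replicates = rep(1:2, times = 4),
                                 r2 = 0.99) {
  stopifnot(ncol(M) == length(treatments))
  ids <- rownames(M) %||% sprintf("P%03d", seq_len(nrow(M)))
  tidyr::expand_grid(
    protein_id = ids,
    idx = seq_len(ncol(M))
  ) |>
    dplyr::mutate(
      treatment = treatments[idx],
      replicate = replicates[idx],
      tm = M[cbind(match(protein_id, ids), idx)],
      r2 = r2
    ) |>
    dplyr::select(-idx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-protein tm_table from per-arm replicate vectors.
tm_one <- function(id = "P1", vehicle = NULL, cosubstrate = NULL,
                   enzyme = NULL, both = NULL, r2 = 0.99) {
  vals <- list(
    vehicle = vehicle, cosubstrate = cosubstrate,
    enzyme = enzyme, both = both
  )
  vals <- vals[!vapply(vals, is.null, logical(1))]
  dplyr::bind_rows(lapply(names(vals), function(tr) {
    tibble::tibble(
      protein_id = id, treatment = tr,
      replicate = seq_along(vals[[tr]]), tm = vals[[tr]], r2 = r2
    )
  }))
}

# Null background proteins: identical structure, tm drawn around 50.
tm_background <- function(n, sd = 0.3, seed = 42, r2 = 0.99) {
  set.seed(seed)
  M <- matrix(rnorm(n * 8, 50, sd), n, 8)
  rownames(M) <- sprintf("BG%03d", seq_len(n))
  tm_table_from_matrix(M, r2 = r2)
}
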