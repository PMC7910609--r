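## Core OPLS (orthogonal projections to latent structures) engine on an
## already-scaled matrix Xs (samples x variables) and centered response yc.
## One predictive component; n_ortho orthogonal components removed first
## (Trygg-Wold filtering). Returns scores/loadings/weights.
opls_engine <- function(Xs, yc, n_ortho) {
  w <- drop(crossprod(Xs, yc))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) abort("degenerate model: response uncorrelated with every variable.")
  w <- w / nw

  X <- Xs
  W_o <- P_o <- NULL
  T_o <- NULL
  ssx_o <- numeric(0)
  for (o in seq_len(n_ortho)) {
    t <- drop(X %*% w)
    p <- drop(crossprod(X, t)) / sum(t^2)
    w_o <- p - sum(w * p) * w
    n_wo <- sqrt(sum(w_o^2))
    if (n_wo < 1e-10) {
      abort("no orthogonal variation left; lower `n_ortho`.")
    }
    w_o <- w_o / n_wo
    t_o <- drop(X %*% w_o)
    p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
    X <- X - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
    ssx_o <- c(ssx_o, sum(t_o^2) * sum(p_o^2))
  }
  t_p <- drop(X %*% w)
  p_p <- drop(crossprod(X, t_p)) / sum(t_p^2)
  c_p <- sum(yc * t_p) / sum(t_p^2)
  list(
    w = w, t_p = t_p, p_p = p_p, c_p = c_p,
    W_o = W_o, P_o = P_o, T_o = T_o, ssx_o = ssx_o,
    X_filtered = X
  )
}

opls_predict_engine <- function(eng, x_new) {
  # x_new: already-scaled matrix (rows = new samples)
  X <- x_new
  for (o in seq_len(NCOL(eng$W_o))) {
    t_o <- drop(X %*% eng$W_o[, o])
    X <- X - tcrossprod(t_o, eng$P_o[, o])
  }
  drop(X %*% eng$w) * eng$c_p
}

#' Fit an OPLS-DA model on the Tm matrix
#'
#' Observations are the samples (treatment x replicate), variables are the
#' proteins. The two classes (e.g. the enzyme+cosubstrate arm against the
#' two single-treatment arms) are coded +1/-1; proteins must have a Tm in
#' every included sample (complete cases), and zero-variance proteins are
#' dropped with a warning. Columns are mean-centered and, by default,
#' scaled to unit variance. `n_ortho` orthogonal components are removed
#' before the single predictive component is extracted; the fit is fully
#' deterministic.
#'
#' Class "reference points" are the loading-space coordinates of an ideal
#' indicator variable perfectly correlated with each class: the autoscaled
#' class dummy projected onto the score vectors,
#' `p_ref = t' d / (t' t)`.
#'
#' @param tm_table Tibble with `protein_id`, `treatment`, `replicate`,
#'   `tm`.
#' @param class_a,class_b Character vectors of treatment arms defining the
#'   two classes (class A coded +1).
#' @param n_ortho Number of orthogonal components (default 1; 0 reduces
#'   the model to one-component PLS-DA).
#' @param scale `"uv"` (unit variance, default) or `"center"`.
#' @return An `opls_da` object with scores, loadings, weights, VIP,
#'   reference points and explained-variance summaries (R2X, R2Y and
#'   leave-one-out Q2).
#' @export
fit_oplsda <- function(tm_table, class_a = "both",
                       class_b = c("enzyme", "cosubstrate"),
                       n_ortho = 1, scale = c("uv", "center")) {
  scale <- match.arg(scale)
  w <- tm_wide(tm_table)
  use <- w$treatment %in% c(class_a, class_b)
  TM <- w$tm[, use, drop = FALSE]
  treat <- w$treatment[use]
  y <- ifelse(treat %in% class_a, 1, -1)
  if (sum(y > 0) < 2 || sum(y < 0) < 2) abort("each class needs >= 2 samples.")

  keep <- rowSums(is.na(TM)) == 0
  X <- t(TM[keep, , drop = FALSE]) # samples x proteins
  proteins <- w$proteins[keep]
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("dropping ", sum(sds == 0), " zero-variance protein(s)."))
    X <- X[, sds > 0, drop = FALSE]
    proteins <- proteins[sds > 0]
    sds <- sds[sds > 0]
  }
  if (ncol(X) < 2) abort("fewer than 2 usable proteins.")
  if (n_ortho >= qr(base::scale(X))$rank) {
    abort("`n_ortho` must be smaller than the rank of the data.")
  }

  x_mean <- colMeans(X)
  x_sd <- if (scale == "uv") sds else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  y_mean <- mean(y)
  yc <- y - y_mean

  eng <- opls_engine(Xs, yc, n_ortho)

  ssx <- sum(Xs^2)
  ssy <- sum(yc^2)
  ssx_pred <- sum(eng$t_p^2) * sum(eng$p_p^2)
  r2x <- (ssx_pred + sum(eng$ssx_o)) / ssx
  y_fit <- eng$t_p * eng$c_p
  r2y <- 1 - sum((yc - y_fit)^2) / ssy

  ## leave-one-out Q2
  press <- 0
  for (i in seq_len(nrow(Xs))) {
    fit_i <- tryCatch(
      {
        Xi <- X[-i, , drop = FALSE]
        mi <- colMeans(Xi)
        si <- if (scale == "uv") apply(Xi, 2, sd) else rep(1, ncol(Xi))
        si[si == 0] <- 1
        Xsi <- sweep(sweep(Xi, 2, mi), 2, si, "/")
        yi <- y[-i] - mean(y[-i])
        ei <- opls_engine(Xsi, yi, n_ortho)
        xnew <- matrix((X[i, ] - mi) / si, nrow = 1)
        opls_predict_engine(ei, xnew) + mean(y[-i])
      },
      error = function(e) NA_real_
    )
    press <- press + (y[i] - fit_i)^2
  }
  q2 <- 1 - press / ssy

  ## reference points: autoscaled class dummies projected onto the scores
  ref <- lapply(list(A = as.numeric(y > 0), B = as.numeric(y < 0)), function(d) {
    d <- (d - mean(d)) / sd(d)
    c(
      p_pred = sum(eng$t_p * d) / sum(eng$t_p^2),
      p_ortho = if (NCOL(eng$T_o) > 0) sum(eng$T_o[, 1] * d) / sum(eng$T_o[, 1]^2) else 0
    )
  })

  samples <- colnames(TM)
  model <- structure(
    list(
      proteins = proteins, samples = samples, treatment = treat, y = y,
      y_mean = y_mean, x_mean = x_mean, x_sd = x_sd, scale = scale,
      n_ortho = n_ortho, class_a = class_a, class_b = class_b,
      weights = eng$w, loadings_pred = eng$p_p, scores_pred = eng$t_p,
      c_pred = eng$c_p, weights_ortho = eng$W_o, loadings_ortho = eng$P_o,
      scores_ortho = eng$T_o, ref_points = ref,
      r2x = r2x, r2y = r2y, q2 = q2,
      X = X, engine = eng
    ),
    class = "opls_da"
  )
  model$vip <- vip_point(model, type = "predictive")
  model
}

#' @export
print.opls_da <- function(x, ...) {
  cat("<opls_da>\n")
  cat(sprintf(
    "  %d samples (%s vs %s), %d proteins, %d orthogonal component(s)\n",
    length(x$y), paste(x$class_a, collapse = "+"),
    paste(x$class_b, collapse = "+"), length(x$proteins), x$n_ortho
  ))
  cat(sprintf("  R2X %.3f | R2Y %.3f | Q2 %.3f\n", x$r2x, x$r2y, x$q2))
  invisible(x)
}

## VIP point estimates for a fitted model.
## predictive: one predictive component -> VIP_j = sqrt(K) |w_j| / ||w||.
## total: adds the orthogonal components, weighting each component's
## normalized weights by the X-variance it explains.
vip_point <- function(model, type = c("predictive", "total")) {
  type <- match.arg(type)
  K <- length(model$proteins)
  w <- model$weights
  if (type == "predictive" || model$n_ortho == 0) {
    return(unname(sqrt(K * w^2 / sum(w^2))))
  }
  eng <- model$engine
  ssx_pred <- sum(eng$t_p^2) * sum(eng$p_p^2)
  ss <- c(ssx_pred, eng$ssx_o)
  W <- cbind(w, eng$W_o)
  W2 <- sweep(W^2, 2, colSums(W^2), "/")
  unname(sqrt(K * drop(W2 %*% ss) / sum(ss)))
}

#' Variable-importance (VIP) scores with confidence bounds
#'
#' VIP quantifies each protein's contribution to the discriminant
#' direction, normalized so that the mean squared VIP over the included
#' proteins is 1. Default is the predictive-component VIP; `type =
#' "total"` folds in the orthogonal components weighted by the X-variance
#' they explain. 95 percent bounds come from leave-one-sample-out
#' jackknife refits — approximate at the small sample sizes typical here
#' (4-8 observations).
#'
#' @param model An `opls_da` model.
#' @param type `"predictive"` (default) or `"total"`.
#' @param conf Confidence level (default 0.95); `NULL` skips the
#'   jackknife.
#' @return Tibble: `protein_id`, `vip`, `vip_lo`, `vip_hi`.
#' @export
compute_vip <- function(model, type = c("predictive", "total"), conf = 0.95) {
  type <- match.arg(type)
  stopifnot(inherits(model, "opls_da"))
  point <- vip_point(model, type)
  out <- tibble::tibble(
    protein_id = model$proteins, vip = point,
    vip_lo = NA_real_, vip_hi = NA_real_
  )
  if (is.null(conf)) return(out)

  n <- length(model$y)
  reps <- matrix(NA_real_, nrow = length(point), ncol = n)
  for (i in seq_len(n)) {
    reps[, i] <- tryCatch(
      {
        Xi <- model$X[-i, , drop = FALSE]
        mi <- colMeans(Xi)
        si <- if (model$scale == "uv") apply(Xi, 2, sd) else rep(1, ncol(Xi))
        si[si == 0] <- 1
        Xsi <- sweep(sweep(Xi, 2, mi), 2, si, "/")
        yi <- model$y[-i] - mean(model$y[-i])
        ei <- opls_engine(Xsi, yi, model$n_ortho)
        mi_model <- model
        mi_model$weights <- ei$w
        mi_model$engine <- ei
        vip_point(mi_model, type)
      },
      error = function(e) rep(NA_real_, length(point))
    )
  }
  ok <- colSums(is.na(reps)) == 0
  m <- sum(ok)
  if (m >= 2) {
    reps <- reps[, ok, drop = FALSE]
    se <- sqrt((m - 1) / m * rowSums((reps - rowMeans(reps))^2))
    tcrit <- qt(1 - (1 - conf) / 2, df = m - 1)
    out$vip_lo <- pmax(0, point - tcrit * se)
    out$vip_hi <- point + tcrit * se
  }
  out
}

#' Rank candidates by shift size and VIP
#'
#' Attaches two rankings to a candidate table: by absolute Tm shift and by
#' VIP from a fitted OPLS-DA model. Candidates absent from the model (e.g.
#' incomplete Tm across the modeled samples) get `NA` VIP, are flagged
#' `in_model = FALSE`, and are ordered by |dTm| alone at the end of the
#' VIP ranking. Ties on the primary key are broken by the other key, then
#' by accession.
#'
#' @param candidates Tibble from [select_candidates()].
#' @param model An `opls_da` model (or a VIP tibble from
#'   [compute_vip()]).
#' @param by Primary ordering: `"vip"` (default) or `"abs_delta_tm"`.
#' @return The candidate tibble with `vip`, `in_model`, `rank_vip`,
#'   `rank_dtm`, ordered by the primary key.
#' @export
rank_candidates <- function(candidates, model, by = c("vip", "abs_delta_tm")) {
  by <- match.arg(by)
  vip_tbl <- if (inherits(model, "opls_da")) {
    tibble::tibble(protein_id = model$proteins, vip = model$vip)
  } else {
    dplyr::select(tibble::as_tibble(model), "protein_id", "vip")
  }
  out <- candidates |>
    dplyr::left_join(vip_tbl, by = "protein_id") |>
    dplyr::mutate(in_model = !is.na(.data$vip))
  out <- out |>
    dplyr::mutate(
      rank_dtm = order(order(
        -.data$abs_delta_tm, -dplyr::coalesce(.data$vip, -Inf), .data$protein_id
      )),
      rank_vip = order(order(
        !.data$in_model, -dplyr::coalesce(.data$vip, -Inf),
        -.data$abs_delta_tm, .data$protein_id
      ))
    )
  if (by == "vip") {
    dplyr::arrange(out, .data$rank_vip)
  } else {
    dplyr::arrange(out, .data$rank_dtm)
  }
}

#' Tidy per-protein loadings, weights and VIP of an OPLS-DA model
#'
#' @param x An `opls_da` model.
#' @param ... Unused.
#' @return A tibble with one row per modeled protein.
#' @export
#' @method tidy opls_da
tidy.opls_da <- function(x, ...) {
  out <- tibble::tibble(
    protein_id = x$proteins,
    weight = x$weights,
    loading_pred = x$loadings_pred,
    vip = x$vip
  )
  if (NCOL(x$loadings_ortho) > 0) out$loading_ortho <- x$loadings_ortho[, 1]
  out
}

#' One-row summary of an OPLS-DA model (R2X, R2Y, leave-one-out Q2)
#'
#' @param x An `opls_da` model.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
#' @method glance opls_da
glance.opls_da <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$y), n_proteins = length(x$proteins),
    n_ortho = x$n_ortho, r2x = x$r2x, r2y = x$r2y, q2 = x$q2
  )
}

#' Loading plot of an OPLS-DA model
#'
#' Predictive versus (first) orthogonal loadings, one point per protein,
#' with the two class reference points drawn as stars. Proteins listed in
#' `highlight` are colored.
#'
#' @param object An `opls_da` model.
#' @param highlight Optional character vector of protein ids to highlight.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot opls_da
autoplot.opls_da <- function(object, highlight = NULL, ...) {
  td <- tidy(object)
  if (!"loading_ortho" %in% names(td)) td$loading_ortho <- 0
  td$highlight <- td$protein_id %in% (highlight %||% character())
  refs <- tibble::tibble(
    class = c(
      paste(object$class_a, collapse = "+"),
      paste(object$class_b, collapse = "+")
    ),
    p_pred = c(object$ref_points$A["p_pred"], object$ref_points$B["p_pred"]),
    p_ortho = c(object$ref_points$A["p_ortho"], object$ref_points$B["p_ortho"])
  )
  ggplot2::ggplot(td, ggplot2::aes(x = .data$loading_pred, y = .data$loading_ortho)) +
    ggplot2::geom_point(
      ggplot2::aes(color = .data$highlight),
      alpha = 0.6, show.legend = FALSE
    ) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40", `TRUE` = "forestgreen")) +
    ggplot2::geom_point(
      data = refs,
      ggplot2::aes(x = .data$p_pred, y = .data$p_ortho),
      shape = 8, size = 4, color = "blue", inherit.aes = FALSE
    ) +
    ggplot2::geom_text(
      data = refs,
      ggplot2::aes(x = .data$p_pred, y = .data$p_ortho, label = .data$class),
      vjust = -1.2, color = "blue", inherit.aes = FALSE
    ) +
    ggplot2::labs(
      x = "predictive loading", y = "orthogonal loading",
      title = "OPLS-DA loadings"
    ) +
    ggplot2::theme_minimal()
}
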