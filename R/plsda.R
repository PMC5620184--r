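#' PLS-DA probe selection by VIP score
#'
#' Partial least squares regression of the centered expression matrix on
#' the centered class-indicator matrix (PLS2), fitted by the iterative
#' NIPALS algorithm with X-deflation, used discriminatively for two- or
#' three-class survival groupings. Probes are ranked by their variable
#' importance in projection (VIP); probes with VIP at or above the
#' threshold are selected and, when long/short sample groups are supplied,
#' subsequently fold-change filtered.
#'
#' @param x numeric matrix or `ExpressionMatrix` (probes x samples).
#' @param classes class label per sample (2 or 3 classes, each with at
#'   least 2 samples).
#' @param n_components number of latent components (must be smaller than
#'   both the sample and probe counts).
#' @param vip_threshold VIP selection threshold (conventionally 1).
#' @param long_ids,short_ids optional sample groups for the fold-change
#'   filter applied after VIP selection.
#' @param fold_cutoff fold-change cutoff used when groups are supplied.
#' @return A list of class `plsda_result`: `probes` (selected IDs), `vip`
#'   (named VIP scores), `scores` (latent sample scores, mutually
#'   orthogonal), `weights`, and `explained_y` (per-component Y sum of
#'   squares captured).
#' @export
plsda_select <- function(x, classes, n_components = 2L, vip_threshold = 1,
                         long_ids = NULL, short_ids = NULL, fold_cutoff = 2) {
  V <- as_values(x)
  classes <- factor(as.character(classes))
  if (nlevels(classes) < 2L) stop("need at least two classes")
  if (any(table(classes) < 2L)) stop("each class needs at least 2 samples")
  n <- ncol(V); p <- nrow(V)
  if (n_components >= min(n, p))
    stop("n_components must be smaller than min(samples, probes)")
  X <- scale(t(V), center = TRUE, scale = FALSE)        # samples x probes
  Y <- scale(stats::model.matrix(~ classes - 1), center = TRUE, scale = FALSE)

  W <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  ssy <- numeric(n_components)
  for (a in seq_len(n_components)) {
    u <- Y[, which.max(colSums(Y^2))]
    for (iter in seq_len(500L)) {
      w <- crossprod(X, u)[, 1L]
      w <- w / sqrt(sum(w^2))
      tt <- X %*% w
      qv <- crossprod(Y, tt)[, 1L] / sum(tt^2)
      u_new <- Y %*% qv / sum(qv^2)
      if (sqrt(sum((u_new - u)^2)) < 1e-12 * sqrt(sum(u_new^2))) {
        u <- u_new; break
      }
      u <- u_new
    }
    pl <- crossprod(X, tt)[, 1L] / sum(tt^2)
    X <- X - tt %*% t(pl)
    Y <- Y - tt %*% t(qv)
    W[, a] <- w
    Tm[, a] <- tt
    ssy[a] <- sum(qv^2) * sum(tt^2)
  }
  vip <- sqrt(p * as.numeric(W^2 %*% ssy) / sum(ssy))
  names(vip) <- rownames(V) %||% as.character(seq_len(p))
  selected <- names(vip)[vip >= vip_threshold]
  if (!is.null(long_ids) && !is.null(short_ids) && length(selected)) {
    fc <- fold_change_filter(x, long_ids, short_ids, cutoff = fold_cutoff)
    selected <- intersect(selected, fc$probe_id[fc$retained])
  }
  structure(list(probes = selected, vip = vip, scores = Tm, weights = W,
                 explained_y = ssy),
            class = "plsda_result")
}

#' @export
print.plsda_result <- function(x, ...) {
  cat(sprintf("plsda_result: %d components, %d probes selected (max VIP %.2f)\n",
              ncol(x$scores), length(x$probes), max(x$vip)))
  invisible(x)
}
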