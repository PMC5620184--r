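# Identification of stable qPCR reference genes from the array:
# invariance screen, absence-of-trend screen, geNorm stepwise elimination.

gene_level_matrix <- function(em) {
  keep <- nzchar(em$gene_symbols) & !em$is_control
  v <- em$values[keep, , drop = FALSE]
  sym <- em$gene_symbols[keep]
  if (anyDuplicated(sym)) {
    # one row per gene: the probe with the highest mean expression
    best <- tapply(seq_along(sym), sym, function(ix)
      ix[which.max(rowMeans(v[ix, , drop = FALSE]))])
    v <- v[as.integer(best), , drop = FALSE]
    sym <- names(best)
  }
  rownames(v) <- sym
  v
}

#' Invariance screen for reference-gene candidates
#'
#' Keeps genes whose log2 expression is near-constant across samples
#' (coefficient of variation of the log2 values below `cv_max`,
#' interpreting the "SD below 5%" convention as a unitless CV) while
#' sitting reasonably above the background expression level, so that
#' non-expressed genes cannot masquerade as stable.
#'
#' @param em a log2-scale `ExpressionMatrix` (PBMC samples).
#' @param cv_max CV threshold (default 0.05), must be positive.
#' @param background_level minimum mean log2 expression; defaults to the
#'   matrix-wide median.
#' @return data.frame of candidate genes with mean, SD and CV, sorted by
#'   CV.
#' @export
invariance_screen <- function(em, cv_max = 0.05, background_level = NULL) {
  if (cv_max <= 0) stop("cv_max must be positive")
  if (em$scale != "log2") stop("invariance_screen expects a log2-scale matrix")
  v <- gene_level_matrix(em)
  background_level <- background_level %||% stats::median(v)
  mu <- rowMeans(v)
  sd_ <- apply(v, 1L, stats::sd)
  cv <- ifelse(mu > 0, sd_ / mu, Inf)
  keep <- cv < cv_max & mu > background_level
  out <- data.frame(gene = rownames(v), mean = mu, sd = sd_, cv = cv,
                    row.names = NULL)[keep, , drop = FALSE]
  out[order(out$cv, out$gene), , drop = FALSE]
}

#' Trend-absence screen between long and short survivors
#'
#' For every candidate gene computes four diagnostics of a long/short
#' survivor trend: two-sided Welch t-test and Mann-Whitney p-values, the
#' slope of expression regressed on the group indicator (the difference
#' of group means), and the overlap fraction (share of each group's
#' values lying inside the other group's range). Genes with a small
#' p-value on either test are excluded; survivors are ranked by a
#' composite of larger minimum p, smaller absolute slope and larger
#' overlap (mean of the three ranks, ties broken alphabetically).
#'
#' @param em log2 `ExpressionMatrix`.
#' @param short_ids,long_ids sample IDs of the two survivor groups (each
#'   with at least 2 samples).
#' @param p_min minimum p-value both tests must exceed (absence of trend
#'   wants non-small p).
#' @param genes optional subset of gene symbols to screen.
#' @return data.frame with diagnostics, a `kept` flag and composite rank,
#'   sorted best-first.
#' @export
trend_screen <- function(em, short_ids, long_ids, p_min = 0.3, genes = NULL) {
  v <- gene_level_matrix(em)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(v))
    if (length(miss)) stop("unknown gene: ", miss[1L])
    v <- v[genes, , drop = FALSE]
  }
  if (length(short_ids) < 2L || length(long_ids) < 2L)
    stop("both survivor groups need at least 2 samples")
  xs <- v[, short_ids, drop = FALSE]
  xl <- v[, long_ids, drop = FALSE]
  stats_one <- function(i) {
    a <- xs[i, ]; b <- xl[i, ]
    p_t <- if (stats::sd(a) == 0 && stats::sd(b) == 0) 1
           else tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    p_mw <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE)$p.value)
    slope <- mean(b) - mean(a)
    ov <- (sum(a >= min(b) & a <= max(b)) + sum(b >= min(a) & b <= max(a))) /
      (length(a) + length(b))
    c(p_t = p_t, p_mw = p_mw, slope = slope, overlap = ov)
  }
  res <- t(vapply(seq_len(nrow(v)), stats_one, numeric(4L)))
  out <- data.frame(gene = rownames(v), res, row.names = NULL)
  out$min_p <- pmin(out$p_t, out$p_mw)
  out$kept <- out$p_t > p_min & out$p_mw > p_min
  comp <- rank(-out$min_p, ties.method = "average") +
    rank(abs(out$slope), ties.method = "average") +
    rank(-out$overlap, ties.method = "average")
  out$composite_rank <- comp / 3
  out[order(!out$kept, out$composite_rank, out$gene), , drop = FALSE]
}

genorm_m_values <- function(v) {
  # v: genes x samples log2; M_j = mean over k != j of SD(x_j - x_k)
  g <- nrow(v)
  sds <- matrix(0, g, g)
  for (j in seq_len(g - 1L)) for (k in (j + 1L):g) {
    sds[j, k] <- sds[k, j] <- stats::sd(v[j, ] - v[k, ])
  }
  stats::setNames(rowSums(sds) / (g - 1L), rownames(v))
}

#' geNorm stability ranking by stepwise elimination
#'
#' For each candidate gene j the stability measure M_j is the mean, over
#' all other candidates k, of the standard deviation across samples of
#' the log2 expression ratio between j and k. The gene with the largest M
#' is removed, M values are recomputed, and elimination proceeds until
#' two genes remain (ties broken by removing the alphabetically later
#' gene). Pairwise-variation values V(n/n+1) between successive
#' normalization factors are reported alongside.
#'
#' @param em log2 `ExpressionMatrix`, or a bare genes x samples log2
#'   matrix, restricted to at least 3 candidate genes.
#' @param genes optional candidate gene subset.
#' @return A `StabilityRanking`: per-round M values, elimination order,
#'   the final pair, and the V(n/n+1) series.
#' @export
genorm_rank <- function(em, genes = NULL) {
  v <- if (inherits(em, "ExpressionMatrix")) gene_level_matrix(em) else em
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(v))
    if (length(miss)) stop("unknown gene: ", miss[1L])
    v <- v[genes, , drop = FALSE]
  }
  if (nrow(v) < 3L) stop("geNorm needs at least 3 candidate genes")
  rounds <- list()
  eliminated <- character(0)
  nf <- list()  # per-round normalization factor (mean log2 of remaining genes)
  cur <- v
  while (nrow(cur) >= 2L) {
    M <- genorm_m_values(cur)
    rounds[[length(rounds) + 1L]] <- M
    nf[[length(nf) + 1L]] <- colMeans(cur)
    if (nrow(cur) == 2L) break
    worst <- names(M)[M == max(M)]
    worst <- sort(worst, decreasing = TRUE)[1L]   # tie: drop later name
    eliminated <- c(eliminated, worst)
    cur <- cur[setdiff(rownames(cur), worst), , drop = FALSE]
  }
  # V(n/n+1): SD of the difference of successive normalization factors,
  # indexed by the larger candidate count n+1 -> n
  v_series <- if (length(nf) >= 2L)
    vapply(seq_len(length(nf) - 1L),
           function(i) stats::sd(nf[[i]] - nf[[i + 1L]]), 0)
  else numeric(0)
  structure(list(m_rounds = rounds,
                 elimination_order = eliminated,
                 final_pair = sort(rownames(cur)),
                 v_pairwise = v_series,
                 candidates = rownames(v)),
            class = "StabilityRanking")
}

#' @export
print.StabilityRanking <- function(x, ...) {
  cat(sprintf("StabilityRanking: %d candidates -> final pair %s (eliminated: %s)\n",
              length(x$candidates), paste(x$final_pair, collapse = " + "),
              paste(x$elimination_order, collapse = ", ")))
  invisible(x)
}

#' Select a validated reference-gene pair
#'
#' Composes the three screens: invariance (CV and background), trend
#' absence between short and long survivors, and geNorm stepwise
#' elimination down to the final pair. The returned report carries the
#' full audit trail with per-stage survivor counts.
#'
#' @param em log2 `ExpressionMatrix` over PBMC samples.
#' @param short_ids,long_ids survivor groups for the trend screen.
#' @param cv_max,background_level invariance-screen settings.
#' @param p_min trend-screen minimum p.
#' @param max_candidates cap on genes entering geNorm (most invariant
#'   first), keeping the pairwise stage tractable.
#' @return A list: `pair` (two gene symbols), `ranking`
#'   (`StabilityRanking`), `audit` (stage survivor counts), plus the two
#'   screen tables.
#' @export
select_reference_pair <- function(em, short_ids, long_ids,
                                  cv_max = 0.05, background_level = NULL,
                                  p_min = 0.3, max_candidates = 20L) {
  inv <- invariance_screen(em, cv_max = cv_max,
                           background_level = background_level)
  if (nrow(inv) < 3L)
    stop("fewer than 3 genes pass the invariance screen; relax cv_max or background_level")
  tr <- trend_screen(em, short_ids, long_ids, p_min = p_min, genes = inv$gene)
  cand <- tr$gene[tr$kept]
  if (length(cand) < 3L)
    stop("fewer than 3 genes pass the trend screen; relax p_min")
  cand <- utils::head(tr$gene[tr$kept], max_candidates)
  rk <- genorm_rank(em, genes = sort(cand))
  list(pair = rk$final_pair,
       ranking = rk,
       audit = data.frame(stage = c("invariance", "trend", "genorm_final"),
                          survivors = c(nrow(inv), length(cand), 2L)),
       invariance = inv, trend = tr)
}
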