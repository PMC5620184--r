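# Anchor-gene co-expression ranking and preranked gene-set enrichment
# against blood transcriptional module collections.

#' Rank all genes by Pearson correlation to an anchor gene
#'
#' Correlates every other probe with the anchor gene's expression,
#' collapses probes to gene symbols by the largest absolute correlation,
#' and returns the list sorted by decreasing r — the input ranking for
#' preranked enrichment.
#'
#' @param em log2 `ExpressionMatrix` with at least 4 samples.
#' @param anchor_gene anchor gene symbol (non-constant).
#' @return data.frame (gene, r) sorted by decreasing r.
#' @export
correlate_to_anchor <- function(em, anchor_gene) {
  if (ncol(em$values) < 4L) stop("need at least 4 samples")
  anchor <- gene_values(em, anchor_gene)
  if (stats::sd(anchor) == 0) stop("anchor gene has zero variance")
  keep <- !em$is_control & nzchar(em$gene_symbols) &
    em$gene_symbols != anchor_gene
  v <- em$values[keep, , drop = FALSE]
  sds <- apply(v, 1L, stats::sd)
  v <- v[sds > 0, , drop = FALSE]
  r <- as.numeric(stats::cor(t(v), anchor))
  sym <- em$gene_symbols[keep][sds > 0]
  best <- tapply(seq_along(r), sym, function(ix) ix[which.max(abs(r[ix]))])
  out <- data.frame(gene = names(best), r = r[as.integer(best)],
                    row.names = NULL)
  out[order(-out$r, out$gene), , drop = FALSE]
}

gsea_es <- function(scores, hit) {
  # scores: ranked (descending) weights; hit: logical membership
  nh <- sum(hit)
  w <- abs(scores)
  denom_hit <- sum(w[hit])
  inc <- ifelse(hit,
                if (denom_hit > 0) w / denom_hit else 1 / nh,
                -1 / (length(scores) - nh))
  rs <- cumsum(inc)
  i <- which.max(abs(rs))
  rs[i]
}

#' Preranked gene-set enrichment analysis
#'
#' Classic running-sum enrichment on a ranked gene list: hits advance the
#' sum proportionally to |score|^`weight_p`, misses retreat uniformly,
#' and the enrichment score (ES) is the maximum deviation from zero. A
#' gene-permutation null (random sets of the same size) yields the
#' normalized score NES = ES / mean(|same-sign permuted ES|) and an FDR q
#' from the pooled permuted NES distribution, computed separately for
#' positive and negative scores. Sets smaller than `min_size` (after
#' restriction to genes present in the list) are dropped.
#'
#' @param ranked data.frame with columns `gene` and `r` (or `score`),
#'   already sorted by decreasing score, e.g. from
#'   [correlate_to_anchor()].
#' @param gene_sets named list of gene symbol vectors (e.g. [read_gmt()]).
#' @param min_size minimum post-filter set size (default 10).
#' @param weight_p hit-increment weighting exponent (default 1).
#' @param n_perm gene permutations for the null.
#' @param seed RNG seed.
#' @return An `EnrichmentResult`: data.frame (set, size, es, nes, q,
#'   leading_edge) or an empty table when no set passes the size filter.
#' @export
gsea_preranked <- function(ranked, gene_sets, min_size = 10L, weight_p = 1,
                           n_perm = 1000L, seed = 1L) {
  score_col <- if ("score" %in% names(ranked)) "score" else "r"
  genes <- as.character(ranked$gene)
  scores <- sign(ranked[[score_col]]) * abs(ranked[[score_col]])^weight_p
  ord <- order(ranked[[score_col]], decreasing = TRUE)
  genes <- genes[ord]; scores <- scores[ord]
  set.seed(seed)
  members <- lapply(gene_sets, function(s) which(genes %in% s))
  sizes <- lengths(members)
  keep <- sizes >= min_size
  empty <- data.frame(set = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), q = numeric(0),
                      leading_edge = character(0))
  if (!any(keep)) {
    message("no gene set reaches min_size = ", min_size)
    return(structure(list(table = empty, n_perm = n_perm),
                     class = "EnrichmentResult"))
  }
  members <- members[keep]
  n <- length(genes)
  es_one <- function(idx) {
    hit <- logical(n); hit[idx] <- TRUE
    gsea_es(scores, hit)
  }
  es <- vapply(members, es_one, 0)
  # permutation null per distinct set size
  null_by_size <- lapply(unique(lengths(members)), function(m) {
    vapply(seq_len(n_perm), function(b) es_one(sample.int(n, m)), 0)
  })
  names(null_by_size) <- as.character(unique(lengths(members)))
  nes <- numeric(length(es))
  perm_nes <- vector("list", length(es))
  for (i in seq_along(es)) {
    nul <- null_by_size[[as.character(length(members[[i]]))]]
    pos_mean <- mean(nul[nul >= 0]); neg_mean <- mean(abs(nul[nul < 0]))
    nes[i] <- if (es[i] >= 0) es[i] / pos_mean else es[i] / neg_mean
    perm_nes[[i]] <- ifelse(nul >= 0, nul / pos_mean, nul / neg_mean)
  }
  pooled <- unlist(perm_nes)
  q <- vapply(seq_along(nes), function(i) {
    if (nes[i] >= 0) {
      num <- mean(pooled[pooled >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(pooled[pooled < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    min(1, num / max(den, .Machine$double.eps))
  }, 0)
  leading <- vapply(seq_along(members), function(i) {
    idx <- members[[i]]
    hit <- logical(n); hit[idx] <- TRUE
    w <- abs(scores); dh <- sum(w[hit])
    inc <- ifelse(hit, if (dh > 0) w / dh else 1 / sum(hit), -1 / (n - sum(hit)))
    rs <- cumsum(inc)
    peak <- which.max(abs(rs))
    le <- if (rs[peak] >= 0) idx[idx <= peak] else idx[idx > peak]
    paste(genes[sort(le)], collapse = ",")
  }, "")
  tab <- data.frame(set = names(members), size = lengths(members),
                    es = es, nes = nes, q = q, leading_edge = leading,
                    row.names = NULL)
  structure(list(table = tab[order(-abs(tab$nes)), , drop = FALSE],
                 n_perm = n_perm),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: %d sets (%d permutations)\n",
              nrow(x$table), x$n_perm))
  if (nrow(x$table))
    print(utils::head(x$table[, c("set", "size", "es", "nes", "q")], 10L))
  invisible(x)
}

#' Split enrichment results into positive and negative tails
#'
#' Sets are split by the sign of their normalized enrichment score,
#' sorted by decreasing |NES| within each tail, and filtered at the given
#' FDR q threshold — the two-column layout used when reporting modules
#' co-varying versus anti-varying with the anchor gene.
#'
#' @param result an `EnrichmentResult`.
#' @param q_max FDR threshold (default 0.05).
#' @return A list with `positive` and `negative` data.frames (possibly
#'   empty).
#' @export
two_direction_report <- function(result, q_max = 0.05) {
  tab <- result$table
  pos <- tab[tab$nes >= 0 & tab$q <= q_max, , drop = FALSE]
  neg <- tab[tab$nes < 0 & tab$q <= q_max, , drop = FALSE]
  list(positive = pos[order(-abs(pos$nes)), , drop = FALSE],
       negative = neg[order(-abs(neg$nes)), , drop = FALSE])
}
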