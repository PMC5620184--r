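# Delta-Ct relative quantification and the microarray/qPCR validation
# logic: Pearson cross-platform check, then survival Spearman selection
# with multiple-testing correction.

#' Log2 relative expression by the delta-Ct method
#'
#' Replicate wells are averaged per sample and gene (missing wells are
#' dropped from the mean; replicate SDs above 0.5 cycles are flagged),
#' then each sample's log2 relative expression of the target is the mean
#' reference Ct minus the target Ct. Averaging reference Cts is the
#' arithmetic-mean (log scale) equivalent of normalizing to the geometric
#' mean of the reference genes' linear expression, so the result is
#' invariant to adding a constant to all Cts of a sample.
#'
#' @param ct a `CtTable`.
#' @param target target gene symbol.
#' @param refs character vector of reference gene symbols (typically the
#'   validated pair).
#' @return Named numeric vector of log2 relative expression per sample
#'   (samples missing the target or any reference are omitted with a
#'   warning). Noisy replicates are listed in attribute
#'   `"flagged_replicates"`.
#' @export
relative_expression <- function(ct, target, refs) {
  stopifnot(inherits(ct, "CtTable"))
  genes <- c(target, refs)
  sub <- ct[ct$gene %in% genes & !is.na(ct$ct), , drop = FALSE]
  if (!nrow(sub)) stop("no measured wells for ", target, " / references")
  agg <- stats::aggregate(ct ~ sample_id + gene, data = sub, FUN = mean)
  sds <- stats::aggregate(ct ~ sample_id + gene, data = sub,
                          FUN = function(x) if (length(x) > 1L) stats::sd(x) else 0)
  flagged <- sds[sds$ct > 0.5, c("sample_id", "gene"), drop = FALSE]
  wide <- stats::reshape(agg, idvar = "sample_id", timevar = "gene",
                         direction = "wide")
  names(wide) <- sub("^ct\\.", "", names(wide))
  have <- genes[genes %in% names(wide)]
  miss_gene <- setdiff(genes, have)
  if (length(miss_gene)) stop("gene not measured in Ct table: ", miss_gene[1L])
  complete <- stats::complete.cases(wide[, genes, drop = FALSE])
  if (any(!complete))
    warning("omitting ", sum(!complete),
            " sample(s) with missing target or reference wells: ",
            paste(utils::head(wide$sample_id[!complete], 5L), collapse = ", "))
  wide <- wide[complete, , drop = FALSE]
  ref_mean <- rowMeans(wide[, refs, drop = FALSE])
  out <- stats::setNames(ref_mean - wide[[target]], wide$sample_id)
  attr(out, "flagged_replicates") <- flagged
  out
}

#' Cross-platform validation of a gene: microarray versus qPCR
#'
#' One-tailed Pearson test that the microarray and qPCR measurements of
#' the same samples correlate positively; the gene passes when `r > 0`
#' with `p < alpha`.
#'
#' @param ma_values,qpcr_values paired numeric vectors (n >= 4), same
#'   sample order.
#' @param alpha significance level.
#' @return A list: `r`, `p` (one-tailed, r > 0), `pass`, and `reason`
#'   when the test is undefined (zero variance).
#' @export
validate_ma_qpcr <- function(ma_values, qpcr_values, alpha = 0.05) {
  if (length(ma_values) != length(qpcr_values))
    stop("paired vectors must have equal length")
  if (length(ma_values) < 4L) stop("need at least 4 paired samples")
  if (stats::sd(ma_values) == 0 || stats::sd(qpcr_values) == 0)
    return(list(r = NA_real_, p = NA_real_, pass = FALSE,
                reason = "zero variance"))
  ht <- stats::cor.test(ma_values, qpcr_values, method = "pearson",
                        alternative = "greater")
  list(r = unname(ht$estimate), p = ht$p.value,
       pass = ht$p.value < alpha && ht$estimate > 0, reason = NULL)
}

#' Survival-correlation selection among qPCR-validated genes
#'
#' Adjusts the per-gene one-tailed Spearman survival p-values across the
#' qPCR-validated genes (Benjamini-Hochberg by default) and flags genes
#' with adjusted p below alpha as survival-selected. Selection is
#' monotone in alpha. The sign of rho records the direction (expression
#' rising or falling with survival).
#'
#' @param records data.frame with columns `gene`, `rho`, `p` (one-tailed
#'   Spearman p versus survival months); only qPCR-validated genes should
#'   enter.
#' @param alpha significance level on the adjusted p.
#' @param method multiple-testing correction passed to
#'   [stats::p.adjust()] (default `"BH"`, `"bonferroni"` available).
#' @return The data.frame with `p_adjusted`, `survival_selected` and
#'   `direction` columns (empty input gives an empty result).
#' @export
survival_correlation_select <- function(records, alpha = 0.05, method = "BH") {
  if (!nrow(records)) {
    records$p_adjusted <- numeric(0)
    records$survival_selected <- logical(0)
    records$direction <- character(0)
    return(records)
  }
  stopifnot(all(c("gene", "rho", "p") %in% names(records)))
  records$p_adjusted <- stats::p.adjust(records$p, method = method)
  records$survival_selected <- !is.na(records$p_adjusted) &
    records$p_adjusted < alpha
  records$direction <- ifelse(records$rho >= 0, "positive", "negative")
  records
}

#' Build the full qPCR validation table for a candidate panel
#'
#' For each candidate gene: averages replicate Cts, computes delta-Ct
#' relative expression against the reference pair, tests the one-tailed
#' Pearson correlation with the matching microarray values, and, among
#' genes passing that cross-platform check, tests the one-tailed Spearman
#' correlation of qPCR expression with survival months (in the direction
#' of the observed sign) with multiple-testing correction.
#'
#' @param em log2 `ExpressionMatrix` providing the microarray values.
#' @param ct a `CtTable` covering the candidate and reference genes.
#' @param samples a `SampleTable`; survival months are joined by sample
#'   ID.
#' @param genes candidate gene symbols.
#' @param refs reference gene pair.
#' @param alpha significance level for both tests.
#' @param method multiple-testing correction method.
#' @return data.frame shaped like a validation table: gene, Pearson
#'   r / p / qPCR-validated flag, Spearman rho / p / adjusted p /
#'   survival-selected flag and direction.
#' @export
build_validation_table <- function(em, ct, samples, genes, refs,
                                   alpha = 0.05, method = "BH") {
  rows <- lapply(genes, function(g) {
    rel <- relative_expression(ct, g, refs)
    ids <- intersect(names(rel), colnames(em$values))
    ma <- gene_values(em, g)[ids]
    vv <- validate_ma_qpcr(ma, rel[ids], alpha = alpha)
    months <- samples$survival_months[match(ids, samples$sample_id)]
    rho <- p_s <- NA_real_
    if (stats::sd(rel[ids]) > 0 && stats::sd(months) > 0) {
      est <- suppressWarnings(stats::cor(rel[ids], months, method = "spearman"))
      alt <- if (est >= 0) "greater" else "less"
      ht <- suppressWarnings(stats::cor.test(rel[ids], months,
                                             method = "spearman",
                                             alternative = alt))
      rho <- unname(ht$estimate); p_s <- ht$p.value
    }
    data.frame(gene = g, pearson_r = vv$r, pearson_p = vv$p,
               qpcr_validated = vv$pass, rho = rho, p = p_s)
  })
  tab <- do.call(rbind, rows)
  sel <- survival_correlation_select(
    tab[tab$qpcr_validated & !is.na(tab$p), , drop = FALSE],
    alpha = alpha, method = method)
  tab$p_adjusted <- sel$p_adjusted[match(tab$gene, sel$gene)]
  tab$survival_selected <- tab$gene %in% sel$gene[sel$survival_selected]
  tab$direction <- ifelse(is.na(tab$rho), NA_character_,
                          ifelse(tab$rho >= 0, "positive", "negative"))
  tab
}
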