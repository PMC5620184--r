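# Three-arm candidate discovery: survival SAM, PLS-DA, two-pass SAM,
# each fold-change filtered, intersected at the gene level.

#' Two-pass SAM selection: vaccination signature, then survival contrast
#'
#' Pass 1 runs a paired two-class SAM of PBMC versus matched mature DC
#' samples and keeps probes called at 90th-percentile FDR zero (the
#' "vaccination signature"). Pass 2 re-tests only those probes with an
#' unpaired two-class SAM of long versus short survivors on the PBMC
#' samples, with the same calling rule, and finally applies the
#' fold-change filter. An empty pass-1 set short-circuits to an empty
#' result.
#'
#' @param pbmc,dc log2 `ExpressionMatrix` objects sharing probe IDs.
#' @param pairing named character vector mapping DC sample IDs to their
#'   patient's PBMC sample IDs (complete for pass 1).
#' @param classes factor of survival classes named by PBMC sample ID
#'   (levels including short and long; see [survival_class()]).
#' @param n_perm,seed permutation settings passed to [sam_two_class()].
#' @param fold_cutoff fold-change cutoff for the final filter.
#' @return Character vector of retained probe IDs, with pass details in
#'   attribute `"detail"`.
#' @export
two_pass_select <- function(pbmc, dc, pairing, classes,
                            n_perm = 1000L, seed = 1L, fold_cutoff = 2) {
  dc_ids <- names(pairing)
  pbmc_ids <- unname(pairing)
  if (!all(dc_ids %in% colnames(dc$values)) ||
      !all(pbmc_ids %in% colnames(pbmc$values)))
    stop("pairing refers to unknown sample IDs")
  comb <- cbind(pbmc$values[, pbmc_ids, drop = FALSE],
                dc$values[, dc_ids, drop = FALSE])
  colnames(comb) <- make.unique(colnames(comb))
  labels <- factor(rep(c("PBMC", "DC"), each = length(dc_ids)),
                   levels = c("PBMC", "DC"))
  pair_vec <- rep(pbmc_ids, 2L)
  pass1 <- sam_two_class(comb, labels, paired = TRUE, pairing = pair_vec,
                         n_perm = n_perm, seed = seed)
  probes1 <- call_at_percentile_fdr_zero(pass1)
  detail <- list(pass1 = pass1, probes1 = as.character(probes1))
  if (!length(probes1)) {
    out <- character(0)
    attr(out, "detail") <- detail
    return(out)
  }
  short_ids <- names(classes)[which(classes == "short")]
  long_ids <- names(classes)[which(classes == "long")]
  if (!length(short_ids) || !length(long_ids))
    stop("need non-empty short and long classes for pass 2")
  sub <- em_subset(pbmc, probes = as.character(probes1),
                   samples = c(short_ids, long_ids))
  labels2 <- factor(c(rep("short", length(short_ids)),
                      rep("long", length(long_ids))),
                    levels = c("short", "long"))
  pass2 <- sam_two_class(sub, labels2, n_perm = n_perm, seed = seed + 1L)
  probes2 <- call_at_percentile_fdr_zero(pass2)
  detail$pass2 <- pass2
  detail$probes2 <- as.character(probes2)
  out <- character(0)
  if (length(probes2)) {
    fc <- fold_change_filter(em_subset(pbmc, probes = as.character(probes2)),
                             long_ids, short_ids, cutoff = fold_cutoff)
    out <- fc$probe_id[fc$retained]
  }
  attr(out, "detail") <- detail
  out
}

collapse_to_genes <- function(probes, probe_to_gene) {
  g <- unname(probe_to_gene[probes])
  sort(unique(g[!is.na(g) & nzchar(g)]))
}

#' Intersect the three discovery arms into a candidate panel
#'
#' Arm probe lists are collapsed to gene symbols (probes without a symbol
#' are dropped from the join) and intersected; only candidates emerging
#' from all three arms are retained. Per-arm provenance is kept.
#'
#' @param arm_survival,arm_plsda,arm_twopass character vectors of probe
#'   IDs selected by each arm.
#' @param probe_to_gene named character vector mapping probe IDs to gene
#'   symbols.
#' @return A `CandidatePanel`: `genes` (the intersection), `arms`
#'   (per-arm gene lists) and `provenance` (gene x arm membership table).
#' @export
intersect_candidates <- function(arm_survival, arm_plsda, arm_twopass,
                                 probe_to_gene) {
  arms <- list(survival = collapse_to_genes(arm_survival, probe_to_gene),
               plsda = collapse_to_genes(arm_plsda, probe_to_gene),
               twopass = collapse_to_genes(arm_twopass, probe_to_gene))
  genes <- Reduce(intersect, arms)
  all_genes <- sort(unique(unlist(arms)))
  prov <- data.frame(gene = all_genes,
                     survival = all_genes %in% arms$survival,
                     plsda = all_genes %in% arms$plsda,
                     twopass = all_genes %in% arms$twopass,
                     in_panel = all_genes %in% genes,
                     row.names = NULL)
  structure(list(genes = genes, arms = arms, provenance = prov),
            class = "CandidatePanel")
}

#' @export
print.CandidatePanel <- function(x, ...) {
  cat(sprintf("CandidatePanel: %d genes (arms: survival %d, plsda %d, twopass %d)\n",
              length(x$genes), length(x$arms$survival),
              length(x$arms$plsda), length(x$arms$twopass)))
  if (length(x$genes)) cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full three-arm candidate discovery
#'
#' Convenience wrapper over the three arms on a preprocessed cohort:
#' survival SAM called at 90th-percentile FDR zero plus fold-change
#' filter; PLS-DA VIP selection (three survival classes) plus fold-change
#' filter; and the two-pass PBMC-vs-DC then long-vs-short SAM. Control
#' probes are excluded. The arms are intersected at the gene level.
#'
#' @param pbmc,dc log2 `ExpressionMatrix` objects (DC optional: when
#'   `NULL` the two-pass arm is skipped and the intersection uses the
#'   remaining arms).
#' @param samples a `SampleTable` covering the matrix samples.
#' @param n_perm,seed permutation settings.
#' @param fold_cutoff fold-change cutoff shared by all arms.
#' @param vip_threshold,n_components PLS-DA settings.
#' @return A list: `panel` (`CandidatePanel`), per-arm probe vectors and
#'   the fitted `SamResult`s.
#' @export
discover_candidates <- function(pbmc, dc, samples, n_perm = 1000L, seed = 1L,
                                fold_cutoff = 2, vip_threshold = 1,
                                n_components = 2L) {
  st <- samples[samples$material == "PBMC" &
                  samples$sample_id %in% colnames(pbmc$values), , drop = FALSE]
  pb <- em_subset(pbmc, probes = !pbmc$is_control, samples = st$sample_id)
  classes <- survival_class(st$survival_months)
  names(classes) <- st$sample_id
  # a patient censored before 12 months has an unknown class (the follow-up
  # ended early); such samples are excluded from the class contrasts, the
  # same convention the ROC stage applies to censored-before-window patients
  classes[classes == "short" & !st$event] <- NA
  short_ids <- names(classes)[which(classes == "short")]
  long_ids <- names(classes)[which(classes == "long")]

  sam_surv <- sam_survival(pb, st$survival_months, st$event,
                           n_perm = n_perm, seed = seed)
  called <- as.character(call_at_percentile_fdr_zero(sam_surv))
  arm_survival <- character(0)
  if (length(called)) {
    fc <- fold_change_filter(em_subset(pb, probes = called),
                             long_ids, short_ids, cutoff = fold_cutoff)
    arm_survival <- fc$probe_id[fc$retained]
  }

  known <- names(classes)[!is.na(classes)]
  pls <- plsda_select(em_subset(pb, samples = known), classes[known],
                      n_components = n_components,
                      vip_threshold = vip_threshold,
                      long_ids = long_ids, short_ids = short_ids,
                      fold_cutoff = fold_cutoff)
  arm_plsda <- pls$probes

  arm_twopass <- NULL
  if (!is.null(dc)) {
    dc_sub <- em_subset(dc, probes = !dc$is_control)
    dc_rows <- samples[samples$material == "DC" &
                         samples$sample_id %in% colnames(dc_sub$values), ,
                       drop = FALSE]
    pbmc_of <- st$sample_id[match(dc_rows$pairing_id, st$patient_id)]
    keep <- !is.na(pbmc_of)
    pairing <- stats::setNames(pbmc_of[keep], dc_rows$sample_id[keep])
    arm_twopass <- two_pass_select(pb, dc_sub, pairing, classes,
                                   n_perm = n_perm, seed = seed + 2L,
                                   fold_cutoff = fold_cutoff)
  }

  p2g <- stats::setNames(pb$gene_symbols, rownames(pb$values))
  panel <- intersect_candidates(arm_survival, arm_plsda,
                                if (is.null(arm_twopass)) arm_plsda else arm_twopass,
                                p2g)
  if (is.null(arm_twopass)) panel$arms$twopass <- NULL
  list(panel = panel,
       arm_survival = arm_survival, arm_plsda = arm_plsda,
       arm_twopass = arm_twopass,
       sam_survival = sam_surv, plsda = pls)
}
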