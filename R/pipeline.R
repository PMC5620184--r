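# End-to-end orchestration: simulate (or load) -> preprocess -> discover
# -> reference genes -> qPCR validation -> biomarker evaluation -> GSEA,
# with per-stage seeds derived from one global seed.

stage_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 10007 + index * 101) %% 2147483647)
}

config_hash <- function(txt) {
  # polynomial rolling hash, enough to stamp artifacts with their config
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Build synthetic gene modules over a cohort's gene namespace
#'
#' Constructs a gene-set collection for enrichment demos and tests: one
#' module per supplied truth block (e.g. planted survival genes,
#' myeloid-like genes) plus random modules drawn from the remaining
#' symbols.
#'
#' @param gene_symbols all gene symbols of the cohort.
#' @param truth_sets named list of gene vectors to keep as dedicated
#'   modules (may be empty).
#' @param n_random number of random filler modules.
#' @param size_range module size range for the random modules.
#' @param seed RNG seed.
#' @return A `GeneSetCollection`.
#' @export
make_synthetic_modules <- function(gene_symbols, truth_sets = list(),
                                   n_random = 8L, size_range = c(10L, 30L),
                                   seed = 1L) {
  set.seed(seed)
  pool <- setdiff(unique(gene_symbols[nzchar(gene_symbols)]),
                  unlist(truth_sets))
  sets <- truth_sets
  for (i in seq_len(n_random)) {
    m <- sample(seq(size_range[1L], size_range[2L]), 1L)
    sets[[sprintf("RANDOM%02d", i)]] <- sample(pool, min(m, length(pool)))
  }
  attr(sets, "descriptions") <- stats::setNames(
    c(rep("planted module", length(truth_sets)),
      rep("random module", n_random)), names(sets))
  class(sets) <- "GeneSetCollection"
  sets
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full biomarker pipeline from a config
#'
#' Executes the configured stages in order — `simulate` (or loading the
#' input files named in the config), `preprocess`, `discover`,
#' `refgenes`, `qpcr`, `evaluate`, `gsea` — writing every stage's tables
#' under `outdir` together with a log stamping the run with the config
#' hash and seed and recording every defaulted parameter. Each stage's
#' RNG seed is derived deterministically from the global seed, so stages
#' are individually reproducible and a rerun with the same seed yields
#' identical artifacts.
#'
#' @param config path to a YAML file or an equivalent nested list. Must
#'   contain either a `simulate` block (generator parameters) or an
#'   `inputs` block naming `pbmc`, `dc` and `samples` files. Optional
#'   blocks tune the other stages.
#' @param outdir output directory (created if missing).
#' @param seed global integer seed; overrides `config$seed`.
#' @return Invisibly, a list with the stage results and artifact paths.
#' @export
run_pipeline <- function(config, outdir = "bloodmark_run", seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config needs a `simulate` block or an `inputs` block naming pbmc, dc and samples")
  if (!is.null(cfg$inputs)) {
    need <- setdiff(c("pbmc", "samples"), names(cfg$inputs))
    if (length(need)) stop("config inputs missing: ", need[1L])
  }
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "pipeline.log")
  cfg_hash <- config_hash(yaml::as.yaml(cfg))
  logf <- function(...) {
    msg <- sprintf("[%s seed=%d] %s", cfg_hash, seed, sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  run_stage <- function(name, expr) {
    logf("stage %s: start", name)
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }
  out <- list(seed = seed, config_hash = cfg_hash, outdir = outdir)

  # -- inputs ---------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- run_stage("simulate", {
      sc <- do.call(simulation_config,
                    c(cfg$simulate, list(seed = stage_seed(seed, 1L))))
      simulate_cohort(sc)
    })
    write_expression_matrix(sim$pbmc, file.path(outdir, "pbmc_raw.tsv"))
    if (!is.null(sim$dc))
      write_expression_matrix(sim$dc, file.path(outdir, "dc_raw.tsv"))
    write_sample_table(sim$samples, file.path(outdir, "samples.tsv"))
    pbmc_raw <- sim$pbmc; dc_raw <- sim$dc; samples <- sim$samples
    truth <- sim$truth
  } else {
    pbmc_raw <- run_stage("load", read_expression_matrix(cfg$inputs$pbmc))
    dc_raw <- if (!is.null(cfg$inputs$dc))
      read_expression_matrix(cfg$inputs$dc) else NULL
    samples <- read_sample_table(cfg$inputs$samples)
    truth <- NULL
  }

  # -- preprocess -----------------------------------------------------
  pp <- cfg$preprocess %||% list()
  logf("preprocess defaults: quantile=%s detection=%s correlation=%s",
       pp$quantile %||% 0.05, pp$min_detection %||% 0.5,
       pp$min_correlation %||% 0.8)
  pre <- run_stage("preprocess", {
    pb <- preprocess(pbmc_raw, q = pp$quantile %||% 0.05,
                     min_detection_fraction = pp$min_detection %||% 0.5,
                     min_median_correlation = pp$min_correlation %||% 0.8)
    dc <- if (!is.null(dc_raw))
      preprocess(dc_raw, q = pp$quantile %||% 0.05,
                 min_detection_fraction = pp$min_detection %||% 0.5,
                 min_median_correlation = pp$min_correlation %||% 0.8)
    list(pbmc = pb, dc = dc)
  })
  write_tsv(pre$pbmc$qc, file.path(outdir, "qc_pbmc.tsv"))
  write_expression_matrix(pre$pbmc$matrix, file.path(outdir, "pbmc_log2.tsv"))
  pbmc <- pre$pbmc$matrix
  dc <- if (!is.null(pre$dc)) pre$dc$matrix else NULL

  # -- discovery ------------------------------------------------------
  dcf <- cfg$discover %||% list()
  disc <- run_stage("discover",
    discover_candidates(pbmc, dc, samples,
                        n_perm = dcf$n_perm %||% 200L,
                        seed = stage_seed(seed, 3L),
                        fold_cutoff = dcf$fold_cutoff %||% 2,
                        vip_threshold = dcf$vip_threshold %||% 1,
                        n_components = dcf$n_components %||% 2L))
  write_tsv(disc$panel$provenance, file.path(outdir, "panel.tsv"))
  out$panel <- disc$panel

  # -- reference genes ------------------------------------------------
  rg <- cfg$refgenes %||% list()
  st_pb <- samples[samples$material == "PBMC" &
                     samples$sample_id %in% colnames(pbmc$values), ]
  cls <- survival_class(st_pb$survival_months)
  refpair <- run_stage("refgenes",
    select_reference_pair(pbmc,
                          short_ids = st_pb$sample_id[cls == "short"],
                          long_ids = st_pb$sample_id[cls == "long"],
                          cv_max = rg$cv_max %||% 0.05,
                          p_min = rg$p_min %||% 0.3))
  write_tsv(refpair$trend, file.path(outdir, "refgenes_trend.tsv"))
  writeLines(refpair$pair, file.path(outdir, "reference_pair.txt"))
  out$reference_pair <- refpair$pair
  logf("reference pair: %s", paste(refpair$pair, collapse = " + "))

  # -- qPCR validation ------------------------------------------------
  qp <- cfg$qpcr %||% list()
  anchor <- cfg$evaluate$gene %||% cfg$simulate$anchor_gene %||% "PEBP1"
  qpcr_genes <- unique(c(out$panel$genes, anchor))
  qpcr_genes <- qpcr_genes[qpcr_genes %in% pbmc$gene_symbols]
  val <- run_stage("qpcr", {
    ctab <- simulate_qpcr(pbmc, qpcr_genes, refpair$pair,
                          noise_sd = qp$noise_sd %||% 0.15,
                          seed = stage_seed(seed, 5L))
    write_ct_table(ctab, file.path(outdir, "ct_table.tsv"))
    list(ct = ctab,
         table = build_validation_table(pbmc, ctab, samples, qpcr_genes,
                                        refpair$pair,
                                        alpha = qp$alpha %||% 0.05,
                                        method = qp$method %||% "BH"))
  })
  write_tsv(val$table, file.path(outdir, "validation.tsv"))
  out$validation <- val$table

  # -- biomarker evaluation -------------------------------------------
  ev <- cfg$evaluate %||% list()
  eval_res <- run_stage("evaluate", {
    rel <- relative_expression(val$ct, anchor, refpair$pair)
    evaluate_biomarker(rel, samples,
                       windows = ev$windows %||% 10:18,
                       cutoff_policy = ev$cutoff_policy %||% "youden",
                       spec_target = ev$spec_target %||% 0.89)
  })
  write_tsv(eval_res$sweep, file.path(outdir, "window_sweep.tsv"))
  write_tsv(eval_res$roc$curve, file.path(outdir, "roc_curve.tsv"))
  write_tsv(eval_res$km$curves, file.path(outdir, "km_curves.tsv"))
  write_tsv(data.frame(metric = c("spearman_rho", "spearman_p", "window",
                                  "auc", "auc_se", "cutoff", "sensitivity",
                                  "specificity", "logrank_chisq", "logrank_p"),
                       value = c(eval_res$rho, eval_res$rho_p,
                                 eval_res$window, eval_res$roc$auc,
                                 eval_res$roc$se, eval_res$cutoff,
                                 eval_res$sensitivity, eval_res$specificity,
                                 eval_res$km$chisq, eval_res$km$p)),
            file.path(outdir, "evaluation.tsv"))
  out$evaluation <- eval_res

  # -- GSEA -----------------------------------------------------------
  gs <- cfg$gsea %||% list()
  gsea_res <- run_stage("gsea", {
    mods <- if (!is.null(gs$gmt)) read_gmt(gs$gmt)
      else make_synthetic_modules(
        pbmc$gene_symbols,
        truth_sets = if (!is.null(truth) && length(truth$planted_genes) >= 2L)
          list(SURVIVAL_MODULE = truth$planted_genes) else list(),
        seed = stage_seed(seed, 6L))
    ranked <- correlate_to_anchor(pbmc, anchor)
    gsea_preranked(ranked, mods,
                   min_size = gs$min_size %||% 10L,
                   n_perm = gs$n_perm %||% 200L,
                   seed = stage_seed(seed, 7L))
  })
  write_tsv(gsea_res$table[, c("set", "size", "es", "nes", "q")],
            file.path(outdir, "gsea.tsv"))
  out$gsea <- gsea_res
  logf("pipeline complete: %d panel genes, best window %g months",
       length(out$panel$genes), eval_res$window)
  invisible(out)
}
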