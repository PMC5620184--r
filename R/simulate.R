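#' Simulation configuration for synthetic vaccination cohorts
#'
#' Bundles every knob of the cohort generator with validated defaults. The
#' defaults emulate the structure of a multi-center dendritic-cell
#' vaccination study: 74 PBMC samples with 68 patient-matched mature
#' monocyte-derived DC samples, right-skewed censored overall survival, a
#' small set of planted survival-associated genes that double as part of
#' the PBMC-vs-DC "vaccination signature", near-constant reference genes,
#' and low-level control probes.
#'
#' @param n_patients number of patients (one post-vaccination PBMC sample
#'   each).
#' @param n_dc number of patients that additionally contribute a matched
#'   mature DC sample (`<= n_patients`).
#' @param n_probes number of non-control probes.
#' @param n_controls number of control probes appended to each matrix.
#' @param n_planted number of planted survival-associated genes (positive
#'   effect: expression rises with survival).
#' @param n_planted_down optional extra block of genes with effect
#'   `-effect_size` (expression falls with survival, myeloid-like); default 0.
#' @param effect_size beta, log2 units per SD of standardized log survival.
#'   Together with `noise_sd` the default is calibrated so a planted gene's
#'   Spearman correlation with survival is about 0.46 at n = 74 while its
#'   long/short group separation is about 2.3-fold.
#' @param noise_sd residual SD (log2) of planted and DC-signature genes.
#' @param null_sd_range range of per-probe residual SDs (log2) for
#'   unplanted genes, drawn uniformly; keeps inter-sample correlations in
#'   the range seen on real arrays.
#' @param n_centers,center_offsets number of treatment centers and their
#'   additive log2 offsets (length `n_centers`); samples are assigned
#'   round-robin.
#' @param censoring_fraction expected fraction of patients whose survival
#'   is right-censored.
#' @param weibull_shape,weibull_scale survival-time distribution (months).
#' @param dc_signature_n number of genes shifted in DC samples (the planted
#'   genes are a subset, so survival candidates can also pass a
#'   PBMC-vs-DC screen).
#' @param dc_shift log2 shift of signature genes in DC samples.
#' @param n_reference,reference_cv number of near-constant reference genes
#'   and the coefficient of variation of their log2 expression.
#' @param baseline_range range of per-probe baseline log2 expression.
#' @param background_level raw-scale additive background; control probes
#'   sit at this level.
#' @param timepoints,timepoint_n,slope_short,slope_long,survival_split
#'   longitudinal design: timepoint labels, per-timepoint patient counts
#'   (monotone dropout), per-timepoint-step log2 slopes of the anchor gene
#'   in short and long survivors, and the months threshold splitting them.
#' @param longitudinal_noise_sd residual SD (log2) per patient x timepoint
#'   in the longitudinal trajectories.
#' @param ct_intercept,qpcr_noise_sd,qpcr_replicates qPCR measurement
#'   model: Ct = intercept - log2(expression) + N(0, qpcr_noise_sd), with
#'   this many replicate wells.
#' @param ml_coupling,ml_noise_sd myeloid/lymphoid balance model:
#'   M/L = exp(-coupling * standardized(anchor) + N(0, ml_noise_sd)).
#' @param anchor_gene symbol given to the first planted gene; the
#'   evaluation stages use it as the default biomarker.
#' @param seed integer RNG seed; fixed seed implies bit-identical output.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 74L,
                              n_dc = 68L,
                              n_probes = 1000L,
                              n_controls = 50L,
                              n_planted = 10L,
                              n_planted_down = 0L,
                              effect_size = 0.85,
                              noise_sd = 1.4,
                              null_sd_range = c(0.2, 0.6),
                              n_centers = 2L,
                              center_offsets = c(0, 0.8),
                              censoring_fraction = 0.15,
                              weibull_shape = 1.2,
                              weibull_scale = 18,
                              dc_signature_n = 80L,
                              dc_shift = 1.5,
                              n_reference = 5L,
                              reference_cv = 0.02,
                              baseline_range = c(5, 10),
                              background_level = 100,
                              timepoints = c("pre", "post4", "post6"),
                              timepoint_n = c(39L, 38L, 30L),
                              slope_short = -0.5,
                              slope_long = 0.5,
                              survival_split = 14,
                              longitudinal_noise_sd = 0.4,
                              ct_intercept = 30,
                              qpcr_noise_sd = 0.15,
                              qpcr_replicates = 2L,
                              ml_coupling = 0.8,
                              ml_noise_sd = 0.3,
                              anchor_gene = "PEBP1",
                              seed = 1L) {
  cfg <- as.list(environment())
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  pos <- c("n_patients", "n_probes", "n_controls", "n_centers",
           "weibull_shape", "weibull_scale", "background_level")
  for (f in pos) if (cfg[[f]] <= 0) stop(f, " must be positive")
  nonneg <- c("n_planted", "n_planted_down", "n_dc", "noise_sd",
              "n_reference", "reference_cv", "longitudinal_noise_sd",
              "qpcr_noise_sd", "ml_noise_sd")
  for (f in nonneg) if (cfg[[f]] < 0) stop(f, " must be non-negative")
  if (cfg$n_dc > cfg$n_patients) stop("n_dc must not exceed n_patients")
  if (cfg$censoring_fraction < 0 || cfg$censoring_fraction >= 1)
    stop("censoring_fraction must lie in [0, 1)")
  if (cfg$n_planted + cfg$n_planted_down + cfg$n_reference > cfg$n_probes ||
      cfg$dc_signature_n + cfg$n_planted_down + cfg$n_reference > cfg$n_probes)
    stop("planted, signature and reference genes must fit within n_probes")
  if (cfg$n_planted > cfg$dc_signature_n)
    stop("planted genes are a subset of the DC signature: n_planted <= dc_signature_n")
  if (length(cfg$center_offsets) != cfg$n_centers)
    stop("center_offsets must have length n_centers")
  if (length(cfg$timepoint_n) != length(cfg$timepoints) ||
      is.unsorted(rev(cfg$timepoint_n)))
    stop("timepoint_n must match timepoints and be non-increasing (dropout only)")
  invisible(cfg)
}

ref_symbols <- c("OXSR1", "PBGD", "EEF1A1", "GAPDH", "ACTB")

sim_probe_layout <- function(cfg) {
  p <- cfg$n_probes
  planted <- seq_len(cfg$n_planted)
  down <- seq_len(cfg$n_planted_down) + cfg$n_planted
  sig_extra <- seq_len(cfg$dc_signature_n - cfg$n_planted) +
    cfg$n_planted + cfg$n_planted_down
  refs <- seq_len(cfg$n_reference) + cfg$n_planted + cfg$n_planted_down +
    (cfg$dc_signature_n - cfg$n_planted)
  symbols <- sprintf("GENE%04d", seq_len(p))
  if (cfg$n_planted) {
    symbols[planted] <- c(cfg$anchor_gene,
                          sprintf("SURV%02d", seq_len(p)))[seq_len(cfg$n_planted)]
  }
  if (cfg$n_planted_down) symbols[down] <- sprintf("MYLD%02d", seq_along(down))
  if (length(sig_extra)) symbols[sig_extra] <- sprintf("DCSIG%03d", seq_along(sig_extra))
  if (cfg$n_reference)
    symbols[refs] <- c(ref_symbols, sprintf("HK%02d", seq_len(p)))[seq_len(cfg$n_reference)]
  list(planted = planted, down = down, signature = c(planted, sig_extra),
       refs = refs, symbols = symbols)
}

sim_survival <- function(cfg, n) {
  true_t <- stats::rweibull(n, shape = cfg$weibull_shape, scale = cfg$weibull_scale)
  censored <- stats::runif(n) < cfg$censoring_fraction
  obs <- ifelse(censored, stats::runif(n, 0.5, 1) * true_t, true_t)
  list(true = true_t, months = obs, event = !censored)
}

#' Simulate a paired PBMC / DC expression cohort
#'
#' Draws censored Weibull survival times and builds raw-scale probe
#' matrices in which each planted gene's log2 expression is
#' `baseline + beta * standardized(log survival) + center offset + noise`;
#' DC-signature genes are additionally shifted in the matched DC sample of
#' the same patient, reference genes are constant up to their stated CV,
#' and control probes sit near the raw background level. Deterministic for
#' a fixed seed.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `pbmc` and `dc` (raw-scale
#'   `ExpressionMatrix`), `samples` (a `SampleTable` covering both
#'   materials), and `truth` (planted / signature / reference probe IDs,
#'   true survival times and the standardized log-survival covariate), so
#'   recovery metrics are computable.
#' @export
simulate_cohort <- function(config) {
  cfg <- config
  validate_simulation_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_patients
  lay <- sim_probe_layout(cfg)
  surv <- sim_survival(cfg, n)
  z <- as.numeric(scale(log(surv$true)))
  if (n == 1L) z <- 0

  p <- cfg$n_probes
  baseline <- stats::runif(p, cfg$baseline_range[1L], cfg$baseline_range[2L])
  if (cfg$n_reference)
    baseline[lay$refs] <- stats::runif(cfg$n_reference, 8.5, 10)
  probe_sd <- stats::runif(p, cfg$null_sd_range[1L], cfg$null_sd_range[2L])
  probe_sd[c(lay$planted, lay$down, lay$signature)] <- cfg$noise_sd
  if (cfg$n_reference) probe_sd[lay$refs] <- cfg$reference_cv * baseline[lay$refs]

  effect <- numeric(p)
  effect[lay$planted] <- cfg$effect_size
  effect[lay$down] <- -cfg$effect_size

  centers <- c("Nijmegen", "Erlangen", "Copenhagen", "Innsbruck",
               sprintf("Center%02d", seq_len(max(0L, cfg$n_centers - 4L)) + 4L))
  center_idx <- rep_len(seq_len(cfg$n_centers), n)
  offs <- cfg$center_offsets[center_idx]

  patient_id <- sprintf("P%03d", seq_len(n))
  build_mat <- function(sample_patients, dc) {
    m <- length(sample_patients)
    L <- matrix(baseline, p, m) +
      outer(effect, z[sample_patients]) +
      matrix(offs[sample_patients], p, m, byrow = TRUE) +
      matrix(stats::rnorm(p * m, 0, probe_sd), p, m)
    if (dc) L[lay$signature, ] <- L[lay$signature, ] + cfg$dc_shift
    raw <- 2^L + cfg$background_level
    ctrl_sd <- 0.03 * cfg$background_level * (cfg$noise_sd > 0)
    ctrl <- matrix(cfg$background_level +
                     stats::rnorm(cfg$n_controls * m, 0, ctrl_sd),
                   cfg$n_controls, m)
    ctrl <- pmax(ctrl, 1)
    vals <- rbind(raw, ctrl)
    rownames(vals) <- c(sprintf("ILMN_%06d", seq_len(p)),
                        sprintf("CTRL_%04d", seq_len(cfg$n_controls)))
    colnames(vals) <- paste0(patient_id[sample_patients], if (dc) "_DC" else "_PBMC")
    expression_matrix(vals,
                      c(lay$symbols, rep("", cfg$n_controls)),
                      c(rep(FALSE, p), rep(TRUE, cfg$n_controls)),
                      scale = "raw")
  }
  pbmc <- build_mat(seq_len(n), dc = FALSE)
  dc_patients <- seq_len(cfg$n_dc)
  dc <- if (cfg$n_dc) build_mat(dc_patients, dc = TRUE) else NULL

  st <- data.frame(
    sample_id = c(colnames(pbmc$values), if (cfg$n_dc) colnames(dc$values)),
    patient_id = c(patient_id, patient_id[dc_patients][seq_len(cfg$n_dc)]),
    material = c(rep("PBMC", n), rep("DC", cfg$n_dc)),
    center = centers[c(center_idx, center_idx[dc_patients])],
    stage = "IV",
    survival_months = c(surv$months, surv$months[dc_patients]),
    event = c(surv$event, surv$event[dc_patients]),
    timepoint = "post",
    pairing_id = c(patient_id, patient_id[dc_patients]),
    stringsAsFactors = FALSE)
  samples <- sample_table(st)

  pid <- rownames(pbmc$values)
  truth <- list(planted_probes = pid[lay$planted],
                planted_genes = lay$symbols[lay$planted],
                planted_down_probes = pid[lay$down],
                planted_down_genes = lay$symbols[lay$down],
                signature_probes = pid[lay$signature],
                reference_probes = pid[lay$refs],
                reference_genes = lay$symbols[lay$refs],
                true_survival = stats::setNames(surv$true, patient_id),
                z = stats::setNames(z, patient_id))
  list(pbmc = pbmc, dc = dc, samples = samples, truth = truth)
}

#' Simulate longitudinal qPCR trajectories of the anchor gene
#'
#' Patients are sampled at successive vaccination timepoints with monotone
#' dropout. The anchor gene's log2 expression follows a group-dependent
#' linear trajectory: decreasing per timepoint step in short survivors and
#' increasing in long survivors (split at `survival_split` months of true
#' survival). Reference genes stay flat up to their CV. Expression is then
#' pushed through the Ct model `Ct = intercept - log2(expression) + noise`.
#'
#' @param config a [simulation_config()].
#' @return A list with `ct` (a `CtTable` for the anchor and reference
#'   genes), `samples` (one row per patient x timepoint), and `truth`
#'   (per-patient group, slopes and true survival).
#' @export
simulate_longitudinal <- function(config) {
  cfg <- config
  validate_simulation_config(cfg)
  set.seed(cfg$seed + 1L)
  n <- max(cfg$timepoint_n)
  tp <- cfg$timepoints
  surv <- sim_survival(cfg, n)
  grp_long <- surv$true > cfg$survival_split
  slope <- ifelse(grp_long, cfg$slope_long, cfg$slope_short)
  patient_id <- sprintf("L%03d", seq_len(n))
  base <- stats::runif(n, 6, 8)
  ref_base <- stats::runif(min(cfg$n_reference, 2L), 8.5, 10)
  ref_genes <- ref_symbols[seq_along(ref_base)]

  rows <- list()
  srows <- list()
  for (k in seq_along(tp)) {
    present <- seq_len(cfg$timepoint_n[k])   # dropout keeps a prefix
    expr <- base[present] + slope[present] * (k - 1L) +
      stats::rnorm(length(present), 0, cfg$longitudinal_noise_sd)
    sample_id <- paste0(patient_id[present], "_", tp[k])
    genes <- c(cfg$anchor_gene, ref_genes)
    for (r in seq_len(cfg$qpcr_replicates)) {
      # log2 expression, genes x patients-present; refs flat up to their CV
      lv <- rbind(expr,
                  t(vapply(ref_base, function(b)
                    b + stats::rnorm(length(present), 0, cfg$reference_cv * b),
                    numeric(length(present)))))
      ct <- cfg$ct_intercept - lv +
        matrix(stats::rnorm(length(lv), 0, cfg$qpcr_noise_sd), nrow(lv))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = rep(sample_id, each = length(genes)),
        gene = rep(genes, times = length(present)),
        ct = as.numeric(ct),   # column-major: gene-fastest within sample
        replicate = r)
    }
    srows[[k]] <- data.frame(
      sample_id = sample_id, patient_id = patient_id[present],
      material = "PBMC", center = "Copenhagen", stage = "IV",
      survival_months = surv$months[present], event = surv$event[present],
      timepoint = tp[k], pairing_id = NA_character_,
      stringsAsFactors = FALSE)
  }
  ct <- ct_table(do.call(rbind, rows))
  samples <- sample_table(do.call(rbind, srows))
  list(ct = ct, samples = samples,
       truth = list(group_long = stats::setNames(grp_long, patient_id),
                    slope = stats::setNames(slope, patient_id),
                    true_survival = stats::setNames(surv$true, patient_id)))
}

#' Simulate qPCR Ct measurements from an expression matrix
#'
#' Inverts the cycle-threshold readout: each well measures
#' `Ct = intercept - log2(expression) + N(0, noise_sd)`, so doubling a
#' sample's expression lowers its Ct by one cycle. Reference genes are
#' taken from their (near-constant) rows of the matrix like any other
#' target.
#'
#' @param em a log2-scale `ExpressionMatrix`.
#' @param target_genes,ref_genes gene symbols to assay (must be present in
#'   the matrix).
#' @param ct_intercept Ct of one unit of log2 expression.
#' @param noise_sd per-well Gaussian Ct noise (cycles).
#' @param n_replicates replicate wells per sample x gene.
#' @param seed RNG seed.
#' @return A `CtTable`.
#' @export
simulate_qpcr <- function(em, target_genes, ref_genes,
                          ct_intercept = 30, noise_sd = 0.15,
                          n_replicates = 2L, seed = 1L) {
  if (em$scale != "log2") stop("simulate_qpcr expects a log2-scale matrix")
  set.seed(seed)
  genes <- c(target_genes, ref_genes)
  vals <- vapply(genes, function(g) gene_values(em, g),
                 numeric(ncol(em$values)))
  rows <- lapply(seq_len(n_replicates), function(r) {
    data.frame(sample_id = rep(colnames(em$values), times = length(genes)),
               gene = rep(genes, each = ncol(em$values)),
               ct = ct_intercept - as.numeric(vals) +
                 stats::rnorm(length(vals), 0, noise_sd),
               replicate = r)
  })
  ct_table(do.call(rbind, rows))
}

#' Simulate a per-sample myeloid/lymphoid balance
#'
#' `M/L = exp(-coupling * standardized(anchor) + N(0, noise_sd))`: a
#' strictly positive ratio that falls when the anchor gene rises, emulating
#' a flow-cytometry myeloid/lymphocyte readout coupled to the biomarker.
#'
#' @param anchor_values named numeric vector of anchor-gene expression per
#'   sample.
#' @param coupling coupling coefficient (>= 0; 0 decouples the ratio).
#' @param noise_sd log-scale Gaussian noise SD.
#' @param seed RNG seed.
#' @return Named numeric vector of M/L ratios.
#' @export
simulate_ml_balance <- function(anchor_values, coupling = 0.8,
                                noise_sd = 0.3, seed = 1L) {
  if (coupling < 0 || noise_sd < 0) stop("coupling and noise_sd must be >= 0")
  set.seed(seed)
  z <- if (stats::sd(anchor_values) > 0)
    as.numeric(scale(anchor_values)) else rep(0, length(anchor_values))
  stats::setNames(exp(-coupling * z +
                        stats::rnorm(length(anchor_values), 0, noise_sd)),
                  names(anchor_values))
}
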