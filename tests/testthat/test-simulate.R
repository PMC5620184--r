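small_cfg <- function(...) {
  simulation_config(n_patients = 24, n_dc = 20, n_probes = 60,
                    n_controls = 10, n_planted = 4, dc_signature_n = 10,
                    n_reference = 3, ...)
}

test_that("a fixed seed reproduces the cohort bit-identically", {
  a <- simulate_cohort(small_cfg(seed = 9))
  b <- simulate_cohort(small_cfg(seed = 9))
  expect_identical(a$pbmc$values, b$pbmc$values)
  expect_identical(a$dc$values, b$dc$values)
  expect_identical(a$samples, b$samples)
  c <- simulate_cohort(small_cfg(seed = 10))
  expect_false(identical(a$pbmc$values, c$pbmc$values))
})

test_that("generated matrices satisfy the container invariants", {
  sim <- simulate_cohort(small_cfg(seed = 4))
  expect_silent(validate_expression_matrix(sim$pbmc))
  expect_silent(validate_expression_matrix(sim$dc))
  expect_s3_class(sim$samples, "SampleTable")
  expect_true(all(sim$truth$planted_probes %in% rownames(sim$pbmc$values)))
})

test_that("default configuration matches the paired-cohort dimensions", {
  cfg <- simulation_config(n_probes = 50, n_controls = 5, n_planted = 2,
                           dc_signature_n = 6, n_reference = 2, seed = 1)
  sim <- simulate_cohort(cfg)
  expect_identical(ncol(sim$pbmc$values), 74L)
  expect_identical(ncol(sim$dc$values), 68L)
  expect_identical(nrow(sim$samples), 142L)
})

test_that("zero noise makes planted expression an exact affine function of standardized log survival", {
  cfg <- simulation_config(n_patients = 20, n_dc = 0, n_probes = 30,
                           n_controls = 4, n_planted = 3, dc_signature_n = 5,
                           n_reference = 2, noise_sd = 0,
                           null_sd_range = c(0, 0), reference_cv = 0,
                           n_centers = 1L, center_offsets = 0,
                           censoring_fraction = 0, seed = 6)
  sim <- simulate_cohort(cfg)
  z <- sim$truth$z
  for (pr in sim$truth$planted_probes) {
    v <- log2(sim$pbmc$values[pr, ] - cfg$background_level)
    fit <- stats::lm(v ~ z)
    expect_lt(max(abs(stats::residuals(fit))), 1e-9)
    expect_equal(unname(stats::coef(fit)[2]), cfg$effect_size,
                 tolerance = 1e-9)
  }
})

test_that("beta = 0 leaves planted probes uncorrelated with survival", {
  frac_low <- vapply(c(11, 22, 33, 44, 55), function(s) {
    sim <- simulate_cohort(simulation_config(
      effect_size = 0, n_planted = 20, dc_signature_n = 20,
      n_patients = 74, n_dc = 0, n_probes = 60, n_controls = 10,
      n_reference = 3, seed = s))
    st <- sim$samples
    rs <- apply(sim$pbmc$values[sim$truth$planted_probes, ], 1L,
                function(v) stats::cor(log2(v - 100), st$survival_months,
                                       method = "pearson"))
    mean(abs(rs) < 0.3)
  }, 0)
  expect_gte(mean(frac_low), 0.95)
})

test_that("longitudinal defaults reproduce the timepoint sample counts", {
  lg <- simulate_longitudinal(simulation_config(seed = 3))
  counts <- table(lg$samples$timepoint)[c("pre", "post4", "post6")]
  expect_identical(as.integer(counts), c(39L, 38L, 30L))
})

test_that("zero-noise longitudinal change is exactly the slope times two steps", {
  cfg <- simulation_config(longitudinal_noise_sd = 0, qpcr_noise_sd = 0,
                           reference_cv = 0, slope_short = -0.5,
                           slope_long = 0.5, seed = 8)
  lg <- simulate_longitudinal(cfg)
  rel <- relative_expression(lg$ct, cfg$anchor_gene, c("OXSR1", "PBGD"))
  ids <- names(rel)
  df <- data.frame(patient_id = sub("_[^_]+$", "", ids),
                   timepoint = sub("^.*_", "", ids), value = as.numeric(rel))
  de <- delta_expression(df, lg$truth$true_survival, baseline = "pre")
  post6 <- de$deltas[de$deltas$timepoint == "post6", ]
  expected <- ifelse(lg$truth$group_long[post6$patient_id], 1, -1)
  expect_equal(post6$delta, unname(expected), tolerance = 1e-9)
})

test_that("longitudinal change rises with survival when slopes diverge", {
  ok <- vapply(1:8, function(s) {
    cfg <- simulation_config(seed = s)
    lg <- simulate_longitudinal(cfg)
    rel <- relative_expression(lg$ct, cfg$anchor_gene, c("OXSR1", "PBGD"))
    df <- data.frame(patient_id = sub("_[^_]+$", "", names(rel)),
                     timepoint = sub("^.*_", "", names(rel)),
                     value = as.numeric(rel))
    months <- stats::setNames(lg$samples$survival_months,
                              lg$samples$patient_id)
    months <- months[!duplicated(names(months))]
    delta_expression(df, months, baseline = "pre")$rho > 0
  }, NA)
  expect_gte(mean(ok), 7 / 8)
})

test_that("qPCR model: doubling expression lowers Ct by one cycle, noise-free", {
  em <- make_small_em(n_probes = 3, n_samples = 4, scale = "log2", seed = 2)
  em$values[1, ] <- c(5, 6, 8, 8)     # +1 log2 = doubling
  ct <- simulate_qpcr(em, target_genes = "G001", ref_genes = "G002",
                      noise_sd = 0, n_replicates = 1)
  w <- ct[ct$gene == "G001", ]
  expect_equal(w$ct[match("S02", w$sample_id)],
               w$ct[match("S01", w$sample_id)] - 1, tolerance = 1e-12)
  expect_error(simulate_qpcr(em, "NOPE", "G002"), "unknown gene: NOPE")
})

test_that("replicate Ct scatter matches the configured noise", {
  em <- make_small_em(n_probes = 10, n_samples = 50, scale = "log2", seed = 3)
  ct <- simulate_qpcr(em, target_genes = sprintf("G%03d", 1:10),
                      ref_genes = character(0), noise_sd = 0.3,
                      n_replicates = 2, seed = 99)
  wide <- stats::reshape(as.data.frame(ct), idvar = c("sample_id", "gene"),
                         timevar = "replicate", direction = "wide")
  sds <- abs(wide$ct.1 - wide$ct.2) / sqrt(2)
  expect_equal(sqrt(mean(sds^2)), 0.3, tolerance = 0.2 * 0.3)
})

test_that("myeloid/lymphoid balance is monotone in the anchor at zero noise", {
  set.seed(31)
  anchor <- stats::setNames(stats::rnorm(100, 7, 1), sprintf("s%03d", 1:100))
  ml <- simulate_ml_balance(anchor, coupling = 0.8, noise_sd = 0)
  expect_true(all(ml > 0))
  expect_equal(unname(stats::cor(anchor, ml, method = "spearman")), -1)
  # coupling 0 decouples the ratio
  frac_low <- mean(vapply(1:40, function(s) {
    ml0 <- simulate_ml_balance(anchor, coupling = 0, noise_sd = 0.3, seed = s)
    abs(stats::cor(anchor, ml0, method = "spearman")) < 0.3
  }, NA))
  expect_gte(frac_low, 0.9)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(censoring_fraction = 1), "censoring_fraction")
  expect_error(simulation_config(n_probes = 0), "must be positive")
  expect_error(simulation_config(n_planted = 30, dc_signature_n = 20),
               "subset")
  expect_error(simulation_config(n_probes = 10, n_planted = 8,
                                 dc_signature_n = 8, n_reference = 5),
               "fit within")
})
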