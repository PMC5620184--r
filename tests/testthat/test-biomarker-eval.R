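test_that("center normalization zeroes every center's median exactly", {
  set.seed(81)
  v <- stats::rnorm(40, 5, 2)
  centers <- sample(c("Nijmegen", "Copenhagen", "Erlangen"), 40, replace = TRUE)
  out <- center_normalize(v, centers)
  for (cc in unique(centers))
    expect_lt(abs(stats::median(out[centers == cc])), 1e-12)
  # single center: output median exactly 0
  out1 <- center_normalize(v, rep("X", 40))
  expect_lt(abs(stats::median(out1)), 1e-12)
  expect_warning(center_normalize(1:4, c("a", "a", "a", "b")), "fewer than 3")
})

test_that("removing a planted center offset restores the pooled correlation", {
  set.seed(82)
  n <- 200
  months <- stats::rweibull(n, 1.2, 18)
  expr <- 0.6 * as.numeric(scale(log(months))) + stats::rnorm(n, 0, 1)
  r_single <- stats::cor(expr, months, method = "spearman")
  centers <- rep(c("A", "B"), each = n / 2)
  shifted <- expr + ifelse(centers == "B", 5, 0)
  r_norm <- stats::cor(center_normalize(shifted, centers), months,
                       method = "spearman")
  expect_lt(abs(r_norm - r_single), 0.02)
})

test_that("ROC separates classes by the stated conventions", {
  # perfect separation: low expression in all observed short survivors
  vals <- c(1, 2, 3, 10, 11, 12, 13)
  months <- c(5, 8, 10, 30, 40, 20, 25)
  ev <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)
  roc <- roc_short_survivor(vals, months, ev, window_months = 14)
  expect_equal(roc$auc, 1)
  # censored before the window are excluded from both classes
  months2 <- c(months, 6); ev2 <- c(ev, FALSE); vals2 <- c(vals, 5)
  roc2 <- roc_short_survivor(vals2, months2, ev2, window_months = 14)
  expect_identical(roc2$n_excluded, 1L)
  expect_identical(roc2$n_pos, roc$n_pos)
  expect_error(roc_short_survivor(vals, months, rep(FALSE, 7), 14),
               "empty class")
})

test_that("AUC equals explicit pair counting and the Mann-Whitney identity", {
  set.seed(83)
  vals <- c(stats::rnorm(6, 5), stats::rnorm(6, 7))
  months <- c(stats::runif(6, 2, 10), stats::runif(6, 20, 40))
  ev <- rep(TRUE, 12)
  roc <- roc_short_survivor(vals, months, ev, window_months = 14)
  pos <- months < 14
  expect_equal(roc$auc, oracle_auc_paircount(vals, pos))
  U <- stats::wilcox.test(-vals[pos], -vals[!pos])$statistic
  expect_equal(roc$auc, unname(U) / (sum(pos) * sum(!pos)))
  # ties contribute one half per pair
  vt <- c(1, 1, 2, 2)
  roct <- roc_short_survivor(vt, c(5, 20, 5, 20), rep(TRUE, 4), 14)
  expect_equal(roct$auc, oracle_auc_paircount(vt, c(TRUE, FALSE, TRUE, FALSE)))
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(95)
  vals <- stats::rnorm(40, 6, 1.2)
  months <- stats::rweibull(40, 1.2, 18)
  months[vals < 5.5] <- months[vals < 5.5] * 0.5   # low expression, short survival
  roc <- roc_short_survivor(vals, months, rep(TRUE, 40), 14)
  ref <- pROC::roc(response = months < 14, predictor = -vals,
                   direction = "<", quiet = TRUE)
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("AUC is invariant under monotone transforms of expression", {
  set.seed(84)
  vals <- stats::rnorm(30, 6, 1)
  months <- stats::rweibull(30, 1.2, 18)
  ev <- rep(TRUE, 30)
  a1 <- roc_short_survivor(vals, months, ev, 14)$auc
  a2 <- roc_short_survivor(exp(vals / 2) + 3, months, ev, 14)$auc
  expect_equal(a1, a2)
})

test_that("permuted labels give AUC centered at one half", {
  set.seed(85)
  n <- 74
  vals <- stats::rnorm(n, 6, 1)
  months <- stats::rweibull(n, 1.2, 18)
  ev <- rep(TRUE, n)
  aucs <- vapply(1:100, function(b) {
    idx <- sample.int(n)
    roc_short_survivor(vals, months[idx], ev, 14)$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("cutoff policies: Youden equals an exhaustive scan, specificity floor holds", {
  set.seed(86)
  vals <- c(stats::rnorm(10, 5, 1), stats::rnorm(10, 7, 1))
  months <- c(stats::runif(10, 2, 10), stats::runif(10, 20, 40))
  ev <- rep(TRUE, 20)
  roc <- roc_short_survivor(vals, months, ev, 14)
  ch <- choose_cutoff(roc, "youden")
  pos <- months < 14
  grid <- sort(unique(c(vals - 1e-6, vals + 1e-6)))
  best_j <- max(vapply(grid, function(cc)
    mean(vals[pos] <= cc) + mean(vals[!pos] > cc) - 1, 0))
  expect_equal(ch$sensitivity + ch$specificity - 1, best_j, tolerance = 1e-9)
  ms <- choose_cutoff(roc, "min_specificity", spec_target = 0.89)
  expect_gte(ms$specificity, 0.89)
  expect_error(choose_cutoff(roc, "min_specificity", spec_target = 1.01),
               "unattainable")
})

test_that("perfectly separating data admits a cutoff with sensitivity and specificity 1", {
  roc <- roc_short_survivor(c(1, 2, 9, 10), c(4, 6, 30, 28),
                            rep(TRUE, 4), 14)
  ch <- choose_cutoff(roc, "youden")
  expect_equal(ch$sensitivity, 1)
  expect_equal(ch$specificity, 1)
})

test_that("window sweep picks the window that matches the planted separation", {
  hits <- vapply(1:10, function(s) {
    set.seed(s + 860)
    n <- 80
    months <- stats::runif(n, 2, 30)
    ev <- stats::runif(n) < 0.9
    vals <- ifelse(months < 14 & ev, -1, 1) + stats::rnorm(n, 0, 0.4)
    sweep_survival_window(vals, months, ev, windows = 10:18)$best_window == 14
  }, NA)
  expect_gte(sum(hits), 9L)
  # a single candidate window is returned trivially
  set.seed(87)
  one <- sweep_survival_window(stats::rnorm(20, 6), stats::runif(20, 2, 30),
                               rep(TRUE, 20), windows = 12)
  expect_identical(one$best_window, 12)
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(88)
  months <- stats::rweibull(24, 1.2, 18)
  vals <- stats::rnorm(24, 6, 1)
  km <- km_logrank(vals, stats::median(vals), months, rep(TRUE, 24))
  for (g in c("low", "high")) {
    cur <- km$curves[km$curves$stratum == g, ]
    grp_months <- months[if (g == "low") vals <= stats::median(vals)
                         else vals > stats::median(vals)]
    expect_equal(cur$survival, 1 - stats::ecdf(grp_months)(cur$time),
                 tolerance = 1e-12)
    expect_true(all(diff(cur$survival) <= 1e-12))
    expect_true(all(cur$survival >= 0 & cur$survival <= 1))
  }
})

test_that("log-rank matches the event-table oracle, is zero for identical strata", {
  set.seed(89)
  months <- c(stats::rweibull(20, 1.2, 12), stats::rweibull(20, 1.2, 24))
  ev <- stats::runif(40) < 0.8
  vals <- c(stats::rnorm(20, 5), stats::rnorm(20, 7))
  km <- km_logrank(vals, 6, months, ev)
  expect_equal(km$chisq, oracle_logrank(months, ev, vals <= 6),
               tolerance = 1e-10)
  # two strata with identical survival data
  months2 <- rep(c(3, 8, 15, 22, 30), 2)
  vals2 <- rep(c(1, 9), each = 5)
  km2 <- km_logrank(vals2, 5, months2, rep(TRUE, 10))
  expect_lt(km2$chisq, 1e-12)
  expect_error(km_logrank(rep(1, 5), 0, months2[1:5], rep(TRUE, 5)),
               "empty stratum")
})

test_that("longitudinal deltas are plain subtraction with baseline handling", {
  lv <- data.frame(patient_id = rep(c("p1", "p2", "p3"), each = 3),
                   timepoint = rep(c("pre", "post4", "post6"), 3),
                   value = c(5, 5.5, 6, 7, 6.5, 6, 4, 4, 4))
  lv <- lv[-c(6), ]   # p2 misses post6
  surv <- c(p1 = 30, p2 = 8, p3 = 15)
  de <- delta_expression(lv, surv, baseline = "pre")
  expect_equal(de$deltas$delta[de$deltas$patient_id == "p1"], c(0.5, 1))
  expect_equal(de$latest["p1", "delta"], 1)
  expect_equal(de$latest["p2", "delta"], -0.5)  # post4 is p2's latest
  # missing baseline excluded with warning
  nb <- rbind(lv, data.frame(patient_id = "p4", timepoint = "post4",
                             value = 9))
  expect_warning(delta_expression(nb, c(surv, p4 = 5)), "without baseline")
  # all-constant changes are degenerate
  flat <- data.frame(patient_id = rep(c("a", "b"), each = 2),
                     timepoint = rep(c("pre", "post4"), 2),
                     value = c(5, 5, 7, 7))
  d0 <- delta_expression(flat, c(a = 10, b = 20))
  expect_true(all(d0$deltas$delta == 0))
  expect_true(is.na(d0$rho))
})

test_that("sign concordance uses the exact hypergeometric law", {
  tab <- matrix(c(8, 1, 1, 8), 2)
  de <- c(rep(-1, 8), rep(-1, 1), rep(1, 1), rep(1, 8)) * stats::runif(18, 0.5, 2)
  dm <- c(rep(-1, 8), rep(1, 1), rep(-1, 1), rep(1, 8)) * stats::runif(18, 0.5, 2)
  res <- ml_concordance(de, dm)
  expect_equal(sort(as.integer(res$table)), sort(as.integer(tab)))
  expect_equal(res$p, oracle_fisher_p(matrix(as.integer(res$table), 2)),
               tolerance = 1e-12)
  # perfectly concordant 10 vs 10
  de2 <- c(rep(1, 10), rep(-1, 10)); dm2 <- de2
  expect_lt(ml_concordance(de2, dm2)$p, 0.01)
  # zeros are excluded; all-zero input errors
  expect_identical(ml_concordance(c(0, de2), c(1, dm2))$n_zero_excluded, 1L)
  expect_error(ml_concordance(c(0, 0), c(1, 1)), "all changes are zero")
})

test_that("the end-to-end evaluation report is internally consistent", {
  cfg <- simulation_config(n_patients = 74, n_dc = 0, n_probes = 60,
                           n_controls = 10, n_planted = 3,
                           dc_signature_n = 10, n_reference = 3, seed = 90)
  sim <- simulate_cohort(cfg)
  em <- preprocess(sim$pbmc)$matrix
  vals <- gene_values(em, cfg$anchor_gene)
  rep_ <- evaluate_biomarker(vals, sim$samples, windows = 10:18)
  expect_gte(rep_$roc$auc, 0.5)
  expect_true(rep_$window %in% 10:18)
  expect_true(rep_$sensitivity >= 0 && rep_$sensitivity <= 1)
  expect_true(rep_$specificity >= 0 && rep_$specificity <= 1)
  expect_gt(rep_$rho, 0)
  expect_identical(sum(rep_$km$n), length(vals))
})
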