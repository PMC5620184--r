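test_that("unpaired d-statistics match a direct-formula oracle", {
  set.seed(21)
  X <- matrix(stats::rnorm(50 * 12, 7, 1), 50,
              dimnames = list(sprintf("p%02d", 1:50), sprintf("s%02d", 1:12)))
  labels <- rep(c("A", "B"), each = 6)
  res <- sam_two_class(X, labels, n_perm = 20, seed = 1)
  expect_equal(res$d, oracle_two_class_d(X, labels, res$s0),
               tolerance = 1e-12)
})

test_that("a probe identical in both classes scores d = 0", {
  set.seed(22)
  X <- matrix(stats::rnorm(5 * 8), 5,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:8)))
  X[3, ] <- rep(c(1, 2, 3, 4), 2)
  labels <- rep(c("A", "B"), each = 4)
  res <- sam_two_class(X, labels, n_perm = 10, seed = 1)
  expect_equal(res$d[3], 0)
})

test_that("4v4 permutation null equals exhaustive enumeration", {
  set.seed(23)
  X <- matrix(stats::rnorm(12 * 8), 12,
              dimnames = list(paste0("p", 1:12), paste0("s", 1:8)))
  labels <- rep(c("A", "B"), each = 4)
  res <- sam_two_class(X, labels, n_perm = 70, seed = 5)
  expect_true(res$exhaustive)
  expect_identical(res$n_perm, 70L)
  # independent enumeration of all 70 assignments of 4 samples to class B
  combs <- utils::combn(8, 4)
  null_oracle <- apply(combs, 2L, function(idx) {
    lab <- rep("A", 8); lab[idx] <- "B"
    oracle_two_class_d(X, lab, res$s0)
  })
  expect_equal(apply(res$perm_d, 2L, sort),
               apply(null_oracle, 1L, sort), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("paired statistics use per-pair differences and sign-flip nulls", {
  set.seed(24)
  m <- 6
  X <- matrix(stats::rnorm(8 * 2 * m), 8,
              dimnames = list(paste0("p", 1:8), paste0("s", 1:(2 * m))))
  labels <- factor(rep(c("pre", "post"), each = m),
                   levels = c("pre", "post"))
  pairing <- rep(paste0("pt", 1:m), 2)
  res <- sam_two_class(X, labels, paired = TRUE, pairing = pairing,
                       n_perm = 64, seed = 2)
  expect_true(res$exhaustive)
  D <- X[, labels == "post"] - X[, labels == "pre"]
  r_oracle <- rowMeans(D)
  s_oracle <- apply(D, 1L, stats::sd) / sqrt(m)
  expect_equal(res$d, unname(r_oracle / (s_oracle + res$s0)),
               tolerance = 1e-12)
  expect_error(sam_two_class(X, labels, paired = TRUE,
                             pairing = c(pairing[-1], "ptX")),
               "incomplete pairing")
})

test_that("unpaired d is invariant to sample order and reproducible by seed", {
  set.seed(25)
  X <- matrix(stats::rnorm(10 * 10), 10,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:10)))
  labels <- rep(c("A", "B"), 5)
  perm <- sample(10)
  r1 <- sam_two_class(X, labels, n_perm = 50, seed = 3)
  r2 <- sam_two_class(X[, perm], labels[perm], n_perm = 50, seed = 3)
  expect_equal(r1$d, r2$d, tolerance = 1e-12)
  r3 <- sam_two_class(X, labels, n_perm = 500, seed = 7)
  r4 <- sam_two_class(X, labels, n_perm = 500, seed = 7)
  expect_identical(r3$perm_d, r4$perm_d)
})

test_that("rescaling one probe keeps the sign of its d and moves |d| continuously", {
  set.seed(26)
  X <- matrix(stats::rnorm(20 * 10), 20,
              dimnames = list(paste0("p", 1:20), paste0("s", 1:10)))
  X[1, 6:10] <- X[1, 6:10] + 2
  labels <- rep(c("A", "B"), each = 5)
  base <- sam_two_class(X, labels, n_perm = 10, seed = 1)
  for (cc in c(0.5, 2, 10)) {
    Xc <- X; Xc[1, ] <- Xc[1, ] * cc
    res <- sam_two_class(Xc, labels, n_perm = 10, seed = 1)
    expect_identical(sign(res$d[1]), sign(base$d[1]))
    expect_gt(abs(res$d[1]), 0)
  }
})

test_that("survival scores vanish for constant probes and match the Cox score", {
  set.seed(27)
  n <- 30
  X <- matrix(stats::rnorm(20 * n, 7, 1), 20,
              dimnames = list(paste0("p", 1:20), paste0("s", 1:n)))
  X[5, ] <- 3.14
  time <- stats::rweibull(n, 1.2, 18)
  for (event in list(rep(TRUE, n), stats::runif(n) > 0.3)) {
    res <- sam_survival(X, time, event, n_perm = 10, seed = 1)
    expect_equal(res$r[5], 0, tolerance = 1e-10)
    # score equals the numerical derivative of the Cox log partial likelihood
    h <- 1e-5
    for (i in c(1, 7, 20)) {
      num <- (oracle_cox_loglik(X[i, ], time, event, h) -
                oracle_cox_loglik(X[i, ], time, event, -h)) / (2 * h)
      expect_lt(abs(res$r[i] - num), 1e-8)
    }
  }
  expect_error(sam_survival(X, time, rep(FALSE, n), n_perm = 5),
               "at least one observed event")
})

test_that("a planted survival gene ranks at the top of |d|", {
  ok <- vapply(1:5, function(s) {
    cfg <- simulation_config(n_patients = 74, n_dc = 0, n_probes = 300,
                             n_controls = 20, n_planted = 1,
                             dc_signature_n = 10, n_reference = 3,
                             effect_size = 1, seed = s)
    sim <- simulate_cohort(cfg)
    st <- sim$samples
    pp <- preprocess(sim$pbmc)$matrix
    pb <- em_subset(pp, probes = !pp$is_control, samples = st$sample_id)
    res <- sam_survival(pb, st$survival_months, st$event,
                        n_perm = 50, seed = s)
    rank_pl <- rank(-abs(res$d))[match(sim$truth$planted_probes,
                                       res$probe_ids)]
    rank_pl <= ceiling(0.01 * length(res$d))
  }, NA)
  expect_gte(mean(ok), 0.8)
})

test_that("FDR90-zero calling matches a brute-force delta scan and calls dominant probes", {
  set.seed(28)
  X <- matrix(stats::rnorm(40 * 12), 40,
              dimnames = list(paste0("p", 1:40), paste0("s", 1:12)))
  # dominant probe: near-constant within each class, far apart between
  # classes, so its observed |d| exceeds every permuted statistic
  X[7, ] <- c(stats::rnorm(6, 0, 0.05), stats::rnorm(6, 6, 0.05))
  labels <- rep(c("A", "B"), each = 6)
  res <- sam_two_class(X, labels, n_perm = 200, seed = 4)
  called <- call_at_percentile_fdr_zero(res)
  expect_true("p7" %in% called)
  expect_setequal(as.character(called), oracle_fdr90_calls(res))
  # null data: agreement with the oracle even when the call set is empty
  X0 <- matrix(stats::rnorm(40 * 12), 40,
               dimnames = dimnames(X))
  res0 <- sam_two_class(X0, labels, n_perm = 200, seed = 4)
  expect_setequal(as.character(call_at_percentile_fdr_zero(res0)),
                  oracle_fdr90_calls(res0))
})

test_that("the delta table reports coherent FDR columns", {
  set.seed(29)
  X <- matrix(stats::rnorm(30 * 10), 30,
              dimnames = list(paste0("p", 1:30), paste0("s", 1:10)))
  res <- sam_two_class(X, rep(c("A", "B"), each = 5), n_perm = 100, seed = 1)
  tab <- sam_delta_table(res)
  expect_true(all(tab$fdr_median <= tab$fdr_q90 + 1e-12))
  expect_true(all(tab$n_called >= 0))
  expect_true(all(diff(tab$n_called) <= 0))   # larger delta, fewer calls
})

test_that("survival classes follow the 12/24-month boundaries", {
  expect_identical(as.character(survival_class(c(6, 30, 12, 24, 11.9, 24.1))),
                   c("short", "long", "medium", "medium", "short", "long"))
  expect_error(survival_class(-1), "non-negative")
})

test_that("fold change works on the linear scale with the 2-fold rule", {
  X <- rbind(a = c(10, 10, 5, 5), b = c(7, 7, 7, 7), c = 2^c(4, 4, 3, 3))
  colnames(X) <- c("l1", "l2", "s1", "s2")
  fc <- fold_change_filter(X, c("l1", "l2"), c("s1", "s2"),
                           log2_scale = FALSE)
  expect_equal(fc$fold[1], 2)
  expect_true(fc$retained[1])
  expect_equal(fc$fold[2], 1)
  expect_false(fc$retained[2])
  # log2 input with group means 4 and 3 un-logs to a 2-fold change
  Xl <- rbind(g = c(4, 4, 3, 3))
  colnames(Xl) <- colnames(X)
  fcl <- fold_change_filter(Xl, c("l1", "l2"), c("s1", "s2"),
                            log2_scale = TRUE)
  expect_equal(fcl$fold, 2)
  expect_true(fcl$retained)
})
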