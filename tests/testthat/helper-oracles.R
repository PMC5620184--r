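# Independent oracle implementations used to cross-check the package's
# statistics on small fixtures. These deliberately use naive loops or
# closed forms and never call the code paths they verify.

# small random expression matrix with a few control probes
make_small_em <- function(n_probes = 20, n_samples = 8, n_controls = 3,
                          scale = "log2", seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rnorm(n_probes * n_samples, 7, 1), n_probes)
  if (scale == "raw") v <- 2^v
  ctrl <- matrix(stats::runif(n_controls * n_samples, 80, 120), n_controls)
  if (scale == "log2") ctrl <- log2(ctrl)
  vals <- rbind(v, ctrl)
  rownames(vals) <- c(sprintf("P%03d", seq_len(n_probes)),
                      sprintf("C%03d", seq_len(n_controls)))
  colnames(vals) <- sprintf("S%02d", seq_len(n_samples))
  expression_matrix(vals,
                    c(sprintf("G%03d", seq_len(n_probes)), rep("", n_controls)),
                    c(rep(FALSE, n_probes), rep(TRUE, n_controls)),
                    scale = scale)
}

# direct-formula unpaired SAM statistics, loops only
oracle_two_class_d <- function(X, labels, s0) {
  lv <- levels(factor(labels))
  vapply(seq_len(nrow(X)), function(i) {
    a <- X[i, labels == lv[1]]
    b <- X[i, labels == lv[2]]
    n1 <- length(a); n2 <- length(b)
    r <- mean(b) - mean(a)
    pooled <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    s <- sqrt((1 / n1 + 1 / n2) * pooled / (n1 + n2 - 2))
    r / (s + s0)
  }, 0)
}

# Cox log partial likelihood (Breslow ties) for one probe
oracle_cox_loglik <- function(x, time, event, beta) {
  ll <- 0
  for (u in sort(unique(time[event]))) {
    deaths <- which(event & time == u)
    risk <- which(time >= u)
    ll <- ll + sum(beta * x[deaths]) -
      length(deaths) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# geNorm M values by brute-force double loop
oracle_genorm_m <- function(v) {
  g <- nrow(v)
  M <- numeric(g)
  for (j in seq_len(g)) {
    acc <- 0
    for (k in seq_len(g)) if (k != j) acc <- acc + stats::sd(v[j, ] - v[k, ])
    M[j] <- acc / (g - 1)
  }
  stats::setNames(M, rownames(v))
}

# AUC by explicit pair counting (low value predicts positive), ties 1/2
oracle_auc_paircount <- function(values, positive) {
  pos <- values[positive]; neg <- values[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a < b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# two-group log-rank chi-square from the event table
oracle_logrank <- function(time, event, group) {
  group <- as.integer(factor(group))
  o_minus_e <- 0; var_sum <- 0
  for (u in sort(unique(time[as.logical(event)]))) {
    at_risk <- time >= u
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d <- sum(event & time == u)
    d1 <- sum(event & time == u & group == 1L)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      var_sum <- var_sum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / var_sum
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# GSEA enrichment score by an explicit cumulative scan
oracle_es <- function(scores, hit, p = 1) {
  n <- length(scores)
  w <- abs(scores)^p
  denom <- sum(w[hit])
  rs <- 0; best <- 0
  for (i in seq_len(n)) {
    rs <- rs + if (hit[i]) w[i] / denom else -1 / (n - sum(hit))
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# brute-force delta scan reproducing the FDR90 = 0 call set
oracle_fdr90_calls <- function(sam, level = 0.9) {
  ds <- sort(sam$d)
  dbar <- rowMeans(apply(sam$perm_d, 1L, sort))
  B <- nrow(sam$perm_d)
  cand <- sort(unique(c(ds - dbar, dbar - ds)))
  cand <- cand[cand > 0]
  for (delta in cand) {
    up <- ds[ds - dbar >= delta & ds > 0]
    dn <- ds[dbar - ds >= delta & ds < 0]
    cutup <- if (length(up)) min(up) else Inf
    cutlow <- if (length(dn)) max(dn) else -Inf
    false_b <- vapply(seq_len(B), function(b)
      sum(sam$perm_d[b, ] >= cutup) + sum(sam$perm_d[b, ] <= cutlow), 0)
    q90 <- sort(false_b)[ceiling(level * B)]
    if (q90 == 0)
      return(sam$probe_ids[sam$d >= cutup | sam$d <= cutlow])
  }
  character(0)
}

# construct a vector pair with an exact sample Pearson correlation
make_exact_cor <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  e <- stats::rnorm(n)
  e <- stats::residuals(stats::lm(e ~ x))
  x <- as.numeric(scale(x)); e <- as.numeric(scale(e))
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}
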