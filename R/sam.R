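# Significance analysis of microarrays: regularized statistics
# d = r / (s + s0) with a permutation null, for two-class (paired and
# unpaired) designs and for censored-survival association via the Cox
# partial-likelihood score at beta = 0.

as_values <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$values
  else if (is.matrix(x)) x
  else stop("expected a matrix or ExpressionMatrix")
}

#' Choose the SAM fudge factor s0 by the percentile rule
#'
#' Scans candidate s0 values (percentiles 0, 5, ..., 100 of the gene-wise
#' scatter `s`) and returns the one minimizing the coefficient of
#' variation of the median absolute deviation of `d = r/(s + s0)` across
#' windows of `s`: the choice that makes the statistic's spread least
#' dependent on the gene's variance.
#'
#' @param r per-probe numerator (effect estimate).
#' @param s per-probe scatter (standard error scale), non-negative.
#' @return The selected s0 (a single non-negative number), with the
#'   candidate percentile in attribute `"alpha"`.
#' @export
sam_s0 <- function(r, s) {
  stopifnot(length(r) == length(s), all(s >= 0))
  alphas <- seq(0, 1, by = 0.05)
  cands <- unique(stats::quantile(s, alphas, names = FALSE))
  n_win <- max(2L, min(10L, floor(length(s) / 5)))
  br <- unique(stats::quantile(s, seq(0, 1, length.out = n_win + 1L),
                               names = FALSE))
  if (length(s) < 10L || length(br) < 3L) {
    # too few probes (or a degenerate scatter) to window: median fallback
    s0 <- stats::median(s)
    attr(s0, "alpha") <- 0.5
    return(s0)
  }
  win <- cut(s, breaks = br, include.lowest = TRUE)
  cvs <- vapply(cands, function(s0) {
    d <- r / (s + s0)
    mads <- tapply(d, win, stats::mad)
    mads <- mads[!is.na(mads) & mads > 0]
    if (length(mads) < 2L) return(Inf)
    stats::sd(mads) / mean(mads)
  }, 0)
  s0 <- cands[which.min(cvs)]
  attr(s0, "alpha") <- alphas[match(s0, cands)]
  s0
}

two_class_stats <- function(X, in2, n1, n2) {
  # r = mean(group2) - mean(group1); s = pooled-SD standard error
  s2 <- X %*% in2
  s1 <- rowSums(X) - s2
  ssq2 <- (X * X) %*% in2
  ssq1 <- rowSums(X * X) - ssq2
  m1 <- s1 / n1
  m2 <- s2 / n2
  pooled <- pmax((ssq1 - n1 * m1^2) + (ssq2 - n2 * m2^2), 0)
  s <- sqrt((1 / n1 + 1 / n2) * pooled / (n1 + n2 - 2))
  list(r = as.numeric(m2 - m1), s = as.numeric(s))
}

paired_stats <- function(D, signs) {
  # D: per-pair differences (probes x pairs); signs flip pairs in the null
  m <- ncol(D)
  mu <- as.numeric(D %*% signs) / m
  ssq <- rowSums(D * D)       # invariant under sign flips
  v <- (ssq - m * mu^2) / (m - 1)
  list(r = mu, s = sqrt(pmax(v, 0) / m))
}

#' Two-class SAM statistics with a permutation null
#'
#' Computes per-probe regularized difference statistics
#' `d = r / (s + s0)`: unpaired (`r` = difference of class means, `s` =
#' pooled-SD standard error) or paired (`r` = mean per-pair difference,
#' `s` = its standard error). The permutation null permutes class labels
#' (unpaired) or flips pair signs (paired), with `s0` held at its observed
#' value; enumeration is exhaustive whenever the permutation space is no
#' larger than `n_perm`.
#'
#' @param x numeric matrix or `ExpressionMatrix` (probes x samples).
#' @param labels two-level factor (or vector) of class labels per sample;
#'   `d > 0` means higher expression in the second level.
#' @param paired set `TRUE` for a paired design.
#' @param pairing pair identifiers per sample (required when `paired`);
#'   each pair must occur exactly once in each class.
#' @param n_perm number of permutations (cap; exhaustive below it).
#' @param seed RNG seed for the permutation draw.
#' @return A `SamResult`: observed `d`, `r`, `s`, `s0`, the permutation
#'   statistic matrix `perm_d` (permutations x probes), and bookkeeping.
#' @export
sam_two_class <- function(x, labels, paired = FALSE, pairing = NULL,
                          n_perm = 1000L, seed = 1L) {
  X <- as_values(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two classes")
  if (any(table(labels) < 2L)) stop("each class needs at least 2 samples")
  set.seed(seed)
  if (paired) {
    if (is.null(pairing)) stop("paired = TRUE requires `pairing`")
    p1 <- pairing[labels == levels(labels)[1L]]
    p2 <- pairing[labels == levels(labels)[2L]]
    if (anyDuplicated(p1) || anyDuplicated(p2) || !setequal(p1, p2))
      stop("incomplete pairing: each pair needs one sample in each class")
    i1 <- which(labels == levels(labels)[1L])[match(sort(p1), p1)]
    i2 <- which(labels == levels(labels)[2L])[match(sort(p1), p2)]
    D <- X[, i2, drop = FALSE] - X[, i1, drop = FALSE]
    m <- ncol(D)
    obs <- paired_stats(D, rep(1, m))
    s0 <- sam_s0(obs$r, obs$s)
    d <- obs$r / (obs$s + s0)
    exhaustive <- 2^m <= n_perm
    signs <- if (exhaustive) {
      as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
    } else {
      matrix(sample(c(-1, 1), n_perm * m, replace = TRUE), ncol = m)
    }
    pd <- apply(signs, 1L, function(sg) {
      st <- paired_stats(D, sg)
      st$r / (st$s + s0)
    })
    perm_d <- if (is.matrix(pd)) t(pd) else matrix(pd, ncol = 1L)
  } else {
    in2 <- as.numeric(labels == levels(labels)[2L])
    n2 <- sum(in2); n1 <- length(in2) - n2
    obs <- two_class_stats(X, in2, n1, n2)
    s0 <- sam_s0(obs$r, obs$s)
    d <- obs$r / (obs$s + s0)
    n <- length(in2)
    exhaustive <- choose(n, n2) <= n_perm
    assigns <- if (exhaustive) {
      utils::combn(n, n2, simplify = FALSE)
    } else {
      lapply(seq_len(n_perm), function(b) sample.int(n, n2))
    }
    pd <- vapply(assigns, function(idx2) {
      v <- numeric(n); v[idx2] <- 1
      st <- two_class_stats(X, v, n1, n2)
      st$r / (st$s + s0)
    }, numeric(nrow(X)))
    perm_d <- if (is.matrix(pd)) t(pd) else matrix(pd, ncol = 1L)
  }
  structure(list(d = as.numeric(d), r = obs$r, s = obs$s, s0 = as.numeric(s0),
                 perm_d = perm_d, probe_ids = rownames(X),
                 type = if (paired) "paired" else "unpaired",
                 n_perm = nrow(perm_d), exhaustive = exhaustive),
            class = "SamResult")
}

cox_score_prep <- function(time, event) {
  n <- length(time)
  ord <- order(time)
  ts <- time[ord]; ev <- as.logical(event)[ord]
  ut <- unique(ts[ev])
  j_first <- match(ut, ts)                 # first sorted index at each event time
  n_risk <- n - j_first + 1
  d_t <- vapply(ut, function(u) sum(ev & ts == u), 0L)
  # b: X %*% b = per-probe score U; W, wd: risk-set means for the variance
  M <- outer(seq_len(n), j_first, ">=") * 1          # n x T suffix indicators
  a <- d_t / n_risk
  b <- as.numeric(ev) - as.numeric(M %*% a)
  W <- sweep(M, 2L, n_risk, "/")
  list(ord = ord, b = b, c = as.numeric(M %*% a), W = W, d_t = d_t)
}

cox_score_stats <- function(X, prep, col_order) {
  Xs <- X[, col_order, drop = FALSE]
  U <- as.numeric(Xs %*% prep$b)
  means <- Xs %*% prep$W
  V <- as.numeric((Xs * Xs) %*% prep$c) - as.numeric((means * means) %*% prep$d_t)
  list(r = U, s = sqrt(pmax(V, 0)))
}

#' Survival SAM: Cox-score statistics with a permutation null
#'
#' For each probe the numerator is the Cox partial-likelihood score at
#' `beta = 0` (the sum over event times of the deceased patient's
#' expression minus the risk-set mean, Breslow handling of ties), the
#' scatter is the square root of the score variance, and
#' `d = r / (s + s0)`. The null permutes the (survival, event) pairs
#' against the samples. Positive `d` marks genes expressed higher in
#' patients who die early; genes rising with survival get negative `d`.
#'
#' @param x numeric matrix or `ExpressionMatrix` (probes x samples).
#' @param time non-negative survival in months, one per sample.
#' @param event logical/0-1, `TRUE` when death was observed.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return A `SamResult` with `type = "survival"`.
#' @export
sam_survival <- function(x, time, event, n_perm = 1000L, seed = 1L) {
  X <- as_values(x)
  event <- as.logical(event)
  if (length(time) != ncol(X) || length(event) != ncol(X))
    stop("time and event must have one entry per sample")
  if (any(time < 0)) stop("survival months must be non-negative")
  if (!any(event)) stop("need at least one observed event")
  set.seed(seed)
  prep <- cox_score_prep(time, event)
  obs <- cox_score_stats(X, prep, prep$ord)
  s0 <- sam_s0(obs$r, obs$s)
  d <- obs$r / (obs$s + s0)
  n <- ncol(X)
  pd <- vapply(seq_len(n_perm), function(b) {
    st <- cox_score_stats(X, prep, sample.int(n))
    st$r / (st$s + s0)
  }, numeric(nrow(X)))
  perm_d <- if (is.matrix(pd)) t(pd) else matrix(pd, ncol = 1L)
  structure(list(d = as.numeric(d), r = obs$r, s = obs$s, s0 = as.numeric(s0),
                 perm_d = perm_d, probe_ids = rownames(X),
                 type = "survival", n_perm = n_perm, exhaustive = FALSE),
            class = "SamResult")
}

#' @export
print.SamResult <- function(x, ...) {
  cat(sprintf("SamResult (%s): %d probes, %d permutations%s, s0 = %.4g\n",
              x$type, length(x$d), x$n_perm,
              if (x$exhaustive) " (exhaustive)" else "", x$s0))
  invisible(x)
}

sorted_perm_rows <- function(pm) {
  # probes x permutations matrix of row-sorted permutation statistics
  out <- apply(pm, 1L, sort)
  if (!is.matrix(out)) out <- matrix(out, nrow = 1L)
  out
}

sam_cuts <- function(ds, dbar, delta) {
  up <- ds[ds - dbar >= delta & ds > 0]
  dn <- ds[dbar - ds >= delta & ds < 0]
  list(cutup = if (length(up)) min(up) else Inf,
       cutlow = if (length(dn)) max(dn) else -Inf)
}

#' Delta-threshold table for a SAM result
#'
#' For a grid of delta values, probes are called when their ordered
#' statistic departs from the permutation-expected order statistic by at
#' least delta; the table reports the cut points, the number of calls, and
#' the median and 90th-percentile (across permutations) false-call counts
#' and FDRs.
#'
#' @param sam a `SamResult`.
#' @param deltas numeric grid; defaults to 30 values spanning the observed
#'   departures.
#' @return A data.frame with one row per delta.
#' @export
sam_delta_table <- function(sam, deltas = NULL) {
  ds <- sort(sam$d)
  dbar <- rowMeans(sorted_perm_rows(sam$perm_d))
  if (is.null(deltas)) {
    dev <- abs(ds - dbar)
    deltas <- unique(stats::quantile(dev[dev > 0], seq(0, 1, length.out = 30),
                                     names = FALSE))
  }
  B <- nrow(sam$perm_d)
  sorted_rows <- sorted_perm_rows(sam$perm_d)
  p <- length(ds)
  rows <- lapply(deltas, function(delta) {
    cuts <- sam_cuts(ds, dbar, delta)
    n_called <- sum(sam$d >= cuts$cutup) + sum(sam$d <= cuts$cutlow)
    false_b <- vapply(seq_len(B), function(b) {
      col <- sorted_rows[, b]
      (p - sum(col < cuts$cutup)) + sum(col <= cuts$cutlow)
    }, 0)
    data.frame(delta = delta, cutlow = cuts$cutlow, cutup = cuts$cutup,
               n_called = n_called,
               false_median = stats::median(false_b),
               false_q90 = stats::quantile(false_b, 0.9, type = 1, names = FALSE),
               fdr_median = stats::median(false_b) / max(1, n_called),
               fdr_q90 = stats::quantile(false_b, 0.9, type = 1,
                                         names = FALSE) / max(1, n_called))
  })
  do.call(rbind, rows)
}

#' Call probes at 90th-percentile FDR zero
#'
#' Finds the smallest delta (largest call set in the delta-indexed family)
#' such that in at least `level` of the permutations no permuted statistic
#' exceeds the calling thresholds, i.e. the 90th percentile across
#' permutations of the false-call count is zero, then returns the probes
#' called at that delta. May return an empty set.
#'
#' @param sam a `SamResult`.
#' @param level required fraction of clean permutations (default 0.9).
#' @return Character vector of called probe IDs (empty when nothing can be
#'   called cleanly), with the cut points in attribute `"cuts"`.
#' @export
call_at_percentile_fdr_zero <- function(sam, level = 0.9) {
  ds <- sort(sam$d)
  dbar <- rowMeans(sorted_perm_rows(sam$perm_d))
  B <- nrow(sam$perm_d)
  perm_max <- apply(sam$perm_d, 1L, max)
  perm_min <- apply(sam$perm_d, 1L, min)
  allowed_bad <- B - ceiling(level * B)
  cand <- sort(unique(c(ds - dbar, dbar - ds)))
  cand <- c(cand[cand > 0], Inf)
  for (delta in cand) {
    cuts <- sam_cuts(ds, dbar, delta)
    nv <- sum(perm_max >= cuts$cutup | perm_min <= cuts$cutlow)
    if (nv <= allowed_bad) {
      called <- sam$probe_ids[sam$d >= cuts$cutup | sam$d <= cuts$cutlow]
      attr(called, "cuts") <- cuts
      attr(called, "delta") <- delta
      return(called)
    }
  }
  character(0)
}

#' Classify survival into short / medium / long
#'
#' Under 12 months is short, 12 to 24 months inclusive is medium, beyond
#' 24 months is long.
#'
#' @param survival_months non-negative numeric vector.
#' @return Factor with levels short, medium, long.
#' @export
survival_class <- function(survival_months) {
  if (any(survival_months < 0)) stop("survival months must be non-negative")
  cls <- ifelse(survival_months < 12, "short",
                ifelse(survival_months <= 24, "medium", "long"))
  factor(cls, levels = c("short", "medium", "long"))
}

#' Fold-change filter between long and short survivors
#'
#' Fold change is the ratio of mean expression in long survivors over mean
#' expression in short survivors, computed on the linear scale (log2
#' matrices are un-logged first). Probes with fold >= cutoff or
#' <= 1/cutoff are retained.
#'
#' @param x numeric matrix or `ExpressionMatrix`.
#' @param long_ids,short_ids sample IDs (or column indices) of the two
#'   groups, both non-empty.
#' @param cutoff fold-change cutoff (default 2).
#' @param log2_scale when `x` is a bare matrix, whether its values are
#'   log2 (`ExpressionMatrix` input carries its own flag).
#' @return data.frame with probe_id, fold and retained flag.
#' @export
fold_change_filter <- function(x, long_ids, short_ids, cutoff = 2,
                               log2_scale = NULL) {
  X <- as_values(x)
  is_log2 <- if (inherits(x, "ExpressionMatrix")) x$scale == "log2"
             else isTRUE(log2_scale)
  if (!length(long_ids) || !length(short_ids))
    stop("both groups must be non-empty")
  lin <- if (is_log2) 2^X else X
  m_long <- rowMeans(lin[, long_ids, drop = FALSE])
  m_short <- rowMeans(lin[, short_ids, drop = FALSE])
  if (any(m_long <= 0) || any(m_short <= 0))
    stop("non-positive linear mean expression; cannot form fold change")
  fold <- m_long / m_short
  data.frame(probe_id = rownames(X) %||% as.character(seq_along(fold)),
             fold = as.numeric(fold),
             retained = fold >= cutoff | fold <= 1 / cutoff,
             row.names = NULL)
}
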