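# Clinical evaluation of a single biomarker gene: center normalization,
# short-survivor ROC with window sweep, cutoff policies, Kaplan-Meier /
# log-rank stratification, longitudinal change, M/L concordance.

#' Center-normalize expression values
#'
#' Subtracts each treatment center's median from its samples so
#' between-center offsets vanish before pooling: every center's output
#' median is exactly zero. Centers with fewer than 3 samples are still
#' normalized but trigger a warning.
#'
#' @param values named numeric vector of (log2) expression values.
#' @param centers center label per value.
#' @return The normalized values.
#' @export
center_normalize <- function(values, centers) {
  if (length(values) != length(centers))
    stop("every sample needs a center label")
  if (anyNA(centers)) stop("missing center label")
  small <- names(which(table(centers) < 3L))
  if (length(small))
    warning("center(s) with fewer than 3 samples: ",
            paste(small, collapse = ", "))
  values - stats::ave(values, centers, FUN = stats::median)
}

#' ROC for identifying short survivors by low expression
#'
#' Positives are patients with an observed death before `window_months`;
#' negatives survived (or were censored) at or beyond the window;
#' patients censored before the window are excluded (their class is
#' unknown). The classifier is "low expression predicts short survival",
#' so the score is the negated value. AUC is the tie-adjusted
#' Mann-Whitney pair-counting probability (ties count 1/2) and its
#' standard error follows Hanley-McNeil. Thresholds are placed midway
#' between distinct expression values.
#'
#' @param values named numeric expression per patient.
#' @param survival_months,event survival data aligned with `values`.
#' @param window_months months defining the short-survivor class.
#' @return A `roc_curve`: data.frame of (cutoff, sensitivity,
#'   specificity), `auc`, `se`, class sizes and excluded count.
#' @export
roc_short_survivor <- function(values, survival_months, event, window_months) {
  stopifnot(length(values) == length(survival_months),
            length(values) == length(event))
  event <- as.logical(event)
  pos <- event & survival_months < window_months
  neg <- survival_months >= window_months
  excl <- !pos & !neg
  if (!sum(pos) || !sum(neg))
    stop(sprintf("empty class for %g-month window (%d short, %d long)",
                 window_months, sum(pos), sum(neg)))
  v <- values[!excl]
  y <- pos[!excl]
  # AUC via midranks of the score -value (low expression -> positive)
  rk <- rank(-v)
  n1 <- sum(y); n0 <- sum(!y)
  auc <- (sum(rk[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  sv <- sort(unique(v))
  cutoffs <- c(min(sv) - 1, (sv[-1] + sv[-length(sv)]) / 2, max(sv) + 1)
  curve <- data.frame(
    cutoff = cutoffs,
    sensitivity = vapply(cutoffs, function(cc) mean(v[y] <= cc), 0),
    specificity = vapply(cutoffs, function(cc) mean(v[!y] > cc), 0))
  structure(list(curve = curve, auc = auc, se = se,
                 n_pos = n1, n_neg = n0, n_excluded = sum(excl),
                 window_months = window_months),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC (%g-month window): AUC %.3f +/- %.3f (%d short, %d long, %d excluded)\n",
              x$window_months, x$auc, x$se, x$n_pos, x$n_neg, x$n_excluded))
  invisible(x)
}

#' Sweep candidate survival windows and pick the best AUC
#'
#' Computes the short-survivor ROC for each candidate window (default a
#' 10-18 month grid) and returns the per-window AUCs and the window with
#' the highest AUC (ties resolved toward the smaller window). Windows
#' leaving an empty class are skipped with a notice.
#'
#' @param values,survival_months,event as in [roc_short_survivor()].
#' @param windows candidate windows in months.
#' @return A list: `table` (window, AUC, SE, class sizes), `best_window`,
#'   `best_roc` and any skipped windows.
#' @export
sweep_survival_window <- function(values, survival_months, event,
                                  windows = 10:18) {
  if (length(windows) < 1L) stop("need at least one candidate window")
  rocs <- list(); skipped <- numeric(0)
  for (w in windows) {
    r <- tryCatch(roc_short_survivor(values, survival_months, event, w),
                  error = function(e) NULL)
    if (is.null(r)) skipped <- c(skipped, w) else rocs[[as.character(w)]] <- r
  }
  if (!length(rocs)) stop("every candidate window left an empty class")
  if (length(skipped))
    message("skipped window(s) with an empty class: ",
            paste(skipped, collapse = ", "))
  tab <- do.call(rbind, lapply(rocs, function(r)
    data.frame(window = r$window_months, auc = r$auc, se = r$se,
               n_pos = r$n_pos, n_neg = r$n_neg)))
  rownames(tab) <- NULL
  best <- tab$window[order(-tab$auc, tab$window)][1L]
  list(table = tab, best_window = best,
       best_roc = rocs[[as.character(best)]], skipped = skipped)
}

#' Choose an operating cutoff on a ROC curve
#'
#' Policy `"youden"` maximizes sensitivity + specificity - 1. Policy
#' `"min_specificity"` returns the sensitivity-maximizing threshold whose
#' specificity is at least `spec_target` (the high-specificity operating
#' style used when selecting patients for alternative treatment), and
#' errors if the target is unattainable, reporting the attainable
#' maximum.
#'
#' @param roc a `roc_curve`.
#' @param policy `"youden"` or `"min_specificity"`.
#' @param spec_target specificity floor for `"min_specificity"`.
#' @return A list: `cutoff` (expression units; predict short survival at
#'   or below it), `sensitivity`, `specificity`.
#' @export
choose_cutoff <- function(roc, policy = c("youden", "min_specificity"),
                          spec_target = 0.89) {
  policy <- match.arg(policy)
  cv <- roc$curve
  if (policy == "youden") {
    j <- cv$sensitivity + cv$specificity - 1
    pick <- which(j == max(j))
    pick <- pick[order(-cv$specificity[pick], cv$cutoff[pick])][1L]
  } else {
    ok <- which(cv$specificity >= spec_target)
    if (!length(ok))
      stop(sprintf("specificity target %.2f unattainable; maximum %.2f",
                   spec_target, max(cv$specificity)))
    pick <- ok[order(-cv$sensitivity[ok], -cv$specificity[ok])][1L]
  }
  list(cutoff = cv$cutoff[pick],
       sensitivity = cv$sensitivity[pick],
       specificity = cv$specificity[pick])
}

#' Kaplan-Meier curves and log-rank test for a biomarker cutoff
#'
#' Stratifies patients into low (at or below the cutoff) versus high
#' expression, estimates each stratum's survival by the product-limit
#' estimator with right censoring, and compares the strata with the
#' unstratified two-group log-rank test.
#'
#' @param values expression per patient.
#' @param cutoff threshold; `values <= cutoff` forms the low stratum.
#' @param survival_months,event survival data.
#' @return A list: `curves` (stratum, time, survival, at-risk table),
#'   `chisq`, `p` (1 df), stratum sizes and the fitted
#'   `survival::survfit` object.
#' @export
km_logrank <- function(values, cutoff, survival_months, event) {
  grp <- factor(ifelse(values <= cutoff, "low", "high"),
                levels = c("low", "high"))
  if (any(table(grp) == 0L)) stop("empty stratum at cutoff ", cutoff)
  event <- as.integer(as.logical(event))
  fit <- survival::survfit(survival::Surv(survival_months, event) ~ grp)
  sm <- summary(fit)
  strata_lab <- sub("^grp=", "", as.character(sm$strata))
  curves <- data.frame(stratum = strata_lab, time = sm$time,
                       survival = sm$surv, n_risk = sm$n.risk,
                       n_event = sm$n.event, row.names = NULL)
  sd_ <- survival::survdiff(survival::Surv(survival_months, event) ~ grp)
  chisq <- unname(sd_$chisq)
  list(curves = curves, chisq = chisq,
       p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
       n = as.integer(table(grp)), fit = fit)
}

#' Longitudinal expression change versus survival
#'
#' For each patient computes the change in (log2) expression of every
#' later timepoint relative to the baseline timepoint, and correlates the
#' latest available change per patient with survival months (one-tailed
#' Spearman, testing a positive association). Patients without a baseline
#' measurement are excluded with a warning; an all-constant change vector
#' is reported as degenerate (`rho = NA`).
#'
#' @param long_values data.frame with columns `patient_id`, `timepoint`,
#'   `value`.
#' @param survival_months named numeric vector (patient -> months).
#' @param baseline baseline timepoint label.
#' @return A list: `deltas` (patient, timepoint, delta), `latest` (one
#'   delta per patient), `rho`, `p`, `n`.
#' @export
delta_expression <- function(long_values, survival_months, baseline = "pre") {
  stopifnot(all(c("patient_id", "timepoint", "value") %in% names(long_values)))
  tps <- unique(as.character(long_values$timepoint))
  if (!baseline %in% tps) stop("baseline timepoint not present: ", baseline)
  later_levels <- setdiff(tps, baseline)
  base <- long_values[long_values$timepoint == baseline, , drop = FALSE]
  no_base <- setdiff(unique(long_values$patient_id), base$patient_id)
  if (length(no_base))
    warning("excluding ", length(no_base), " patient(s) without baseline: ",
            paste(utils::head(no_base, 5L), collapse = ", "))
  later <- long_values[long_values$timepoint != baseline &
                         long_values$patient_id %in% base$patient_id, ,
                       drop = FALSE]
  if (!nrow(later)) stop("no later timepoints to compare with baseline")
  deltas <- data.frame(
    patient_id = later$patient_id,
    timepoint = later$timepoint,
    delta = later$value - base$value[match(later$patient_id, base$patient_id)],
    row.names = NULL)
  # latest available change per patient (timepoints in their given order)
  ord <- match(as.character(deltas$timepoint), later_levels)
  latest <- do.call(rbind, lapply(split(deltas[order(ord), ],
                                        deltas$patient_id[order(ord)]),
                                  function(df) df[nrow(df), ]))
  months <- survival_months[latest$patient_id]
  rho <- p <- NA_real_
  if (stats::sd(latest$delta) > 0 && stats::sd(months) > 0) {
    ht <- suppressWarnings(stats::cor.test(latest$delta, months,
                                           method = "spearman",
                                           alternative = "greater"))
    rho <- unname(ht$estimate); p <- ht$p.value
  }
  list(deltas = deltas, latest = latest, rho = rho, p = p,
       n = nrow(latest))
}

#' Concordance of expression change with myeloid/lymphoid balance change
#'
#' Cross-tabulates the signs of paired per-patient changes (expression
#' versus M/L ratio), excluding exact zeros, and tests association with
#' the two-sided Fisher exact test (hypergeometric enumeration via
#' [stats::fisher.test()]).
#'
#' @param delta_expr,delta_ml paired numeric vectors of per-patient
#'   changes.
#' @return A list: `table` (2x2 sign counts), `p`, `n_used`,
#'   `n_zero_excluded`.
#' @export
ml_concordance <- function(delta_expr, delta_ml) {
  if (length(delta_expr) != length(delta_ml))
    stop("paired change vectors must have equal length")
  keep <- delta_expr != 0 & delta_ml != 0 &
    !is.na(delta_expr) & !is.na(delta_ml)
  if (!any(keep)) stop("all changes are zero; concordance undefined")
  se <- factor(sign(delta_expr[keep]), levels = c(-1, 1),
               labels = c("expr_down", "expr_up"))
  sm <- factor(sign(delta_ml[keep]), levels = c(-1, 1),
               labels = c("ml_down", "ml_up"))
  tab <- table(se, sm)
  list(table = tab, p = stats::fisher.test(tab)$p.value,
       n_used = sum(keep), n_zero_excluded = sum(!keep))
}

#' Evaluate a biomarker gene end to end
#'
#' Center-normalizes the gene's expression, correlates it with survival
#' (one-tailed Spearman), sweeps the survival window for the best ROC,
#' chooses a cutoff under the given policy, and stratifies survival by
#' that cutoff with a Kaplan-Meier / log-rank comparison.
#'
#' @param values named expression vector (e.g. qPCR log2 relative
#'   expression), one entry per patient sample.
#' @param samples a `SampleTable` providing center, survival and event by
#'   sample ID.
#' @param windows candidate survival windows (months).
#' @param cutoff_policy,spec_target cutoff choice, see [choose_cutoff()].
#' @return An `EvaluationReport` list: normalized values, `rho`/`p`,
#'   window sweep, chosen `window`, `cutoff`, sensitivity/specificity,
#'   ROC and KM/log-rank results.
#' @export
evaluate_biomarker <- function(values, samples, windows = 10:18,
                               cutoff_policy = "youden", spec_target = 0.89) {
  ids <- intersect(names(values), samples$sample_id)
  if (!length(ids)) stop("no overlap between values and sample table")
  st <- samples[match(ids, samples$sample_id), , drop = FALSE]
  norm <- center_normalize(values[ids], st$center)
  rho <- p_rho <- NA_real_
  if (stats::sd(norm) > 0) {
    ht <- suppressWarnings(stats::cor.test(norm, st$survival_months,
                                           method = "spearman",
                                           alternative = "greater"))
    rho <- unname(ht$estimate); p_rho <- ht$p.value
  }
  sw <- sweep_survival_window(norm, st$survival_months, st$event, windows)
  cut <- choose_cutoff(sw$best_roc, policy = cutoff_policy,
                       spec_target = spec_target)
  km <- km_logrank(norm, cut$cutoff, st$survival_months, st$event)
  structure(list(normalized = norm, rho = rho, rho_p = p_rho,
                 sweep = sw$table, window = sw$best_window,
                 roc = sw$best_roc, cutoff = cut$cutoff,
                 sensitivity = cut$sensitivity,
                 specificity = cut$specificity, km = km),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf(paste0("EvaluationReport: rho %.3f (p %.2g); best window %g months, ",
                     "AUC %.3f +/- %.3f;\n  cutoff %.3f -> sens %.2f / spec %.2f; ",
                     "log-rank chisq %.2f (p %.2g)\n"),
              x$rho, x$rho_p, x$window, x$roc$auc, x$roc$se,
              x$cutoff, x$sensitivity, x$specificity, x$km$chisq, x$km$p))
  invisible(x)
}
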