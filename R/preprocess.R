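#' Background-adjust raw intensities using control probes
#'
#' Estimates a global background offset as the `q`-th quantile of all
#' control-probe intensities (pooled over samples, or per sample with
#' `per_sample = TRUE`), subtracts it from every value, and floors the
#' result at a small positive constant so a subsequent log2 transform is
#' defined. Ranking of values above the floor is preserved within each
#' sample.
#'
#' @param em a raw-scale `ExpressionMatrix` with at least one control probe.
#' @param q quantile of the pooled control-probe intensities, in (0, 1).
#' @param floor positive constant replacing values at or below the offset.
#' @param per_sample estimate one offset per sample instead of a pooled one.
#' @return The adjusted raw-scale `ExpressionMatrix`, with the offset(s)
#'   stored in attribute `"offset"`.
#' @export
background_adjust <- function(em, q = 0.05, floor = 1.0, per_sample = FALSE) {
  if (em$scale != "raw") stop("background_adjust expects a raw-scale matrix")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (floor <= 0) stop("floor must be positive")
  ctrl <- em$values[em$is_control, , drop = FALSE]
  if (!nrow(ctrl)) stop("no control probes in matrix")
  v <- em$values
  if (per_sample) {
    offset <- apply(ctrl, 2L, stats::quantile, probs = q, names = FALSE)
    v <- sweep(v, 2L, offset, "-")
  } else {
    offset <- stats::quantile(as.numeric(ctrl), probs = q, names = FALSE)
    v <- v - offset
  }
  v <- pmax(v, floor)
  out <- expression_matrix(v, em$gene_symbols, em$is_control, scale = "raw")
  attr(out, "offset") <- offset
  out
}

#' Log2-transform a background-adjusted matrix
#'
#' @param em a raw-scale `ExpressionMatrix` with strictly positive values
#'   (run [background_adjust()] first).
#' @return The `ExpressionMatrix` on the log2 scale.
#' @export
log2_transform <- function(em) {
  if (em$scale == "log2") stop("matrix is already on the log2 scale")
  if (any(em$values <= 0))
    stop("non-positive values present; run background_adjust() first")
  expression_matrix(log2(em$values), em$gene_symbols, em$is_control,
                    scale = "log2")
}

#' Quality-control sample filter
#'
#' A sample is kept iff (a) the fraction of non-control probes detected
#' above the background floor is at least `min_detection_fraction`, and
#' (b) its median Pearson correlation with all other samples is at least
#' `min_median_correlation`. The report lists every sample with both
#' metrics and the failing criterion for exclusions.
#'
#' @param em a log2-scale `ExpressionMatrix` with at least 3 samples.
#' @param min_detection_fraction minimum detected-probe fraction.
#' @param min_median_correlation minimum median inter-sample Pearson
#'   correlation.
#' @param detection_level log2 level at or below which a probe counts as
#'   undetected (0 = the log2 of the default background floor).
#' @return A list with `kept` (sample IDs) and `report` (per-sample
#'   data.frame: detection, median correlation, kept flag, reason).
#' @export
qc_filter_samples <- function(em, min_detection_fraction = 0.5,
                              min_median_correlation = 0.8,
                              detection_level = 0) {
  if (em$scale != "log2") stop("qc_filter_samples expects a log2-scale matrix")
  v <- em$values[!em$is_control, , drop = FALSE]
  if (ncol(v) < 3L) stop("need at least 3 samples for correlation-based QC")
  detection <- colMeans(v > detection_level)
  cm <- suppressWarnings(stats::cor(v))
  if (anyNA(cm)) {
    # zero-variance samples: correlation 1 with an identical twin, else 0
    nas <- which(is.na(cm), arr.ind = TRUE)
    cm[nas] <- as.numeric(vapply(seq_len(nrow(nas)), function(k)
      isTRUE(all.equal(v[, nas[k, 1L]], v[, nas[k, 2L]])), NA))
  }
  med_cor <- vapply(seq_len(ncol(v)),
                    function(j) stats::median(cm[-j, j]), 0)
  ok_det <- detection >= min_detection_fraction
  ok_cor <- med_cor >= min_median_correlation
  reason <- rep("", ncol(v))
  reason[!ok_det] <- "low_detection"
  reason[ok_det & !ok_cor] <- "low_correlation"
  report <- data.frame(sample_id = colnames(v),
                       detection = detection,
                       median_correlation = med_cor,
                       kept = ok_det & ok_cor,
                       reason = reason,
                       row.names = NULL)
  list(kept = colnames(v)[ok_det & ok_cor], report = report)
}

#' Full preprocessing: background adjustment, log2, sample QC
#'
#' @param em raw-scale `ExpressionMatrix`.
#' @param q control-probe quantile for [background_adjust()].
#' @param floor positive flooring constant.
#' @param min_detection_fraction,min_median_correlation QC thresholds, see
#'   [qc_filter_samples()].
#' @return A list with `matrix` (log2 `ExpressionMatrix` restricted to kept
#'   samples) and `qc` (the QC report).
#' @export
preprocess <- function(em, q = 0.05, floor = 1.0,
                       min_detection_fraction = 0.5,
                       min_median_correlation = 0.8) {
  lm <- log2_transform(background_adjust(em, q = q, floor = floor))
  qc <- qc_filter_samples(lm, min_detection_fraction, min_median_correlation,
                          detection_level = log2(floor))
  list(matrix = em_subset(lm, samples = qc$kept), qc = qc$report)
}
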