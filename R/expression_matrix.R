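#' Construct an expression matrix
#'
#' The central container of the pipeline: a probe x sample grid of raw
#' intensities or log2 expression values, together with per-probe metadata
#' (gene symbol, control-probe flag) and a scale flag that downstream stages
#' use to refuse input on the wrong scale.
#'
#' @param values numeric matrix, probes in rows, samples in columns. Row
#'   names are probe IDs, column names are sample IDs; both mandatory and
#'   unique. No missing values are allowed (no stage defines missing-value
#'   handling).
#' @param gene_symbols character vector, one symbol per probe. May contain
#'   empty strings for unannotated probes; such probes are carried through
#'   matrix operations but excluded from symbol-keyed joins.
#' @param is_control logical vector, one flag per probe, `TRUE` for control
#'   probes (used by background adjustment).
#' @param scale `"raw"` or `"log2"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, gene_symbols, is_control,
                              scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  em <- structure(
    list(values = values,
         gene_symbols = as.character(gene_symbols),
         is_control = as.logical(is_control),
         scale = scale),
    class = "ExpressionMatrix")
  validate_expression_matrix(em)
  em
}

#' Validate ExpressionMatrix invariants
#'
#' Checks dimension agreement, presence and uniqueness of probe and sample
#' IDs, absence of missing values, and a legal scale flag. Called by the
#' constructor and by the readers; the generator's outputs must also pass.
#'
#' @param em an `ExpressionMatrix`.
#' @return `em`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  v <- em$values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    stop("expression matrix must carry probe IDs (rownames) and sample IDs (colnames)")
  if (anyDuplicated(rownames(v)))
    stop("duplicate probe_id: ", rownames(v)[duplicated(rownames(v))][1L])
  if (anyDuplicated(colnames(v)))
    stop("duplicate sample_id: ", colnames(v)[duplicated(colnames(v))][1L])
  if (length(em$gene_symbols) != nrow(v))
    stop("gene_symbols length (", length(em$gene_symbols),
         ") != probe count (", nrow(v), ")")
  if (length(em$is_control) != nrow(v))
    stop("is_control length (", length(em$is_control),
         ") != probe count (", nrow(v), ")")
  if (anyNA(v)) stop("expression matrix contains missing values")
  if (anyNA(em$is_control)) stop("is_control contains missing values")
  if (!em$scale %in% c("raw", "log2")) stop("scale must be 'raw' or 'log2'")
  invisible(em)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples [%s scale], %d control probes\n",
              nrow(x$values), ncol(x$values), x$scale, sum(x$is_control)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

probe_ids <- function(em) rownames(em$values)
sample_ids <- function(em) colnames(em$values)

#' Subset an expression matrix
#'
#' @param em an `ExpressionMatrix`.
#' @param probes probe IDs, indices or a logical vector (default: all).
#' @param samples sample IDs, indices or a logical vector (default: all).
#' @return The subsetted `ExpressionMatrix`.
#' @export
em_subset <- function(em, probes = NULL, samples = NULL) {
  pidx <- if (is.null(probes)) seq_len(nrow(em$values)) else probes
  sidx <- if (is.null(samples)) seq_len(ncol(em$values)) else samples
  if (is.character(pidx)) {
    miss <- setdiff(pidx, rownames(em$values))
    if (length(miss)) stop("unknown probe_id: ", miss[1L])
    pidx <- match(pidx, rownames(em$values))
  }
  if (is.character(sidx)) {
    miss <- setdiff(sidx, colnames(em$values))
    if (length(miss)) stop("unknown sample_id: ", miss[1L])
    sidx <- match(sidx, colnames(em$values))
  }
  if (is.logical(pidx)) pidx <- which(pidx)
  if (is.logical(sidx)) sidx <- which(sidx)
  expression_matrix(em$values[pidx, sidx, drop = FALSE],
                    em$gene_symbols[pidx], em$is_control[pidx],
                    scale = em$scale)
}

#' Look up the expression vector of a gene
#'
#' Resolves a gene symbol to a single probe row. When several probes map to
#' the symbol the probe with the highest mean expression is used, mirroring
#' the common practice of designing qPCR primers against the
#' strongest-signal probe.
#'
#' @param em an `ExpressionMatrix`.
#' @param gene gene symbol.
#' @return Named numeric vector of expression values (one per sample).
#' @export
gene_values <- function(em, gene) {
  idx <- which(em$gene_symbols == gene & nzchar(em$gene_symbols))
  if (!length(idx)) stop("unknown gene: ", gene)
  if (length(idx) > 1L) idx <- idx[which.max(rowMeans(em$values[idx, , drop = FALSE]))]
  em$values[idx, ]
}

#' Write an expression matrix to TSV
#'
#' Layout: a `# scale: <raw|log2>` metadata header line, then a header row
#' (`probe_id`, `gene_symbol`, `is_control`, then one column per sample),
#' then one row per probe. A `.gz` suffix triggers transparent compression.
#'
#' @param em an `ExpressionMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  validate_expression_matrix(em)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scale: ", em$scale), con)
  header <- c("probe_id", "gene_symbol", "is_control", colnames(em$values))
  writeLines(paste(header, collapse = "\t"), con)
  body <- cbind(rownames(em$values), em$gene_symbols,
                ifelse(em$is_control, "1", "0"),
                format(em$values, digits = 15, trim = TRUE, scientific = FALSE))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Inverse of [write_expression_matrix()]. Duplicate probe or sample IDs,
#' ragged rows (wrong column count, reported with the offending line
#' number) and non-numeric or missing expression cells are format errors.
#'
#' @param path input file path (plain or gzip TSV).
#' @param scale optional override of the scale flag when the file lacks a
#'   `# scale:` header.
#' @return An `ExpressionMatrix`.
#' @export
read_expression_matrix <- function(path, scale = NULL) {
  lines <- read_lines_any(path)
  if (!length(lines)) stop("empty expression matrix file: ", path)
  file_scale <- NULL
  while (length(lines) && startsWith(lines[1L], "#")) {
    m <- regmatches(lines[1L], regexec("^#\\s*scale:\\s*(raw|log2)\\s*$", lines[1L]))[[1L]]
    if (length(m) == 2L) file_scale <- m[2L]
    lines <- lines[-1L]
  }
  scale <- scale %||% file_scale %||% "raw"
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 4L || !identical(header[1:3], c("probe_id", "gene_symbol", "is_control")))
    stop("expression matrix header must start with probe_id, gene_symbol, is_control")
  ncols <- length(header)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(body) != ncols)
  if (length(bad))
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 bad[1L] + 1L + (!is.null(file_scale)), ncols, lengths(body)[bad[1L]]))
  cells <- matrix(unlist(body), nrow = length(body), byrow = TRUE)
  vals <- suppressWarnings(matrix(as.numeric(cells[, -(1:3), drop = FALSE]),
                                  nrow = nrow(cells)))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing expression value at probe %s, sample %s",
                 cells[idx[1L], 1L], header[3L + idx[2L]]))
  }
  rownames(vals) <- cells[, 1L]
  colnames(vals) <- header[-(1:3)]
  expression_matrix(vals, cells[, 2L], cells[, 3L] %in% c("1", "TRUE", "true"),
                    scale = scale)
}

read_lines_any <- function(path) {
  con <- gzfile(path, "r")  # gzfile reads plain text transparently
  on.exit(close(con))
  readLines(con)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
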