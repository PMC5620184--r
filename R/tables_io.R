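#' Construct / validate a sample annotation table
#'
#' Per-sample clinical and technical annotations: patient and pairing IDs,
#' sample material (PBMC or DC), treatment center, tumor stage, overall
#' survival in months with an event flag (death observed vs censored), and
#' a timepoint label for longitudinal samples. Unknown columns are
#' preserved as opaque annotations.
#'
#' @param df a data.frame with at least `sample_id`, `material`, `center`,
#'   `survival_months`, `event`. Optional: `patient_id`, `stage`,
#'   `timepoint`, `pairing_id` (filled with `NA` when absent).
#' @return The validated data.frame with class `SampleTable`.
#' @export
sample_table <- function(df) {
  required <- c("sample_id", "material", "center", "survival_months", "event")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing column: ", miss[1L])
  for (opt in c("patient_id", "stage", "timepoint", "pairing_id"))
    if (!opt %in% names(df)) df[[opt]] <- NA_character_
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1L])
  if (!all(df$material %in% c("PBMC", "DC")))
    stop("material must be 'PBMC' or 'DC'")
  df$survival_months <- as.numeric(df$survival_months)
  if (anyNA(df$survival_months) || any(df$survival_months < 0))
    stop("survival_months must be non-negative")
  ev <- df$event
  if (is.character(ev)) ev <- toupper(trimws(ev))
  ok1 <- ev %in% c("1", "TRUE", 1, TRUE)
  ok0 <- ev %in% c("0", "FALSE", 0, FALSE)
  if (!all(ok1 | ok0)) stop("event column must be coded 0/1 or TRUE/FALSE")
  df$event <- ok1
  # every DC sample's pairing_id must match exactly one PBMC sample, when used
  dc <- df[df$material == "DC" & !is.na(df$pairing_id), , drop = FALSE]
  if (nrow(dc)) {
    pb <- df[df$material == "PBMC", , drop = FALSE]
    n_match <- vapply(dc$pairing_id,
                      function(p) sum(pb$pairing_id == p, na.rm = TRUE), 0L)
    if (any(n_match != 1L))
      stop("DC sample ", dc$sample_id[n_match != 1L][1L],
           " does not pair with exactly one PBMC sample")
  }
  class(df) <- c("SampleTable", "data.frame")
  df
}

#' Read a sample annotation table from TSV
#'
#' @param path TSV file with one header row; see [sample_table()] for the
#'   required columns.
#' @return A `SampleTable`.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  sample_table(df)
}

#' Write a sample annotation table to TSV
#' @param st a `SampleTable`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(st, path) {
  out <- as.data.frame(st)
  out$event <- as.integer(out$event)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct / validate a qPCR Ct table
#'
#' Long-format cycle-threshold measurements: one row per well, identified
#' by sample, gene and replicate index. Valid wells have 0 < Ct < 50;
#' missing wells are representable as `NA` and are excluded from replicate
#' means.
#'
#' @param df a data.frame with columns `sample_id`, `gene`, `ct` and
#'   optionally `replicate` (defaults to 1).
#' @return The validated data.frame with class `CtTable`.
#' @export
ct_table <- function(df) {
  required <- c("sample_id", "gene", "ct")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing column: ", miss[1L])
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  df$sample_id <- as.character(df$sample_id)
  df$gene <- as.character(df$gene)
  df$ct <- as.numeric(df$ct)
  df$replicate <- as.integer(df$replicate)
  bad <- !is.na(df$ct) & (df$ct <= 0 | df$ct >= 50)
  if (any(bad))
    stop(sprintf("Ct out of range (0, 50) for sample %s gene %s: %.2f",
                 df$sample_id[bad][1L], df$gene[bad][1L], df$ct[bad][1L]))
  class(df) <- c("CtTable", "data.frame")
  df
}

#' Read a long-format Ct table from TSV
#' @param path TSV with columns sample_id, gene, ct and optional replicate.
#' @return A `CtTable`.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  ct_table(df)
}

#' Write a Ct table to TSV
#' @param ct a `CtTable`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.table(as.data.frame(ct), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then member gene symbols, all
#' tab-separated (the Broad convention used for blood transcriptional
#' module collections). Duplicate genes within a set are collapsed.
#'
#' @param path GMT file.
#' @return A named list of character vectors (class `GeneSetCollection`)
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- read_lines_any(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has %d fields; need name, description and >= 1 gene",
                 short[1L], lengths(fields)[short[1L]]))
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set name: ", names(sets)[duplicated(names(sets))][1L])
  if (any(lengths(sets) == 0L))
    stop("empty gene set: ", names(sets)[lengths(sets) == 0L][1L])
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[`, "", 2L),
                                                names(sets))
  class(sets) <- "GeneSetCollection"
  sets
}

#' Write a gene-set collection to GMT
#' @param sets named list of character vectors; an optional `descriptions`
#'   attribute supplies the second GMT column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
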