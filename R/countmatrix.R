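#' Read a count matrix from TSV
#'
#' Expects a tab-delimited file whose first column is `gene_id` and whose
#' header row names the samples. Values must be non-negative; raw count
#' matrices are integer-valued.
#'
#' @param path TSV file path.
#' @param region_type `"exon"` or `"intron"`; stored as an attribute.
#' @return Numeric matrix (genes x samples) with dimnames and attribute
#'   `region_type`.
#' @export
read_count_matrix <- function(path, region_type = c("exon", "intron")) {
  region_type <- match.arg(region_type)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count matrix needs gene_id plus >= 1 sample: ", path)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicated gene_id '", genes[duplicated(genes)][1], "' in ", path)
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicated sample id '", samples[duplicated(samples)][1],
         "' in ", path)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-numeric value in column '", samples[bad], "' of ", path)
  }
  if (anyNA(m)) {
    w <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing/non-numeric value at gene '", genes[w[1]], "', sample '",
         samples[w[2]], "' in ", path)
  }
  if (any(m < 0)) {
    w <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative count at gene '", genes[w[1]], "', sample '",
         samples[w[2]], "' in ", path)
  }
  dimnames(m) <- list(genes, samples)
  attr(m, "region_type") <- region_type
  m
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_count_matrix()]: first column `gene_id`, then one
#' column per sample.
#'
#' @param m Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pair exon and intron count matrices on shared genes and samples
#'
#' Restricts both matrices to the intersection of their gene and sample
#' sets, in identical order, producing the matched container every
#' downstream measure works from. Genes or samples present in only one
#' matrix are dropped and reported in the `dropped_*` components.
#'
#' @param exon,intron Count matrices (genes x samples) as returned by
#'   [read_count_matrix()] or [build_matrices()].
#' @param calibrated Logical; `TRUE` once size factors have been applied
#'   (values then real, not integer).
#' @return A `matched_counts` object: list with `exon`, `intron` (matrices
#'   over identical dimnames), `calibrated`, `dropped_genes`,
#'   `dropped_samples`.
#' @export
align_matrices <- function(exon, intron, calibrated = FALSE) {
  genes <- intersect(rownames(exon), rownames(intron))
  samples <- intersect(colnames(exon), colnames(intron))
  if (length(genes) == 0) stop("no genes shared between exon and intron matrices")
  if (length(samples) == 0) stop("no samples shared between exon and intron matrices")
  dropped_genes <- setdiff(union(rownames(exon), rownames(intron)), genes)
  dropped_samples <- setdiff(union(colnames(exon), colnames(intron)), samples)
  structure(
    list(exon = exon[genes, samples, drop = FALSE],
         intron = intron[genes, samples, drop = FALSE],
         calibrated = calibrated,
         dropped_genes = dropped_genes,
         dropped_samples = dropped_samples),
    class = "matched_counts")
}

#' @export
print.matched_counts <- function(x, ...) {
  cat(sprintf("matched_counts: %d genes x %d samples (%s)\n",
              nrow(x$exon), ncol(x$exon),
              if (x$calibrated) "calibrated" else "raw"))
  if (length(x$dropped_genes) > 0) {
    cat("  dropped genes:", length(x$dropped_genes), "\n")
  }
  invisible(x)
}

#' Read a two-group sample sheet
#'
#' TSV with columns `sample_id` and `condition` (`control` / `case`).
#'
#' @param path TSV path.
#' @return Data frame with `sample_id`, `condition` (factor).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% colnames(df))) {
    stop("sample sheet must have columns sample_id and condition: ", path)
  }
  sample_sheet(df$sample_id, df$condition)
}

#' Construct and validate a sample sheet
#'
#' @param sample_id Character vector of sample ids.
#' @param condition Character vector, `"control"` or `"case"`.
#' @return Validated data frame.
#' @export
sample_sheet <- function(sample_id, condition) {
  if (anyDuplicated(sample_id)) stop("duplicated sample ids in sample sheet")
  if (!all(condition %in% c("control", "case"))) {
    stop("condition must be 'control' or 'case'")
  }
  tab <- table(factor(condition, levels = c("control", "case")))
  if (any(tab < 4)) {
    stop("each condition needs >= 4 samples (correlation tests require it); ",
         "got control=", tab["control"], " case=", tab["case"])
  }
  data.frame(sample_id = as.character(sample_id),
             condition = factor(condition, levels = c("control", "case")),
             stringsAsFactors = FALSE)
}
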