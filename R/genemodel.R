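#' Gene model with exon-union and intron intervals
#'
#' A `gene_model` holds, for one gene, the union of its exons across all
#' transcripts together with the complementary intron intervals inside the
#' gene span. All coordinates are 0-based half-open (`[start, end)`);
#' conversion from 1-based closed GTF coordinates happens in [parse_gtf()].
#'
#' A genomic position inside the gene span counts as intronic only if it is
#' covered by no transcript's exon — the conservative partition that never
#' mislabels exonic sequence as intronic.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of exon coordinates,
#'   0-based half-open, one entry per (possibly overlapping) exon record.
#' @return An object of class `gene_model` with components `gene_id`,
#'   `chrom`, `strand`, `exons` and `introns` (two-column integer matrices
#'   with columns `start`, `end`), and `span` (length-2 integer vector).
#' @examples
#' gm <- gene_model("g1", "chr1", "+", c(99, 149, 399), c(200, 300, 500))
#' gm$exons    # merged: [99,300) and [399,500)
#' gm$introns  # the gap [300,399)
#' @export
gene_model <- function(gene_id, chrom, strand, exon_starts, exon_ends) {
  stopifnot(length(exon_starts) == length(exon_ends), length(exon_starts) >= 1)
  if (any(exon_ends <= exon_starts)) {
    stop("gene ", gene_id, ": exon end must exceed start (0-based half-open)")
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = exon_starts + 1L,
                                         end = exon_ends))
  exons <- cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  n <- nrow(exons)
  if (n > 1) {
    introns <- cbind(start = exons[-n, "end"], end = exons[-1, "start"])
  } else {
    introns <- cbind(start = integer(0), end = integer(0))
  }
  structure(
    list(gene_id = as.character(gene_id), chrom = as.character(chrom),
         strand = strand, exons = exons, introns = introns,
         span = c(exons[1, "start"], exons[n, "end"])),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s): %d exon(s), %d intron(s), span [%d,%d)\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons), nrow(x$introns),
              x$span[1], x$span[2]))
  invisible(x)
}

#' Parse a GTF gene annotation into gene models
#'
#' Reads an Ensembl-dialect GTF, keeps `feature_filter` records (exons by
#' default), and builds one [gene_model()] per gene: exons of all
#' transcripts are unioned and introns are the complementary gaps within
#' the gene span. GTF's 1-based closed intervals are converted to the
#' package's 0-based half-open convention at this boundary.
#'
#' Genes whose exon records disagree on chromosome or strand are excluded
#' with a warning rather than repaired.
#'
#' @param path Path to a GTF file.
#' @param feature_filter Feature type to use (column 3), default `"exon"`.
#' @return Named list of `gene_model` objects (names are gene ids).
#' @export
parse_gtf <- function(path, feature_filter = "exon") {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  feats <- vapply(strsplit(lines[body], "\t", fixed = TRUE), function(f) {
    if (length(f) >= 3) f[3] else NA_character_
  }, character(1))
  sel <- which(body)[!is.na(feats) & feats == feature_filter]
  if (length(sel) == 0) {
    stop("no '", feature_filter, "' features in ", path)
  }
  bad <- sel[!grepl("gene_id", lines[sel], fixed = TRUE)]
  if (length(bad) > 0) {
    stop("malformed attribute string (no gene_id) at line ", bad[1],
         " of ", path)
  }
  gr <- rtracklayer::import(path, format = "gtf",
                            feature.type = feature_filter)
  gid <- S4Vectors::mcols(gr)$gene_id
  if (is.null(gid) || anyNA(gid)) {
    stop("malformed attribute string: gene_id missing after import of ", path)
  }
  idx <- split(seq_along(gr), gid)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  models <- list()
  dropped <- character(0)
  for (g in names(idx)) {
    i <- idx[[g]]
    if (length(unique(chrom[i])) > 1 || length(unique(strand[i])) > 1) {
      dropped <- c(dropped, g)
      next
    }
    models[[g]] <- gene_model(
      g, chrom[i][1], strand[i][1],
      exon_starts = GenomicRanges::start(gr)[i] - 1L,
      exon_ends = GenomicRanges::end(gr)[i])
  }
  if (length(dropped) > 0) {
    warning("excluded ", length(dropped),
            " gene(s) with exons on multiple chromosomes/strands: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  }
  models
}
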