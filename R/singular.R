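#' Aligned reference blocks of a gapped alignment
#'
#' Expands a CIGAR string into the reference intervals covered by the
#' alignment. `M`, `=`, `X` and `D` operations extend the current block;
#' `N` (spliced gap) closes it and opens a new one; `I`, `S`, `H`, `P`
#' consume no reference.
#'
#' @param cigar CIGAR string.
#' @param start 0-based reference start of the alignment.
#' @return Two-column integer matrix (`start`, `end`), 0-based half-open,
#'   sorted and non-overlapping.
#' @export
cigar_blocks <- function(cigar, start) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(ops) == 0 || sum(nchar(ops)) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- substr(ops, nchar(ops), nchar(ops))
  pos <- as.integer(start)
  bs <- integer(0); be <- integer(0)
  cur <- NA_integer_
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X", "D")) {
      if (is.na(cur)) cur <- pos
      pos <- pos + len[i]
    } else if (op[i] == "N") {
      if (!is.na(cur)) { bs <- c(bs, cur); be <- c(be, pos); cur <- NA_integer_ }
      pos <- pos + len[i]
    }
    # I/S/H/P: no reference advance
  }
  if (!is.na(cur)) { bs <- c(bs, cur); be <- c(be, pos) }
  cbind(start = bs, end = be)
}

#' Classify a read placement against one gene model
#'
#' A read is `exonic` if any aligned block overlaps at least one exonic
#' base of the gene, `intronic` if all blocks lie within the gene span and
#' overlap zero exonic bases, and `outside` otherwise. Reads straddling an
#' exon/intron boundary are therefore exonic. Strand is ignored
#' (unstranded counting).
#'
#' @param read List or one-row data frame with `chrom` and either a
#'   `blocks` matrix (as from [cigar_blocks()]) or `start` + `cigar`.
#' @param model A [gene_model()].
#' @return One of `"exonic"`, `"intronic"`, `"outside"`.
#' @export
classify_read <- function(read, model) {
  if (read$chrom[1] != model$chrom) return("outside")
  blocks <- if (!is.null(read$blocks)) read$blocks
            else cigar_blocks(read$cigar[1], read$start[1])
  ex <- model$exons
  for (b in seq_len(nrow(blocks))) {
    if (any(pmin(blocks[b, 2], ex[, 2]) > pmax(blocks[b, 1], ex[, 1]))) {
      return("exonic")
    }
  }
  inside <- all(blocks[, 1] >= model$span[1] & blocks[, 2] <= model$span[2])
  if (inside) "intronic" else "outside"
}

.blocks_granges <- function(reads) {
  bl <- mapply(cigar_blocks, reads$cigar, reads$start, SIMPLIFY = FALSE)
  nb <- vapply(bl, nrow, integer(1))
  bm <- do.call(rbind, bl)
  GenomicRanges::GRanges(
    seqnames = rep(reads$chrom, nb),
    ranges = IRanges::IRanges(start = bm[, "start"] + 1L, end = bm[, "end"]),
    read = rep(seq_len(nrow(reads)), nb))
}

#' Singular exon/intron counting for one sample
#'
#' Accumulates per-gene "singular" counts from read placements under the
#' two quality gates: only reads with `mapq >= mapq_min` contribute to
#' exon/intron counts, and a gene is flagged non-singular when its
#' lower-quality (alternative) reads exceed `alt_frac_max` of its total.
#' A read overlapping the spans of two or more genes is discarded; reads
#' on chromosomes absent from the models, or falling outside every gene,
#' land in the `unassigned` tally. Counting is unstranded and single-end:
#' each placement is one count.
#'
#' @param reads Data frame of read placements with columns `read_id`,
#'   `chrom`, `start` (0-based), `cigar`, `mapq` (and optionally
#'   `sample_id`), e.g. from [read_sam()] or [read_alignment_tsv()].
#' @param models Named list of [gene_model()] objects.
#' @param mapq_min Minimum MAPQ for a high-quality count (default 40).
#' @param alt_frac_max Maximum tolerated fraction of low-quality reads per
#'   gene (default 0.01, the 1\% rule).
#' @return List with `exon` and `intron` (named integer vectors over genes
#'   passing the singular audit), `audits` (data frame: `gene_id`,
#'   `high_q_exon`, `high_q_intron`, `low_q_total`, `singular`), and
#'   `unassigned` (count of reads assigned to no gene).
#' @export
count_sample <- function(reads, models, mapq_min = 40, alt_frac_max = 0.01) {
  stopifnot(is.data.frame(reads), length(models) >= 1)
  gene_ids <- vapply(models, `[[`, character(1), "gene_id")
  n_reads <- nrow(reads)
  audits <- data.frame(
    gene_id = gene_ids,
    high_q_exon = 0L, high_q_intron = 0L, low_q_total = 0L,
    stringsAsFactors = FALSE, row.names = NULL)
  unassigned <- n_reads
  if (n_reads > 0) {
    spans <- GenomicRanges::GRanges(
      seqnames = vapply(models, `[[`, character(1), "chrom"),
      ranges = IRanges::IRanges(
        start = vapply(models, function(m) m$span[1], numeric(1)) + 1L,
        end = vapply(models, function(m) m$span[2], numeric(1))))
    exn <- lapply(models, `[[`, "exons")
    nex <- vapply(exn, nrow, integer(1))
    exm <- do.call(rbind, exn)
    exons_gr <- GenomicRanges::GRanges(
      seqnames = rep(vapply(models, `[[`, character(1), "chrom"), nex),
      ranges = IRanges::IRanges(start = exm[, "start"] + 1L, end = exm[, "end"]),
      gene = rep(seq_along(models), nex))
    bgr <- .blocks_granges(reads)
    ov <- GenomicRanges::findOverlaps(bgr, spans, ignore.strand = TRUE)
    pair <- unique(data.frame(
      read = S4Vectors::mcols(bgr)$read[S4Vectors::queryHits(ov)],
      gene = S4Vectors::subjectHits(ov)))
    hits_per_read <- table(pair$read)
    single <- as.integer(names(hits_per_read)[hits_per_read == 1])
    pair <- pair[pair$read %in% single, , drop = FALSE]
    if (nrow(pair) > 0) {
      # exonic: any block of the read overlaps an exon of its assigned gene
      sel <- S4Vectors::mcols(bgr)$read %in% pair$read
      bsel <- bgr[sel]
      ov2 <- GenomicRanges::findOverlaps(bsel, exons_gr, ignore.strand = TRUE)
      g_of <- pair$gene[match(S4Vectors::mcols(bsel)$read, pair$read)]
      same <- g_of[S4Vectors::queryHits(ov2)] ==
        S4Vectors::mcols(exons_gr)$gene[S4Vectors::subjectHits(ov2)]
      exonic_reads <- unique(
        S4Vectors::mcols(bsel)$read[S4Vectors::queryHits(ov2)[same]])
      # containment in span (for the intronic / outside split)
      sp <- spans[g_of]
      contained <- GenomicRanges::start(bsel) >= GenomicRanges::start(sp) &
        GenomicRanges::end(bsel) <= GenomicRanges::end(sp)
      all_in <- tapply(contained, S4Vectors::mcols(bsel)$read, all)
      cls <- ifelse(pair$read %in% exonic_reads, "exonic",
                    ifelse(all_in[as.character(pair$read)], "intronic",
                           "outside"))
      keep <- cls != "outside"
      pr <- pair[keep, , drop = FALSE]
      cls <- cls[keep]
      hq <- reads$mapq[pr$read] >= mapq_min
      unassigned <- n_reads - nrow(pr)
      add <- function(idx) tabulate(idx, nbins = length(models))
      audits$high_q_exon <- add(pr$gene[hq & cls == "exonic"])
      audits$high_q_intron <- add(pr$gene[hq & cls == "intronic"])
      audits$low_q_total <- add(pr$gene[!hq])
    }
  }
  tot <- audits$high_q_exon + audits$high_q_intron + audits$low_q_total
  audits$singular <- (audits$high_q_exon + audits$high_q_intron > 0) &
    (audits$low_q_total <= alt_frac_max * tot)
  ok <- audits$singular
  list(exon = stats::setNames(audits$high_q_exon[ok], audits$gene_id[ok]),
       intron = stats::setNames(audits$high_q_intron[ok], audits$gene_id[ok]),
       audits = audits, unassigned = unassigned)
}

#' Assemble matched count matrices from per-sample singular counts
#'
#' Keeps only genes that pass the singular audit in every sample; the
#' resulting exon and intron matrices share gene and sample ordering.
#'
#' @param per_sample Named list (one element per sample) of
#'   [count_sample()] results.
#' @return A `matched_counts` object (raw, uncalibrated).
#' @export
build_matrices <- function(per_sample) {
  if (length(per_sample) < 2) stop("need >= 2 samples to build matrices")
  sample_ids <- names(per_sample)
  if (is.null(sample_ids) || any(!nzchar(sample_ids))) {
    stop("per_sample list must be named by sample id")
  }
  sing <- lapply(per_sample, function(s) {
    s$audits$gene_id[s$audits$singular]
  })
  genes <- Reduce(intersect, sing)
  if (length(genes) == 0) {
    stop("no gene is singular in every sample; consider relaxing mapq_min ",
         "or alt_frac_max")
  }
  grab <- function(field) {
    m <- vapply(per_sample, function(s) {
      v <- s[[field]][genes]
      v[is.na(v)] <- 0L
      as.numeric(v)
    }, numeric(length(genes)))
    m <- matrix(m, nrow = length(genes),
                dimnames = list(genes, sample_ids))
    m
  }
  align_matrices(grab("exon"), grab("intron"), calibrated = FALSE)
}

#' Read alignments from a text SAM file
#'
#' Minimal SAM reader for the fields singular counting needs (read id,
#' chromosome, 0-based start, CIGAR, MAPQ). Unmapped records are skipped.
#'
#' @param path SAM file path.
#' @param sample_id Sample id to attach to every read.
#' @return Data frame of read placements for [count_sample()].
#' @export
read_sam <- function(path, sample_id = NA_character_) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(f, length, integer(1)) < 6
  if (any(short)) stop("malformed SAM record (fewer than 6 fields) in ", path)
  flag <- as.integer(vapply(f, `[[`, character(1), 2))
  rname <- vapply(f, `[[`, character(1), 3)
  keep <- bitwAnd(flag, 4L) == 0L & rname != "*"
  data.frame(
    read_id = vapply(f, `[[`, character(1), 1)[keep],
    chrom = rname[keep],
    start = as.integer(vapply(f, `[[`, character(1), 4))[keep] - 1L,
    cigar = vapply(f, `[[`, character(1), 6)[keep],
    mapq = as.integer(vapply(f, `[[`, character(1), 5))[keep],
    sample_id = sample_id,
    stringsAsFactors = FALSE)
}

#' Read the simplified tabular alignment format
#'
#' TSV with columns `read_id`, `chrom`, `start` (0-based), `cigar`,
#' `mapq`, `sample_id` — a convenience fixture format equivalent to the
#' SAM fields used by [count_sample()].
#'
#' @param path TSV path.
#' @return Data frame of read placements.
#' @export
read_alignment_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("read_id", "chrom", "start", "cigar", "mapq", "sample_id")
  if (!all(need %in% colnames(df))) {
    stop("alignment TSV must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

#' Write read placements as a text SAM file
#'
#' @param reads Read placement data frame (see [read_alignment_tsv()]).
#' @param path Output path.
#' @param chrom_lengths Named integer vector for the `@SQ` header lines.
#' @export
write_sam <- function(reads, path, chrom_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  rec <- sprintf("%s\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                 reads$read_id, reads$chrom, reads$start + 1L,
                 reads$mapq, reads$cigar)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
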