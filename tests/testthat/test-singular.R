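test_that("CIGAR strings expand to the right reference blocks", {
  expect_equal(cigar_blocks("50M", 100), cbind(start = 100, end = 150))
  # N splits blocks, D extends them, I/S consume no reference
  expect_equal(cigar_blocks("10M5N10M", 0),
               cbind(start = c(0, 15), end = c(10, 25)))
  expect_equal(cigar_blocks("5M2D5M", 10), cbind(start = 10, end = 22))
  expect_equal(cigar_blocks("5S10M3I10M", 50), cbind(start = 50, end = 70))
  expect_error(cigar_blocks("10Q", 0), "malformed CIGAR")
})

test_that("reads classify as exonic, intronic or outside", {
  m <- make_test_models()$gA  # exons [99,300) [399,500), intron [300,399)
  r <- function(start, cigar, chrom = "chr1") {
    list(chrom = chrom, start = start, cigar = cigar)
  }
  expect_equal(classify_read(r(150, "30M"), m), "exonic")
  expect_equal(classify_read(r(310, "40M"), m), "intronic")
  # boundary straddle: touches one exonic base -> exonic
  expect_equal(classify_read(r(290, "20M"), m), "exonic")
  expect_equal(classify_read(r(600, "30M"), m), "outside")
  expect_equal(classify_read(r(150, "30M", chrom = "chr9"), m), "outside")
  # spliced read over the intron touching both exons
  expect_equal(classify_read(r(290, "10M99N10M"), m), "exonic")
})

test_that("classify_read agrees with a per-base coverage oracle", {
  set.seed(99)
  for (i in 1:300) {
    k <- sample(1:4, 1)
    starts <- sort(sample(0:800, k))
    ends <- pmin(starts + sample(20:150, k, replace = TRUE), 1000)
    m <- gene_model("g", "chr1", "+", starts, ends)
    for (j in 1:10) {
      s <- sample(0:990, 1)
      cigar <- if (stats::runif(1) < 0.3) {
        sprintf("%dM%dN%dM", sample(5:20, 1), sample(5:50, 1), sample(5:20, 1))
      } else {
        sprintf("%dM", sample(10:80, 1))
      }
      blocks <- cigar_blocks(cigar, s)
      got <- classify_read(list(chrom = "chr1", blocks = blocks), m)
      expect_identical(got, classify_oracle(blocks, m))
    }
  }
})

test_that("singular counting applies the MAPQ and 1% alternative-count gates", {
  models <- make_test_models()
  # 100 clean exonic reads on gA -> singular
  clean <- simulate_alignments(models["gA"], c(gA = 100), c(gA = 0))
  out <- count_sample(clean, models)
  expect_equal(unname(out$exon["gA"]), 100)
  expect_true(out$audits$singular[out$audits$gene_id == "gA"])
  # 99 high + 2 low-quality reads: 2/101 > 1% -> not singular
  dirty <- simulate_alignments(models["gA"], c(gA = 74), c(gA = 25),
                               low_q_reads = c(gA = 2))
  out2 <- count_sample(dirty, models)
  aud <- out2$audits[out2$audits$gene_id == "gA", ]
  expect_equal(aud$high_q_exon + aud$high_q_intron, 99)
  expect_equal(aud$low_q_total, 2)
  expect_false(aud$singular)
  expect_false("gA" %in% names(out2$exon))
  # exactly at the 1% boundary: 1 low of 100 total -> still singular
  edge <- simulate_alignments(models["gA"], c(gA = 99), c(gA = 0),
                              low_q_reads = c(gA = 1))
  out3 <- count_sample(edge, models)
  expect_true(out3$audits$singular[out3$audits$gene_id == "gA"])
})

test_that("reads spanning two genes are discarded and unknown chroms tallied", {
  close_models <- list(
    g1 = gene_model("g1", "chr1", "+", 0, 100),
    g2 = gene_model("g2", "chr1", "+", 120, 220))
  # read [90, 140) overlaps both spans -> contributes to neither
  reads <- data.frame(read_id = c("r1", "r2"), chrom = c("chr1", "chrUn"),
                      start = c(90, 10), cigar = c("50M", "50M"),
                      mapq = c(60, 60), sample_id = "s1",
                      stringsAsFactors = FALSE)
  out <- count_sample(reads, close_models)
  expect_equal(sum(out$audits$high_q_exon), 0)
  expect_equal(out$unassigned, 2)
})

test_that("read tallies are conserved across categories", {
  models <- make_test_models()
  set.seed(5)
  reads <- simulate_alignments(models, c(gA = 40, gB = 30, gC = 20),
                               c(gA = 10, gB = 5, gC = 0),
                               low_q_reads = c(gA = 3),
                               deterministic = FALSE, seed = 5)
  extra <- data.frame(read_id = "stray", chrom = "chr7", start = 0,
                      cigar = "50M", mapq = 60, sample_id = "s1",
                      stringsAsFactors = FALSE)
  reads <- rbind(reads, extra)
  out <- count_sample(reads, models)
  tallied <- sum(out$audits$high_q_exon) + sum(out$audits$high_q_intron) +
    sum(out$audits$low_q_total) + out$unassigned
  expect_equal(tallied, nrow(reads))
})

test_that("quality gates are monotone in their thresholds", {
  models <- make_test_models()
  reads <- simulate_alignments(models, c(gA = 50, gB = 40), c(gA = 20, gB = 10),
                               low_q_reads = c(gA = 1, gB = 1))
  strict <- count_sample(reads, models, mapq_min = 70)
  loose <- count_sample(reads, models, mapq_min = 40)
  expect_true(all(strict$audits$high_q_exon <= loose$audits$high_q_exon))
  tight <- count_sample(reads, models, alt_frac_max = 0.001)
  wide <- count_sample(reads, models, alt_frac_max = 0.05)
  expect_true(all(names(tight$exon) %in% names(wide$exon)))
})

test_that("matrices keep only genes singular in every sample", {
  models <- make_test_models()
  s1 <- count_sample(simulate_alignments(models, c(gA = 50, gB = 50),
                                         c(gA = 20, gB = 20)), models)
  s2 <- count_sample(simulate_alignments(models, c(gA = 50, gB = 50),
                                         c(gA = 20, gB = 20),
                                         low_q_reads = c(gB = 5)), models)
  mc <- build_matrices(list(s1 = s1, s2 = s2))
  expect_equal(rownames(mc$exon), "gA")  # gB singular in s1 only
  expect_equal(unname(mc$exon["gA", ]), c(50, 50))
  expect_equal(unname(mc$intron["gA", ]), c(20, 20))
  expect_error(build_matrices(list()), ">= 2 samples")
  s_bad <- count_sample(simulate_alignments(models, c(gA = 50), c(gA = 0),
                                            low_q_reads = c(gA = 5)), models)
  expect_error(build_matrices(list(a = s_bad, b = s_bad)), "no gene")
})

test_that("SAM and tabular alignment formats round-trip", {
  models <- make_test_models()
  reads <- simulate_alignments(models, c(gA = 30, gC = 10), c(gA = 10, gC = 5))
  sam <- tempfile(fileext = ".sam")
  write_sam(reads, sam, c(chr1 = 2000, chr2 = 1000))
  back <- read_sam(sam, sample_id = "s1")
  expect_equal(back$start, reads$start)
  expect_equal(back$cigar, reads$cigar)
  expect_equal(back$mapq, reads$mapq)
  out_a <- count_sample(reads, models)
  out_b <- count_sample(back, models)
  expect_equal(out_a$exon, out_b$exon)
  expect_equal(out_a$intron, out_b$intron)
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(reads, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_alignment_tsv(tsv)$start, reads$start)
})
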