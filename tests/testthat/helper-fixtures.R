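# Shared fixture builders; everything generated in code, no binary files.

# two-gene toy annotation on one chromosome, plus one single-exon gene
make_test_models <- function() {
  list(
    gA = gene_model("gA", "chr1", "+", c(99, 149, 399), c(200, 300, 500)),
    gB = gene_model("gB", "chr1", "-", c(1000, 1500), c(1200, 1800)),
    gC = gene_model("gC", "chr2", "+", 50, 250))
}

# write a small Ensembl-dialect GTF (1-based closed coordinates)
write_test_gtf <- function(path, rows) {
  lines <- vapply(rows, function(r) {
    sprintf(paste0("%s\ttest\texon\t%d\t%d\t.\t%s\t.\t",
                   "gene_id \"%s\"; transcript_id \"%s\";"),
            r$chrom, r$start, r$end, r$strand, r$gene, r$tx)
  }, character(1))
  writeLines(c("#!genome-build test", lines), path)
}

# brute-force double-sum Gini oracle
gini_oracle <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n * (n - 1) * mean(x))
}

# per-base coverage oracle for read classification
classify_oracle <- function(blocks, model) {
  if (nrow(blocks) == 0) return("outside")
  bases <- unlist(lapply(seq_len(nrow(blocks)), function(b) {
    seq(blocks[b, 1], blocks[b, 2] - 1)
  }))
  exonic_bases <- unlist(lapply(seq_len(nrow(model$exons)), function(e) {
    seq(model$exons[e, 1], model$exons[e, 2] - 1)
  }))
  if (any(bases %in% exonic_bases)) return("exonic")
  if (all(bases >= model$span[1] & bases < model$span[2])) return("intronic")
  "outside"
}

# planted-cluster feature matrix: k prototype profiles + unit noise,
# separation `sep` noise-sd between prototypes, rows z-scored
planted_fm <- function(k, seed, n_genes = 200, d = 35, sep = 5) {
  set.seed(seed)
  proto <- matrix(stats::rnorm(k * d, sd = sep), k, d)
  lab <- rep(seq_len(k), length.out = n_genes)
  x <- proto[lab, ] + matrix(stats::rnorm(n_genes * d), n_genes, d)
  z <- t(scale(t(x)))
  rownames(z) <- sprintf("g%03d", seq_len(n_genes))
  attr(z, "labels") <- lab
  z
}

# all partitions of n elements as restricted-growth label vectors
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (b in seq_len(max(labels) + 1)) grow(c(labels, b))
  }
  grow(1L)
  out
}

# pair-counting ARI oracle: agreement over all unordered element pairs
ari_oracle <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  sa <- a[pairs[1, ]] == a[pairs[2, ]]
  sb <- b[pairs[1, ]] == b[pairs[2, ]]
  a11 <- sum(sa & sb); a00 <- sum(!sa & !sb)
  a10 <- sum(sa & !sb); a01 <- sum(!sa & sb)
  num <- 2 * (a11 * a00 - a10 * a01)
  den <- (a11 + a10) * (a10 + a00) + (a11 + a01) * (a01 + a00)
  if (den == 0) return(1)
  num / den
}

# planted noiseless spike fixture for calibration tests
make_spike_fixture <- function(n_samples = 10, seed = 7, depth = 10) {
  mix <- sim_ercc_mix()
  set.seed(seed)
  f <- exp(stats::rnorm(n_samples, 0, log(2)))
  f <- pmin(pmax(f, 0.25), 4)
  f <- f / exp(mean(log(f)))
  counts <- round(outer(mix * depth, f))
  colnames(counts) <- paste0("s", seq_len(n_samples))
  list(mix = mix, factors = f, counts = counts)
}
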