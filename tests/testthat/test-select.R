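rec <- function(E_p = NA, E_m = NA, I_p = NA, C_d = NA, G_e = NA, G_i = NA,
                gene_id = "g") {
  data.frame(gene_id = gene_id, E_p = E_p, E_m = E_m, I_p = I_p, C_d = C_d,
             G_e = G_e, G_i = G_i, stringsAsFactors = FALSE)
}

test_that("selection criteria follow the exon gate plus one secondary change", {
  cfg <- mei_config()
  # strong exon change with twofold shift: both criteria
  r1 <- evaluate_gene(rec(E_p = 1e-4, E_m = 2.5))
  expect_true(r1$standard_hit && r1$mei_hit)
  # sub-twofold expression change rescued by an exon Gini reduction
  r2 <- evaluate_gene(rec(E_p = 1e-4, E_m = 1.3, G_e = 0.4))
  expect_false(r2$standard_hit)
  expect_true(r2$mei_hit)
  expect_true(r2$flags[["Ge"]])
  # everything extreme but the exon gate fails: no hit of either kind
  r3 <- evaluate_gene(rec(E_p = 0.01, E_m = 10, I_p = 1e-9, C_d = 1e-9,
                          G_e = 5, G_i = 5))
  expect_false(r3$standard_hit || r3$mei_hit)
  # twofold is direction-agnostic
  expect_true(evaluate_gene(rec(E_p = 1e-4, E_m = 0.4))$standard_hit)
  # undefined measures are not evaluable, never hits
  ev <- evaluate_records(rec(E_p = 1e-4), cfg)
  expect_false(ev$mei_hit)
  expect_match(ev$not_evaluable, "G_e")
})

test_that("standard hits are always a subset of MEI hits", {
  set.seed(23)
  records <- do.call(rbind, lapply(1:300, function(i) {
    rec(E_p = runif(1), E_m = exp(rnorm(1)), I_p = runif(1),
        C_d = runif(1), G_e = exp(rnorm(1)), G_i = exp(rnorm(1)),
        gene_id = paste0("g", i))
  }))
  ev <- evaluate_records(records, mei_config(ep_alpha = 0.3))
  expect_true(all(!ev$standard_hit | ev$mei_hit))
})

test_that("relaxing any threshold never shrinks the MEI hit set", {
  set.seed(29)
  records <- do.call(rbind, lapply(1:400, function(i) {
    rec(E_p = runif(1), E_m = exp(rnorm(1)), I_p = runif(1),
        C_d = runif(1), G_e = exp(rnorm(1)), G_i = exp(rnorm(1)),
        gene_id = paste0("g", i))
  }))
  strict <- evaluate_records(records, mei_config())
  for (relaxed in list(mei_config(ep_alpha = 0.01),
                       mei_config(ip_alpha = 0.01),
                       mei_config(cd_alpha = 0.05),
                       mei_config(fold_min = 1.5),
                       mei_config(gini_fold_min = 1.2))) {
    loose <- evaluate_records(records, relaxed)
    expect_true(all(loose$mei_hit[strict$mei_hit]))
  }
})

test_that("the FDR diagnostic reproduces the BH admission threshold", {
  expect_equal(fdr_threshold_check(rep(1, 10), rep(1, 10), 0.1), 0)
  expect_equal(fdr_threshold_check(0.001, 0.001, 0.1), 0.001)
  set.seed(37)
  exon_p <- c(runif(3800), runif(200, 0, 1e-5))
  intron_p <- c(runif(3900), runif(100, 0, 1e-5))
  t <- fdr_threshold_check(exon_p, intron_p, 0.1)
  # oracle: largest p in each vector whose BH q-value clears 0.1
  cut_oracle <- function(p) {
    q <- stats::p.adjust(p, "BH")
    max(p[q <= 0.1])
  }
  expect_equal(t, min(cut_oracle(exon_p), cut_oracle(intron_p)))
  expect_lt(t, 0.01)
})

test_that("reports sort by coordinated-change count then exon p-value", {
  records <- rbind(
    rec(E_p = 5e-4, E_m = 1.2, G_e = 3, gene_id = "two_flags"),
    rec(E_p = 8e-4, E_m = 1.2, G_e = 3, G_i = 3, gene_id = "three_flags"),
    rec(E_p = 1e-6, E_m = 4, I_p = 1e-6, C_d = 1e-4, G_e = 4, G_i = 0.2,
        gene_id = "all_flags"),
    rec(E_p = 0.9, E_m = 1.0, gene_id = "nothing"))
  rep_ <- build_report(records)
  expect_equal(rep_$genes$gene_id[1], "all_flags")
  expect_equal(rep_$genes$gene_id[2], "three_flags")
  expect_equal(rep_$genes$gene_id[3], "two_flags")
  expect_equal(rep_$n_standard, 1)
  expect_equal(rep_$n_mei, 3)
  # empty input
  empty <- build_report(records[0, ])
  expect_equal(nrow(empty$genes), 0)
  expect_equal(empty$n_mei, 0)
  # watch list: secondary change without the exon gate
  watch <- build_report(rec(E_p = 0.5, G_i = 5, gene_id = "watched"))
  expect_equal(watch$watch_list, "watched")
  expect_equal(watch$n_mei, 0)
  tsv <- tempfile(fileext = ".tsv")
  write_report(rep_, tsv)
  expect_equal(utils::read.delim(tsv)$gene_id[1], "all_flags")
})

test_that("planted effect classes are recovered by their designed flags", {
  sim <- sim_mei_cohort(n_genes = 600, seed = 202)
  res <- run_mei(sim$matched$exon, sim$matched$intron, sim$sheet,
                 spike_counts = sim$spike_counts, mix = sim_ercc_mix())
  ev <- evaluate_records(res$measures)
  cls <- sim$truth$class[match(ev$gene_id, sim$truth$gene_id)]
  expect_gte(mean(ev$standard_hit[cls == "mean_shift"]), 0.8)
  expect_gte(mean((ev$Ge | ev$Gi)[cls == "gini_shift"]), 0.8)
  expect_gte(mean(ev$Cd[cls == "corr_break"]), 0.8)
  expect_lte(mean(ev$mei_hit[cls == "null"]), 0.01)
})
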