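# mei — matched change characterization for exons and introns

`mei` is an R package for coordinated differential analysis of **exon
and intron** read counts in two-group bulk RNA-Seq. Standard pipelines
test exonic mean shifts and discard most of what introns — the residue
of unprocessed transcripts — say about regulation. `mei` characterizes
each gene with six coordinated measures between control and case:

- `E_p`, `I_p` — p-values of the exon / intron count change under a
  negative binomial likelihood-ratio test (variance `μ + αμ²`, common ML
  dispersion, χ²₁ reference);
- `E_m` — exon mean fold change (case/control);
- `C_d` — Fisher-z p-value for the change in the exon:intron Pearson
  correlation, `Z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3))`;
- `G_e`, `G_i` — case/control ratios of the unbiased Gini coefficient
  `Σᵢⱼ|xᵢ−xⱼ| / (2n(n−1)x̄)` of exon / intron counts.

The *standard* selection is `E_p < 0.001` with a twofold `E_m`. The
*expanded* (MEI) selection keeps the `E_p` gate but accepts any one
secondary change — twofold `E_m`, `I_p < 0.001`, `C_d < 0.005`, or a
twofold Gini ratio in either direction — so genes whose regulation
shifts through variability or exon–intron decoupling are recovered.

Upstream of the statistics the package provides: quality-gated
**singular counting** from alignments (MAPQ ≥ 40, single-gene reads
only, ≤1% low-quality alternatives per gene and sample), exon-union /
intron interval derivation from GTF, **ERCC spike-in calibration** (a
shared-slope robust proportional model with outlier pruning; median-ratio
fallback), **correlation-distance K-means** clustering of exon-only and
exon/intron-ratio co-expression profiles with automatic cluster-number
selection, and a fully seeded **synthetic cohort generator** with ground
truth for every measure.

## Worked example

A synthetic 12-vs-46 cohort with 500 genes (5% mean-shift, 5%
variability-shift, 5% correlation-break, 85% null) and ERCC spike-ins,
run through the full pipeline:

```r
library(mei)
sim <- sim_mei_cohort(n_genes = 500, seed = 1)
res <- run_mei(sim$matched$exon, sim$matched$intron, sim$sheet,
               spike_counts = sim$spike_counts, mix = sim_ercc_mix())
res$report
#> MEI selection report: 500 genes evaluated
#>   standard hits (Ep & twofold): 25
#>   MEI hits (Ep & >=1 secondary): 26
#>   watch list (secondary only): 54
#>   flag counts:
#> Ep Em Ip Cd Ge Gi
#> 26 25 26 25 27 26

head(res$report$genes[, c("gene_id","E_p","E_m","I_p","C_d","G_e","G_i","n_flags")], 3)
#>     gene_id      E_p   E_m      I_p   C_d   G_e   G_i n_flags
#> 1 gene_0018 2.78e-39 0.279 4.86e-45 0.709 0.862 0.768       3
#> 2 gene_0008 4.53e-35 0.271 2.18e-35 0.485 0.958 1.109       3
#> 3 gene_0012 1.26e-27 0.294 1.74e-24 0.509 1.075 1.151       3

res$fdr_threshold   # per-test p implied by a 0.1 FDR on both region types
#> [1] 0.00229
```

Reading the output: 25 genes pass the standard fold-change criterion and
26 the expanded one (the standard set is always contained in the
expanded set). The top genes change in both exon and intron counts
(`E_p`, `I_p` tiny) with ~3.5-fold reductions (`E_m ≈ 0.28`); 54 genes
show a secondary change without exon significance and are reported on
the watch list, not as hits. The genes ground-truth classes live in
`sim$truth`.

Command-line wrappers over the same functions are installed under
`inst/scripts/`: `mei-simulate.R` writes a cohort as TSVs, and
`mei-run.R` takes exon/intron/sample-sheet TSVs (plus optional spike
counts and mix) and writes the report, measures, size factors, cluster
assignments and a log.

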