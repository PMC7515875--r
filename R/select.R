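#' Selection thresholds for differential analysis
#'
#' Defaults follow the study design this package implements: exon and
#' intron NB p-value gates at 0.001 (the level a 0.1 FDR translates to on
#' both exon and intron data, see [fdr_threshold_check()]), correlation
#' differential at 0.005, twofold mean change and twofold Gini change
#' (both direction-agnostic).
#'
#' @param ep_alpha Exon NB p-value gate (default 0.001).
#' @param ip_alpha Intron NB p-value gate (default 0.001).
#' @param cd_alpha Correlation-differential p gate (default 0.005).
#' @param fold_min Minimum mean fold change, either direction (default 2).
#' @param gini_fold_min Minimum Gini ratio change, either direction
#'   (default 2).
#' @param fdr_target FDR used by the diagnostic threshold check
#'   (default 0.1).
#' @return A `mei_config` list.
#' @export
mei_config <- function(ep_alpha = 0.001, ip_alpha = 0.001, cd_alpha = 0.005,
                       fold_min = 2.0, gini_fold_min = 2.0,
                       fdr_target = 0.1) {
  stopifnot(ep_alpha > 0, ep_alpha <= 1, ip_alpha > 0, ip_alpha <= 1,
            cd_alpha > 0, cd_alpha <= 1, fold_min > 1, gini_fold_min > 1,
            fdr_target > 0, fdr_target <= 1)
  structure(list(ep_alpha = ep_alpha, ip_alpha = ip_alpha,
                 cd_alpha = cd_alpha, fold_min = fold_min,
                 gini_fold_min = gini_fold_min, fdr_target = fdr_target),
            class = "mei_config")
}

#' Compute the six MEI differential measures per gene
#'
#' For every gene of a calibrated matched-count set and a two-group sample
#' sheet, computes: exon NB LRT p-value `E_p` and mean fold change `E_m`
#' (case/control), intron NB p-value `I_p`, the Fisher z p-value `C_d`
#' for the change in exon:intron Pearson correlation, and the
#' case/control Gini ratios `G_e` (exon) and `G_i` (intron). BH q-values
#' for the exon and intron tests are included.
#'
#' @param mc A `matched_counts` object (calibrate first; raw counts are
#'   accepted with a warning).
#' @param sheet Sample sheet from [sample_sheet()].
#' @param cor_method Correlation flavor, `"pearson"` (default) or
#'   `"spearman"`.
#' @return Data frame (one row per gene): `gene_id`, `E_p`, `E_q`, `E_m`,
#'   `I_p`, `I_q`, `C_d`, `G_e`, `G_i`, plus `r_control`, `r_case`,
#'   `gini_*` support columns. Undefined measures are `NA`.
#' @export
mei_measures <- function(mc, sheet, cor_method = "pearson") {
  stopifnot(inherits(mc, "matched_counts"))
  if (!mc$calibrated) {
    warning("matched counts are uncalibrated; measures computed on raw scale")
  }
  samples <- colnames(mc$exon)
  if (!all(samples %in% sheet$sample_id)) {
    stop("sample sheet missing sample(s): ",
         paste(setdiff(samples, sheet$sample_id), collapse = ", "))
  }
  cond <- sheet$condition[match(samples, sheet$sample_id)]
  ctrl <- samples[cond == "control"]
  case <- samples[cond == "case"]
  n1 <- length(ctrl); n2 <- length(case)
  G <- nrow(mc$exon)
  ex_t <- nb_test_many(mc$exon[, ctrl, drop = FALSE],
                       mc$exon[, case, drop = FALSE])
  in_t <- nb_test_many(mc$intron[, ctrl, drop = FALSE],
                       mc$intron[, case, drop = FALSE])
  gini_grp <- function(m, cols) apply(m[, cols, drop = FALSE], 1, function(x) {
    as.numeric(gini_unbiased(x))
  })
  g_ec <- gini_grp(mc$exon, ctrl); g_ea <- gini_grp(mc$exon, case)
  g_ic <- gini_grp(mc$intron, ctrl); g_ia <- gini_grp(mc$intron, case)
  ge <- ifelse(!is.na(g_ec) & g_ec > 0 & !is.na(g_ea), g_ea / g_ec, NA_real_)
  gi <- ifelse(!is.na(g_ic) & g_ic > 0 & !is.na(g_ia), g_ia / g_ic, NA_real_)
  r_ctrl <- r_case <- cd <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    r1 <- exon_intron_correlation(mc$exon[g, ctrl], mc$intron[g, ctrl],
                                  method = cor_method)
    r2 <- exon_intron_correlation(mc$exon[g, case], mc$intron[g, case],
                                  method = cor_method)
    r_ctrl[g] <- r1; r_case[g] <- r2
    if (!is.na(r1) && !is.na(r2)) {
      cd[g] <- suppressWarnings(
        correlation_differential(r1, n1, r2, n2)$p_value)
    }
  }
  data.frame(
    gene_id = rownames(mc$exon),
    E_p = ex_t$p_value, E_q = bh_adjust(ex_t$p_value),
    E_m = ex_t$fold_change,
    I_p = in_t$p_value, I_q = bh_adjust(in_t$p_value),
    C_d = cd, G_e = ge, G_i = gi,
    r_control = r_ctrl, r_case = r_case,
    gini_exon_control = g_ec, gini_exon_case = g_ea,
    gini_intron_control = g_ic, gini_intron_case = g_ia,
    mean_exon_control = ex_t$mean_control, mean_exon_case = ex_t$mean_case,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Evaluate selection criteria per gene
#'
#' Sets the six flags and the two hit calls for each measure record.
#' `Ep`: `E_p < ep_alpha`; `Em`: `max(E_m, 1/E_m) >= fold_min`; `Ip`:
#' `I_p < ip_alpha`; `Cd`: `C_d < cd_alpha`; `Ge`/`Gi`:
#' `max(G, 1/G) >= gini_fold_min` (twofold change in either direction).
#' `standard_hit = Ep & Em`; `mei_hit = Ep & (Em | Ip | Cd | Ge | Gi)` —
#' the exon significance gate plus at least one secondary change.
#' Undefined (`NA`) measures yield `FALSE` flags and are listed in
#' `not_evaluable`.
#'
#' @param records Data frame from [mei_measures()] (needs columns `E_p`,
#'   `E_m`, `I_p`, `C_d`, `G_e`, `G_i`).
#' @param cfg Thresholds from [mei_config()].
#' @return `records` with logical columns `Ep`, `Em`, `Ip`, `Cd`, `Ge`,
#'   `Gi`, `n_flags`, `standard_hit`, `mei_hit`, `not_evaluable`
#'   (comma-separated undefined measures).
#' @export
evaluate_records <- function(records, cfg = mei_config()) {
  fold2 <- function(x, thr) !is.na(x) & x > 0 & pmax(x, 1 / x) >= thr
  lt <- function(p, a) !is.na(p) & p < a
  records$Ep <- lt(records$E_p, cfg$ep_alpha)
  records$Em <- fold2(records$E_m, cfg$fold_min)
  records$Ip <- lt(records$I_p, cfg$ip_alpha)
  records$Cd <- lt(records$C_d, cfg$cd_alpha)
  records$Ge <- fold2(records$G_e, cfg$gini_fold_min)
  records$Gi <- fold2(records$G_i, cfg$gini_fold_min)
  flags <- as.matrix(records[, c("Ep", "Em", "Ip", "Cd", "Ge", "Gi")])
  records$n_flags <- rowSums(flags)
  records$standard_hit <- records$Ep & records$Em
  records$mei_hit <- records$Ep &
    (records$Em | records$Ip | records$Cd | records$Ge | records$Gi)
  nev <- cbind(E_m = is.na(records$E_m), I_p = is.na(records$I_p),
               C_d = is.na(records$C_d), G_e = is.na(records$G_e),
               G_i = is.na(records$G_i))
  records$not_evaluable <- apply(nev, 1, function(z) {
    paste(colnames(nev)[z], collapse = ",")
  })
  records
}

#' Single-gene criterion evaluation
#'
#' Convenience wrapper over [evaluate_records()] for one measure record.
#'
#' @param rec One-row data frame or named list with `E_p`, `E_m`, `I_p`,
#'   `C_d`, `G_e`, `G_i` (`NA` for undefined).
#' @param cfg Thresholds from [mei_config()].
#' @return List with `flags` (named logical vector), `standard_hit`,
#'   `mei_hit`.
#' @export
evaluate_gene <- function(rec, cfg = mei_config()) {
  df <- as.data.frame(as.list(unlist(rec[c("E_p", "E_m", "I_p", "C_d",
                                           "G_e", "G_i")])))
  ev <- evaluate_records(df, cfg)
  list(flags = unlist(ev[1, c("Ep", "Em", "Ip", "Cd", "Ge", "Gi")]),
       standard_hit = ev$standard_hit[1], mei_hit = ev$mei_hit[1])
}

#' Per-test p threshold implied by an FDR target on both region types
#'
#' Diagnostic companion to the fixed `ep_alpha` gate: the largest
#' threshold `t` such that Benjamini-Hochberg at `fdr_target`, applied to
#' the exon and intron p-value vectors separately, admits every `p <= t`
#' in both.
#'
#' @param exon_p,intron_p Non-empty p-value vectors.
#' @param fdr_target FDR level (default 0.1).
#' @return The threshold `t` (0 when nothing passes in either vector).
#' @export
fdr_threshold_check <- function(exon_p, intron_p, fdr_target = 0.1) {
  stopifnot(length(exon_p) >= 1, length(intron_p) >= 1)
  cutoff <- function(p) {
    q <- bh_adjust(p)
    ok <- q <= fdr_target
    if (any(ok)) max(p[ok]) else 0
  }
  min(cutoff(exon_p), cutoff(intron_p))
}

#' Build the annotated selection report
#'
#' Evaluates all criteria, sorts genes by number of satisfied criteria
#' then by exon p-value (most coordinated changes first), and tabulates
#' flag combinations. Genes passing at least one secondary criterion but
#' not the exon gate are set aside in a watch list rather than counted as
#' hits.
#'
#' @param records Data frame from [mei_measures()].
#' @param cfg Thresholds from [mei_config()].
#' @return A `mei_report`: list with `genes` (sorted, annotated data
#'   frame), `summary` (per-flag and per-combination counts),
#'   `watch_list`, `n_standard`, `n_mei`, `config`.
#' @export
build_report <- function(records, cfg = mei_config()) {
  ev <- evaluate_records(records, cfg)
  ord <- order(-ev$n_flags, ev$E_p)
  genes <- ev[ord, , drop = FALSE]
  rownames(genes) <- NULL
  flags <- c("Ep", "Em", "Ip", "Cd", "Ge", "Gi")
  per_flag <- if (nrow(ev) > 0) colSums(ev[, flags, drop = FALSE]) else {
    stats::setNames(rep(0L, 6), flags)
  }
  combo <- if (nrow(ev) > 0) {
    key <- apply(ev[, flags, drop = FALSE], 1, function(z) {
      paste(flags[as.logical(z)], collapse = "+")
    })
    as.data.frame(table(combination = key), stringsAsFactors = FALSE)
  } else {
    data.frame(combination = character(0), Freq = integer(0))
  }
  secondary <- ev$Em | ev$Ip | ev$Cd | ev$Ge | ev$Gi
  structure(
    list(genes = genes,
         summary = list(per_flag = per_flag, combinations = combo),
         watch_list = ev$gene_id[!ev$Ep & secondary],
         n_standard = sum(ev$standard_hit),
         n_mei = sum(ev$mei_hit),
         config = cfg),
    class = "mei_report")
}

#' @export
print.mei_report <- function(x, ...) {
  cat("MEI selection report:", nrow(x$genes), "genes evaluated\n")
  cat("  standard hits (Ep & twofold):", x$n_standard, "\n")
  cat("  MEI hits (Ep & >=1 secondary):", x$n_mei, "\n")
  cat("  watch list (secondary only):", length(x$watch_list), "\n")
  cat("  flag counts:\n")
  print(x$summary$per_flag)
  invisible(x)
}

#' Write a selection report to TSV
#'
#' @param report A `mei_report`.
#' @param path Output TSV path.
#' @export
write_report <- function(report, path) {
  utils::write.table(report$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' End-to-end MEI analysis from count matrices
#'
#' Aligns the exon and intron matrices, estimates size factors (ERCC
#' calibration when spike counts and a mix table are supplied, the median
#' fallback otherwise — the fallback reference is the pooled exon+intron
#' matrix, one library per sample), applies them, computes the six
#' measures and builds the selection report.
#'
#' @param exon,intron Raw count matrices (genes x samples).
#' @param sheet Sample sheet from [sample_sheet()].
#' @param spike_counts,mix Optional ERCC spike counts and nominal mix.
#' @param cfg Thresholds from [mei_config()].
#' @param cor_method Correlation flavor for `C_d`.
#' @return List with `matched` (calibrated counts), `factors`,
#'   `measures`, `report`, `fdr_threshold` (diagnostic from
#'   [fdr_threshold_check()]).
#' @export
run_mei <- function(exon, intron, sheet, spike_counts = NULL, mix = NULL,
                    cfg = mei_config(), cor_method = "pearson") {
  mc <- align_matrices(exon, intron)
  factors <- if (!is.null(spike_counts) && !is.null(mix)) {
    ercc_calibrate(spike_counts[, colnames(mc$exon), drop = FALSE], mix)
  } else {
    median_normalize(rbind(mc$exon, mc$intron))
  }
  mc <- apply_factors(mc, factors)
  measures <- mei_measures(mc, sheet, cor_method = cor_method)
  report <- build_report(measures, cfg)
  list(matched = mc, factors = factors, measures = measures,
       report = report,
       fdr_threshold = fdr_threshold_check(measures$E_p, measures$I_p,
                                           cfg$fdr_target))
}
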