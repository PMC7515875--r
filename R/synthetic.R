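#' Per-gene simulation specification table
#'
#' Builds the gene-level parameter table consumed by [simulate_counts()]:
#' negative binomial exon and intron means, group-specific dispersions
#' (variance `mu + alpha * mu^2`), group-specific latent exon-intron
#' correlations for the Gaussian copula, and the case/control fold change
#' applied to the case means.
#'
#' @param gene_id Character vector of gene ids.
#' @param exon_mean,intron_mean Positive NB means (control scale).
#' @param dispersion_control,dispersion_case Dispersions `>= 0` (0 =
#'   Poisson).
#' @param rho_control,rho_case Latent exon-intron correlations, strictly
#'   inside (-1, 1).
#' @param fold_change Positive multiplier applied to both case means.
#' @param class Optional ground-truth label carried into the truth table.
#' @return Data frame of gene specs.
#' @export
sim_gene_specs <- function(gene_id, exon_mean, intron_mean,
                           dispersion_control = 0.1,
                           dispersion_case = dispersion_control,
                           rho_control = 0.9, rho_case = rho_control,
                           fold_change = 1, class = "null") {
  df <- data.frame(gene_id = as.character(gene_id),
                   exon_mean = exon_mean, intron_mean = intron_mean,
                   dispersion_control = dispersion_control,
                   dispersion_case = dispersion_case,
                   rho_control = rho_control, rho_case = rho_case,
                   fold_change = fold_change, class = class,
                   stringsAsFactors = FALSE)
  stopifnot(all(df$exon_mean > 0), all(df$intron_mean > 0),
            all(df$dispersion_control >= 0), all(df$dispersion_case >= 0),
            all(abs(df$rho_control) < 1), all(abs(df$rho_case) < 1),
            all(df$fold_change > 0), !anyDuplicated(df$gene_id))
  df
}

#' Cohort simulation configuration
#'
#' @param n_control,n_case Group sizes (each `>= 4`).
#' @param genes Gene spec table from [sim_gene_specs()].
#' @param ercc Optional named vector of nominal ERCC concentrations (e.g.
#'   [sim_ercc_mix()]); spike counts are then simulated per sample.
#' @param scale_sd Log-sd of the per-sample technical scale distortion
#'   (log-normal, clamped to `scale_range`); 0 = no distortion.
#' @param scale_range Clamp for sampled scale factors (default 0.25-4).
#' @param ercc_dispersion NB dispersion of spike counts (default 0.005,
#'   near-technical noise).
#' @param ercc_depth Multiplier from nominal concentration to expected
#'   spike counts (default 10).
#' @param seed Mandatory integer seed; all randomness is reproducible.
#' @return A `sim_cohort_config` list.
#' @export
sim_cohort_config <- function(n_control, n_case, genes, ercc = NULL,
                              scale_sd = 0, scale_range = c(0.25, 4),
                              ercc_dispersion = 0.005, ercc_depth = 10,
                              seed) {
  stopifnot(n_control >= 4, n_case >= 4, is.data.frame(genes),
            !missing(seed), is.finite(seed))
  structure(list(n_control = n_control, n_case = n_case, genes = genes,
                 ercc = ercc, scale_sd = scale_sd,
                 scale_range = scale_range,
                 ercc_dispersion = ercc_dispersion, ercc_depth = ercc_depth,
                 seed = as.integer(seed)),
            class = "sim_cohort_config")
}

# NB quantile through a uniform; dispersion 0 -> Poisson
.q_counts <- function(u, mu, alpha) {
  if (alpha < 1e-12) stats::qpois(u, lambda = mu)
  else stats::qnbinom(u, size = 1 / alpha, mu = mu)
}

#' Simulate a matched exon/intron cohort with known ground truth
#'
#' Draws, per gene and sample, correlated (exon, intron) counts via a
#' Gaussian copula with the group's latent correlation and NB marginals
#' `NB(mean * sample_scale, dispersion)`; case means are the control
#' means times `fold_change`. Optional ERCC spike counts are NB around
#' `nominal * ercc_depth * sample_scale`. The truth table records every
#' planted parameter plus the realized per-group empirical exon:intron
#' Pearson correlations, so downstream modules can assert recovery.
#'
#' @param cfg Configuration from [sim_cohort_config()].
#' @return List: `matched` (raw `matched_counts`), `sheet` (sample
#'   sheet), `spike_counts` (matrix or `NULL`), `truth` (gene spec table
#'   with realized `r_control_emp`, `r_case_emp`), `scale_factors`
#'   (planted per-sample factors, geometric mean 1).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_cohort_config"))
  set.seed(cfg$seed)
  gs <- cfg$genes
  G <- nrow(gs)
  n1 <- cfg$n_control; n2 <- cfg$n_case; n <- n1 + n2
  samples <- c(sprintf("ctrl_%02d", seq_len(n1)),
               sprintf("case_%02d", seq_len(n2)))
  cond <- rep(c("control", "case"), c(n1, n2))
  sc <- if (cfg$scale_sd > 0) {
    s <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$scale_sd)
    pmin(pmax(s, cfg$scale_range[1]), cfg$scale_range[2])
  } else rep(1, n)
  sc <- sc / exp(mean(log(sc)))
  exon <- matrix(0, G, n, dimnames = list(gs$gene_id, samples))
  intron <- exon
  draw_group <- function(idx, mu_e, mu_i, alpha, rho) {
    m <- length(idx)
    z1 <- matrix(stats::rnorm(G * m), G, m)
    z2 <- rho * z1 + sqrt(1 - rho^2) * matrix(stats::rnorm(G * m), G, m)
    for (g in seq_len(G)) {
      exon[g, idx] <<- .q_counts(stats::pnorm(z1[g, ]),
                                 mu_e[g] * sc[idx], alpha[g])
      intron[g, idx] <<- .q_counts(stats::pnorm(z2[g, ]),
                                   mu_i[g] * sc[idx], alpha[g])
    }
  }
  draw_group(seq_len(n1), gs$exon_mean, gs$intron_mean,
             gs$dispersion_control, gs$rho_control)
  draw_group(n1 + seq_len(n2), gs$exon_mean * gs$fold_change,
             gs$intron_mean * gs$fold_change,
             gs$dispersion_case, gs$rho_case)
  spikes <- NULL
  if (!is.null(cfg$ercc)) {
    mu <- outer(cfg$ercc * cfg$ercc_depth, sc)
    spikes <- matrix(
      stats::rnbinom(length(mu), size = 1 / cfg$ercc_dispersion, mu = mu),
      nrow = length(cfg$ercc),
      dimnames = list(names(cfg$ercc), samples))
  }
  truth <- gs
  ctrl <- seq_len(n1); case <- n1 + seq_len(n2)
  truth$r_control_emp <- vapply(seq_len(G), function(g) {
    suppressWarnings(stats::cor(exon[g, ctrl], intron[g, ctrl]))
  }, numeric(1))
  truth$r_case_emp <- vapply(seq_len(G), function(g) {
    suppressWarnings(stats::cor(exon[g, case], intron[g, case]))
  }, numeric(1))
  list(matched = align_matrices(exon, intron),
       sheet = sample_sheet(samples, cond),
       spike_counts = spikes,
       truth = truth,
       scale_factors = stats::setNames(sc, samples))
}

#' Synthetic ERCC mix table
#'
#' A deterministic ladder of 92 nominal concentrations spanning ~15
#' doublings (the dynamic range of commercial spike-in mixes), for
#' simulations and fixtures. Synthetic: not the commercial mix sheet.
#'
#' @param n Number of spike-ins (default 92).
#' @return Named numeric vector of nominal concentrations.
#' @export
sim_ercc_mix <- function(n = 92) {
  stats::setNames(2^seq(-2, 13, length.out = n),
                  sprintf("ERCC-%05d", seq_len(n)))
}

#' The package's reference synthetic study cohort
#'
#' Generates the standard evaluation cohort: `n_control` vs `n_case`
#' samples and `n_genes` genes of which `frac_mean` carry a pure mean
#' shift (fold `mean_fold`, alternating up/down), `frac_gini` a pure
#' variability shift (case dispersion `gini_disp_case`), `frac_corr` a
#' pure correlation break (case latent correlation `rho_case_break`), and
#' the rest are null. Baseline exon means are log-normal around ~200
#' counts with intron means at one third of the exon mean; baseline
#' dispersion and latent correlation emulate a human blood cohort.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_control,n_case Group sizes (defaults 12 and 46).
#' @param frac_mean,frac_gini,frac_corr Planted class fractions
#'   (defaults 0.05 each).
#' @param mean_fold Fold change of the mean-shift class (default 3).
#' @param base_dispersion Control dispersion (default 0.15).
#' @param gini_disp_case Case dispersion of the variability-shift class
#'   (default 2).
#' @param rho_base Baseline latent exon-intron correlation (default 0.95).
#' @param rho_case_break Case latent correlation of the
#'   correlation-break class (default 0).
#' @param scale_sd,ercc Per-sample scale distortion and optional spike
#'   mix, as in [sim_cohort_config()].
#' @param seed Integer seed.
#' @return [simulate_counts()] output; `truth$class` holds the labels
#'   `mean_shift`, `gini_shift`, `corr_break`, `null`.
#' @export
sim_mei_cohort <- function(n_genes = 2000, n_control = 12, n_case = 46,
                           frac_mean = 0.05, frac_gini = 0.05,
                           frac_corr = 0.05, mean_fold = 3,
                           base_dispersion = 0.15, gini_disp_case = 2,
                           rho_base = 0.95, rho_case_break = 0,
                           scale_sd = 0.25, ercc = sim_ercc_mix(),
                           seed) {
  stopifnot(!missing(seed))
  n_m <- round(frac_mean * n_genes)
  n_g <- round(frac_gini * n_genes)
  n_c <- round(frac_corr * n_genes)
  cls <- c(rep("mean_shift", n_m), rep("gini_shift", n_g),
           rep("corr_break", n_c),
           rep("null", n_genes - n_m - n_g - n_c))
  set.seed(seed)
  e_mu <- pmax(20, stats::rlnorm(n_genes, meanlog = log(200), sdlog = 1))
  fold <- rep(1, n_genes)
  fold[cls == "mean_shift"] <- rep(c(mean_fold, 1 / mean_fold),
                                   length.out = n_m)
  disp_case <- rep(base_dispersion, n_genes)
  disp_case[cls == "gini_shift"] <- gini_disp_case
  rho_case <- rep(rho_base, n_genes)
  rho_case[cls == "corr_break"] <- rho_case_break
  specs <- sim_gene_specs(
    gene_id = sprintf("gene_%04d", seq_len(n_genes)),
    exon_mean = e_mu, intron_mean = e_mu / 3,
    dispersion_control = base_dispersion, dispersion_case = disp_case,
    rho_control = rho_base, rho_case = rho_case,
    fold_change = fold, class = cls)
  cfg <- sim_cohort_config(n_control = n_control, n_case = n_case,
                           genes = specs, ercc = ercc, scale_sd = scale_sd,
                           seed = seed + 1L)
  simulate_counts(cfg)
}

#' Simulate read placements for the singular-counting gates
#'
#' Emits reads over gene models with planted per-gene exon and intron
#' placement numbers, plus optional low-MAPQ contamination, so
#' [count_sample()] has exact expected outputs. In deterministic mode
#' reads are tiled round-robin across the region's intervals (trimmed to
#' fit inside one interval, so an exon read is exonic and an intron read
#' intronic by construction); otherwise positions are drawn uniformly.
#'
#' @param models Named list of [gene_model()] objects.
#' @param exon_reads,intron_reads Named integer vectors (per gene id) of
#'   high-quality placements to emit.
#' @param low_q_reads Named integer vector of additional low-MAPQ exonic
#'   placements (default none).
#' @param sample_id Sample id attached to the reads.
#' @param read_len Read length (default 50; trimmed to the interval).
#' @param mapq_high,mapq_low MAPQ of clean vs contaminating reads
#'   (defaults 60 and 10).
#' @param deterministic Tile placements (default `TRUE`) instead of
#'   sampling them.
#' @param seed Seed for the random mode.
#' @return Read placement data frame for [count_sample()].
#' @export
simulate_alignments <- function(models, exon_reads, intron_reads,
                                low_q_reads = NULL, sample_id = "s1",
                                read_len = 50, mapq_high = 60, mapq_low = 10,
                                deterministic = TRUE, seed = 1) {
  if (!deterministic) set.seed(seed)
  place <- function(iv, k, det) {
    # k read starts + lengths inside intervals iv (matrix start/end)
    if (k == 0 || nrow(iv) == 0) {
      return(cbind(start = integer(0), len = integer(0)))
    }
    which_iv <- rep(seq_len(nrow(iv)), length.out = k)
    lens <- pmin(read_len, iv[which_iv, 2] - iv[which_iv, 1])
    room <- iv[which_iv, 2] - iv[which_iv, 1] - lens
    off <- if (det) {
      slot <- stats::ave(seq_len(k), which_iv, FUN = seq_along) - 1
      per <- stats::ave(seq_len(k), which_iv, FUN = length)
      floor(slot * room / pmax(per - 1, 1))
    } else {
      floor(stats::runif(k) * (room + 1))
    }
    cbind(start = iv[which_iv, 1] + pmin(off, room), len = lens)
  }
  out <- list()
  for (g in names(models)) {
    m <- models[[g]]
    ne <- if (g %in% names(exon_reads)) exon_reads[[g]] else 0L
    ni <- if (g %in% names(intron_reads)) intron_reads[[g]] else 0L
    nl <- if (!is.null(low_q_reads) && g %in% names(low_q_reads)) {
      low_q_reads[[g]]
    } else 0L
    pe <- place(m$exons, ne, deterministic)
    pi <- place(m$introns, ni, deterministic)
    pl <- place(m$exons, nl, deterministic)
    k <- nrow(pe) + nrow(pi) + nrow(pl)
    if (k == 0) next
    pos <- rbind(pe, pi, pl)
    out[[g]] <- data.frame(
      read_id = sprintf("%s_r%04d", g, seq_len(k)),
      chrom = m$chrom,
      start = pos[, "start"],
      cigar = sprintf("%dM", pos[, "len"]),
      mapq = rep(c(mapq_high, mapq_high, mapq_low),
                 c(nrow(pe), nrow(pi), nrow(pl))),
      sample_id = sample_id,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), cigar = character(0),
                      mapq = integer(0), sample_id = character(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
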