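#' Read an ERCC spike-in mix table
#'
#' ExFold-style TSV with columns `spike_id`, `mix1_conc` and (optionally)
#' `mix2_conc` in attomoles/uL.
#'
#' @param path TSV path.
#' @param mix Which mix column to use (1 or 2).
#' @return Named numeric vector of nominal concentrations.
#' @export
read_ercc_mix <- function(path, mix = 1) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  col <- paste0("mix", mix, "_conc")
  if (!all(c("spike_id", col) %in% colnames(df))) {
    stop("ERCC mix table must have columns spike_id and ", col, ": ", path)
  }
  conc <- df[[col]]
  if (any(conc <= 0)) stop("nominal concentrations must be positive: ", path)
  if (anyDuplicated(df$spike_id)) stop("duplicated spike ids in ", path)
  stats::setNames(conc, df$spike_id)
}

.geo_normalize <- function(s) {
  s / exp(mean(log(s)))
}

#' ERCC spike-in iterative proportional calibration
#'
#' Estimates one positive size factor per sample from spike-in counts and
#' the known nominal mix concentrations. The model is proportional: a
#' single slope `b` shared by all samples with per-sample intercepts,
#' `log2(count_ij) = a_j + b * log2(nominal_i)`, fitted by
#' iteratively reweighted least squares (Tukey bisquare). After each fit,
#' spike-in measurements with `|residual| > max(resid_mad_cut * MAD,
#' resid_abs_floor)` are excluded and the model refitted until the
#' excluded set stabilizes (or `max_iter`); the absolute floor keeps
#' measurements within ordinary pipetting/counting error (a few percent)
#' from ever being treated as outliers when the cohort happens to fit
#' almost perfectly. The closing estimate is least squares on the
#' retained measurements. Size factors are `2^(a_j - mean(a))`, rescaled to
#' geometric mean 1. Only spike-ins with nonzero counts in every sample
#' enter the fit, so the log is always finite and scaling one sample's
#' counts by `c` scales its factor by exactly `c` (equivariance).
#'
#' @param spike_counts Matrix of spike-in counts (spikes x samples), row
#'   names matching `names(mix)`.
#' @param mix Named vector of nominal concentrations ([read_ercc_mix()]).
#' @param max_iter Maximum outlier-pruning refits (default 20).
#' @param resid_mad_cut Residual cut in MAD units (default 2).
#' @param resid_abs_floor Minimum absolute residual (log2 units) for
#'   exclusion (default 0.05, i.e. ~3.5\% deviation).
#' @return Named numeric vector of size factors (class `size_factors`),
#'   geometric mean 1, with attribute `excluded` (pruned measurements as a
#'   spike x sample logical matrix) and `slope`.
#' @export
ercc_calibrate <- function(spike_counts, mix, max_iter = 20,
                           resid_mad_cut = 2.0, resid_abs_floor = 0.05) {
  common <- intersect(rownames(spike_counts), names(mix))
  usable <- common[rowSums(spike_counts[common, , drop = FALSE] > 0) ==
                     ncol(spike_counts)]
  if (length(usable) < 8) {
    stop("fewer than 8 spike-ins with nonzero counts in every sample (",
         length(usable), "); fall back to median_normalize()")
  }
  cm <- spike_counts[usable, , drop = FALSE]
  ns <- ncol(cm)
  y <- as.vector(log2(cm))
  x <- rep(log2(mix[usable]), times = ns)
  f <- factor(rep(colnames(cm), each = length(usable)),
              levels = colnames(cm))
  include <- rep(TRUE, length(y))
  cf <- NULL
  for (it in seq_len(max_iter)) {
    fit <- suppressWarnings(
      MASS::rlm(y[include] ~ 0 + f[include] + x[include],
                psi = MASS::psi.bisquare, maxit = 100))
    cf_new <- stats::coef(fit)
    if (anyNA(cf_new)) break  # refit degenerated; keep previous solution
    cf <- cf_new
    a <- cf[seq_len(ns)]
    b <- cf[ns + 1]
    res_all <- y - (a[as.integer(f)] + b * x)
    cut <- max(resid_mad_cut * stats::mad(res_all[include]),
               resid_abs_floor)
    if (!is.finite(cut)) break
    new_include <- abs(res_all) <= cut
    # keep each sample's 8 best-fitting spike-ins even when the cut is tiny
    for (j in levels(f)) {
      jj <- which(f == j)
      if (sum(new_include[jj]) < 8) {
        new_include[jj[order(abs(res_all[jj]))[1:8]]] <- TRUE
      }
    }
    if (identical(new_include, include)) break
    include <- new_include
  }
  # final estimate: least squares on the retained measurements (outliers
  # already pruned, so LS is the efficient, deterministic closing step)
  cf_ls <- stats::coef(stats::lm(y[include] ~ 0 + f[include] + x[include]))
  if (!anyNA(cf_ls)) cf <- cf_ls
  a <- cf[seq_len(ns)]
  s <- .geo_normalize(2^(a - mean(a)))
  names(s) <- colnames(cm)
  excluded <- matrix(!include, nrow = length(usable),
                     dimnames = list(usable, colnames(cm)))
  structure(s, class = "size_factors", excluded = excluded,
            slope = unname(cf[ns + 1]))
}

#' Median-ratio size factors (spike-in-free fallback)
#'
#' Per-gene reference is the median count across samples; each sample's
#' factor is the median over genes of its count over the reference (genes
#' with zero reference are skipped), geometric-mean normalized.
#'
#' @param counts Count matrix (genes x samples).
#' @return Named numeric vector of size factors (class `size_factors`).
#' @export
median_normalize <- function(counts) {
  if (!any(rowSums(counts > 0) == ncol(counts))) {
    stop("no gene with nonzero counts in all samples; cannot normalize")
  }
  ref <- apply(counts, 1, stats::median)
  keep <- ref > 0
  s <- apply(counts[keep, , drop = FALSE], 2, function(col) {
    stats::median(col / ref[keep])
  })
  if (any(s <= 0)) {
    stop("non-positive size factor; too many zero counts for median ",
         "normalization")
  }
  structure(.geo_normalize(s), class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  cat("size_factors for", length(x), "samples:\n")
  print(round(unclass(x)[seq_len(min(8, length(x)))], 4))
  if (length(x) > 8) cat("...\n")
  invisible(x)
}

#' Apply per-sample size factors to matched counts
#'
#' Divides each sample's exon and intron columns by its factor (one factor
#' per sample-library) and marks the result calibrated.
#'
#' @param mc A `matched_counts` object.
#' @param factors A `size_factors` vector covering all samples of `mc`.
#' @return Calibrated `matched_counts`.
#' @export
apply_factors <- function(mc, factors) {
  stopifnot(inherits(mc, "matched_counts"))
  samples <- colnames(mc$exon)
  if (!all(samples %in% names(factors))) {
    stop("size factors missing for sample(s): ",
         paste(setdiff(samples, names(factors)), collapse = ", "))
  }
  fv <- unclass(factors)[samples]
  mc$exon <- sweep(mc$exon, 2, fv, "/")
  mc$intron <- sweep(mc$intron, 2, fv, "/")
  mc$calibrated <- TRUE
  mc
}
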