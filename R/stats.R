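#' Unbiased Gini coefficient of expression variability
#'
#' Dispersion measure in `[0, 1]` (the unbiased estimator may slightly
#' exceed 1): the sum of absolute pairwise differences normalized by
#' `2 * n * (n - 1) * mean(x)`. Scale-invariant, so gene-length or depth
#' rescaling of a gene's counts leaves it unchanged; 0 iff all values are
#' equal. Computed via the sorted-order identity, O(n log n).
#'
#' @param x Non-negative numeric vector, `length(x) >= 2`.
#' @return The Gini coefficient, or `NA` (with a `"reason"` attribute)
#'   when `mean(x) == 0`.
#' @examples
#' gini_unbiased(c(5, 5, 5, 5))  # 0
#' gini_unbiased(c(0, 1))        # 1
#' gini_unbiased(c(1, 2, 3))     # 1/3
#' @export
gini_unbiased <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  if (any(x < 0)) stop("gini_unbiased requires non-negative values")
  m <- mean(x)
  if (m == 0) {
    return(structure(NA_real_, reason = "undefined: mean(x) == 0"))
  }
  xs <- sort(x)
  i <- seq_len(n)
  sum((2 * i - n - 1) * xs) / (n * (n - 1) * m)
}

#' Relative Gini change between conditions
#'
#' @param g_control,g_case Gini coefficients of the two groups.
#' @return List with `rel_change` `(g_case - g_control) / g_control` and
#'   `ratio` `g_case / g_control`; both `NA` when `g_control` is 0 or
#'   undefined.
#' @export
delta_gini <- function(g_control, g_case) {
  if (is.na(g_control) || is.na(g_case) || g_control == 0) {
    return(list(rel_change = NA_real_, ratio = NA_real_))
  }
  list(rel_change = (g_case - g_control) / g_control,
       ratio = g_case / g_control)
}

# Row-wise NB log-likelihood; mu, alpha length nrow(M), alpha 0 = Poisson.
.nb_ll_rows <- function(M, mu, alpha) {
  out <- numeric(length(mu))
  pois <- alpha < 1e-12
  if (any(pois)) {
    out[pois] <- rowSums(stats::dpois(M[pois, , drop = FALSE],
                                      lambda = pmax(mu[pois], 1e-300),
                                      log = TRUE))
  }
  if (any(!pois)) {
    out[!pois] <- rowSums(stats::dnbinom(M[!pois, , drop = FALSE],
                                         size = 1 / alpha[!pois],
                                         mu = pmax(mu[!pois], 1e-300),
                                         log = TRUE))
  }
  out
}

#' Negative binomial likelihood-ratio tests, many genes at once
#'
#' For each gene (row), tests H0: one shared NB mean against H1:
#' group-specific means, with a common dispersion `alpha`
#' (variance `mu + alpha * mu^2`) estimated by maximum likelihood under H1
#' and floored at 0 (the Poisson limit). The LR statistic is referred to
#' chi-squared with 1 df. Calibrated (real-valued) inputs are rounded to
#' the nearest integer for the likelihood. All-zero genes get `p = 1`.
#'
#' The dispersion maximization is a vectorized golden-section search on
#' `log(alpha)` over `[e^-12, e^3]`, with an explicit Poisson boundary
#' check, so thousands of genes are tested in one call.
#'
#' @param control,case Matrices (genes x samples per group) of counts with
#'   identical row order.
#' @return Data frame with one row per gene: `mean_control`, `mean_case`,
#'   `dispersion`, `fold_change` (case/control of means with 0.5
#'   pseudocounts), `p_value`.
#' @export
nb_test_many <- function(control, case) {
  control <- round(as.matrix(control))
  case <- round(as.matrix(case))
  stopifnot(nrow(control) == nrow(case), ncol(control) >= 2, ncol(case) >= 2)
  G <- nrow(control)
  n1 <- ncol(control); n2 <- ncol(case)
  mu1 <- rowMeans(control); mu2 <- rowMeans(case)
  mu0 <- (rowSums(control) + rowSums(case)) / (n1 + n2)
  ll1 <- function(la) {
    a <- exp(la)
    .nb_ll_rows(control, mu1, a) + .nb_ll_rows(case, mu2, a)
  }
  gr <- (sqrt(5) - 1) / 2
  lo <- rep(-12, G); hi <- rep(3, G)
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- ll1(x1); f2 <- ll1(x2)
  for (i in seq_len(60)) {
    up <- f1 < f2
    lo[up] <- x1[up]; x1[up] <- x2[up]; f1[up] <- f2[up]
    x2[up] <- lo[up] + gr * (hi[up] - lo[up])
    f2[up] <- ll1(x2)[up]
    dn <- !up
    hi[dn] <- x2[dn]; x2[dn] <- x1[dn]; f2[dn] <- f1[dn]
    x1[dn] <- hi[dn] - gr * (hi[dn] - lo[dn])
    f1[dn] <- ll1(x1)[dn]
  }
  la_hat <- (lo + hi) / 2
  a_hat <- exp(la_hat)
  l1 <- ll1(la_hat)
  l_pois <- .nb_ll_rows(control, mu1, numeric(G)) +
    .nb_ll_rows(case, mu2, numeric(G))
  at_floor <- l_pois >= l1
  a_hat[at_floor] <- 0
  l1 <- pmax(l1, l_pois)
  l0 <- .nb_ll_rows(cbind(control, case), mu0, a_hat)
  lr <- pmax(0, 2 * (l1 - l0))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  p[mu0 == 0] <- 1
  data.frame(
    mean_control = mu1, mean_case = mu2, dispersion = a_hat,
    fold_change = (mu2 + 0.5) / (mu1 + 0.5),
    p_value = p, row.names = rownames(control))
}

#' Negative binomial likelihood-ratio test for one gene
#'
#' Single-gene wrapper around [nb_test_many()]; see there for the model.
#'
#' @param control,case Numeric count vectors (each `n >= 2`).
#' @return One-row data frame (`NBTestResult` fields); `q_value` is `NA`
#'   until filled by [bh_adjust()] over a gene set.
#' @export
nb_test <- function(control, case) {
  r <- nb_test_many(matrix(control, nrow = 1), matrix(case, nrow = 1))
  r$q_value <- NA_real_
  r
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Rescale a gene's counts by its lowest value
#'
#' Division by the per-gene minimum puts every sample on a relative scale
#' starting at 1, reducing heteroscedasticity before ratio/log transforms.
#' When the minimum is 0 and `zero_guard` is set, 1 is added to all values
#' first (the minimum then being 1, the result is `x + 1`).
#'
#' @param x Non-negative numeric vector.
#' @param zero_guard Apply the +1 mitigation when `min(x) == 0`
#'   (default `TRUE`).
#' @return Rescaled vector (minimum 1), or all-`NA` when `min(x) == 0`
#'   and `zero_guard` is `FALSE`.
#' @examples
#' rescale_by_min(c(10, 20, 40))  # 1 2 4
#' rescale_by_min(c(0, 3, 9))     # 1 4 10
#' @export
rescale_by_min <- function(x, zero_guard = TRUE) {
  stopifnot(length(x) >= 1, all(x >= 0))
  m <- min(x)
  if (m > 0) return(x / m)
  if (zero_guard) return(x + 1)
  rep(NA_real_, length(x))
}

#' Exon:intron correlation across samples
#'
#' @param exon,intron Numeric vectors over the same samples (`n >= 4`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation coefficient, or `NA` when either vector has zero
#'   variance.
#' @export
exon_intron_correlation <- function(exon, intron,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(exon) == length(intron), length(exon) >= 4)
  if (stats::sd(exon) == 0 || stats::sd(intron) == 0) {
    return(structure(NA_real_, reason = "zero variance"))
  }
  stats::cor(exon, intron, method = method)
}

#' Fisher z test for a change in correlation
#'
#' Tests whether two correlation coefficients estimated on independent
#' groups differ, via the classical Fisher transform:
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' normal p-value. Correlations of exactly +/-1 are clipped to
#' `+/-(1 - 1e-7)` with a warning.
#'
#' @param r1,r2 Correlations in the two groups.
#' @param n1,n2 Group sample sizes (each `>= 4`).
#' @return List (`CorrDiffResult`): `r_control`, `r_case`, `n_control`,
#'   `n_case`, `statistic`, `p_value`. `p_value` is exactly 1 when
#'   `r1 == r2`.
#' @export
correlation_differential <- function(r1, n1, r2, n2) {
  stopifnot(n1 >= 4, n2 >= 4)
  clip <- function(r) {
    if (abs(r) >= 1) {
      warning("correlation of |r| = 1 clipped to 1 - 1e-7")
      r <- sign(r) * (1 - 1e-7)
    }
    r
  }
  r1c <- clip(r1); r2c <- clip(r2)
  z <- (atanh(r1c) - atanh(r2c)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- if (r1 == r2) 1 else 2 * stats::pnorm(-abs(z))
  list(r_control = r1, r_case = r2, n_control = n1, n_case = n2,
       statistic = z, p_value = p)
}

#' Robust zero-intercept slope of intron on exon
#'
#' Huber-loss IRLS regression of rescaled intron counts on rescaled exon
#' counts with the intercept fixed at 0 (the exon:intron ratio line passes
#' through the origin on the min-rescaled scale).
#'
#' @param exon_rescaled,intron_rescaled Numeric vectors (`n >= 4`).
#' @return List with `slope` and `se`.
#' @export
robust_slope <- function(exon_rescaled, intron_rescaled) {
  stopifnot(length(exon_rescaled) == length(intron_rescaled),
            length(exon_rescaled) >= 4)
  if (stats::sd(exon_rescaled) == 0) {
    stop("degenerate predictor: all exon values equal")
  }
  if (all(intron_rescaled == 0)) {
    return(list(slope = 0, se = 0))
  }
  fit <- MASS::rlm(intron_rescaled ~ 0 + exon_rescaled,
                   psi = MASS::psi.huber, maxit = 100)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm[1, "Value"]), se = unname(sm[1, "Std. Error"]))
}

#' Test for a difference between two slopes
#'
#' Normal-approximation two-sided test on
#' `t = (s1 - s2) / sqrt(se1^2 + se2^2)`.
#'
#' @param s1,se1 First slope and its standard error.
#' @param s2,se2 Second slope and its standard error.
#' @return Two-sided p-value (1 when `s1 == s2`).
#' @export
slope_difference_test <- function(s1, se1, s2, se2) {
  stopifnot(se1 > 0 || s1 == s2, se2 > 0 || s1 == s2)
  if (s1 == s2) return(1)
  t <- (s1 - s2) / sqrt(se1^2 + se2^2)
  2 * stats::pnorm(-abs(t))
}
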