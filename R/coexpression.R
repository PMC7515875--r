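# Row z-score with sample sd; rows with zero variance -> NA rows.
.zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  sw <- sweep(m, 1, mu, "-")
  sweep(sw, 1, sdv, "/")
}

#' Build co-expression feature profiles
#'
#' Turns calibrated matched counts into per-gene feature vectors over
#' samples, the clustering input. Mode `"exon_only"`: min-rescaled exon
#' counts, `log2`, row z-score. Mode `"exon_intron_ratio"`: min-rescaled
#' exon over min-rescaled intron (both with the +1 zero guard of
#' [rescale_by_min()]), `log2`, row z-score. Genes with zero variance
#' after the transform are dropped with a warning.
#'
#' @param mc A `matched_counts` object (calibrated).
#' @param mode `"exon_only"` or `"exon_intron_ratio"`.
#' @return Matrix (genes x samples) of z-scored profiles with attributes
#'   `mode` and `dropped` (zero-variance gene ids).
#' @export
build_features <- function(mc, mode = c("exon_only", "exon_intron_ratio")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mc, "matched_counts"))
  if (ncol(mc$exon) < 2) stop("z-scoring needs >= 2 samples")
  ex <- t(apply(mc$exon, 1, rescale_by_min))
  v <- if (mode == "exon_only") {
    log2(ex)
  } else {
    im <- t(apply(mc$intron, 1, rescale_by_min))
    log2(ex / im)
  }
  z <- .zscore_rows(v)
  bad <- !stats::complete.cases(z) | !is.finite(rowSums(z))
  if (any(bad)) {
    warning("dropped ", sum(bad), " zero-variance gene(s) from features")
  }
  out <- z[!bad, , drop = FALSE]
  attr(out, "mode") <- mode
  attr(out, "dropped") <- rownames(z)[bad]
  out
}

# correlation of z-scored rows with z-scored centroids: r = x.c/(d-1)
.row_cor <- function(z, cz) {
  tcrossprod(z, cz) / (ncol(z) - 1)
}

.lloyd_once <- function(z, k, init_rows) {
  n <- nrow(z)
  cent <- z[init_rows, , drop = FALSE]
  assign_old <- rep(0L, n)
  assign <- NULL
  for (it in seq_len(100)) {
    r <- .row_cor(z, cent)
    assign <- max.col(r, ties.method = "first")
    if (identical(assign, assign_old)) break
    assign_old <- assign
    own_r <- r[cbind(seq_len(n), assign)]
    for (c in seq_len(k)) {
      mem <- which(assign == c)
      if (length(mem) == 0) {
        # re-seed an empty cluster from the farthest (least correlated) point
        cent[c, ] <- z[which.min(own_r), ]
        next
      }
      cm <- colMeans(z[mem, , drop = FALSE])
      s <- stats::sd(cm)
      cent[c, ] <- if (is.finite(s) && s > 0) (cm - mean(cm)) / s else z[mem[1], ]
    }
  }
  r <- .row_cor(z, cent)
  wcss <- sum(1 - r[cbind(seq_len(n), assign)])
  list(assignment = assign, centroids = cent, wcss = wcss)
}

#' K-means clustering with Pearson-correlation distance
#'
#' Lloyd's algorithm on row-z-scored profiles with distance
#' `d(x, y) = 1 - cor(x, y)`; on z-scored rows this is Euclidean geometry
#' up to a constant (`1 - r = ||x - y||^2 / (2 (d - 1))`), so the
#' mean-update step is well defined (cluster means are re-z-scored).
#' The best of `restarts` random initializations by total within-cluster
#' correlation distance is returned; given `seed`, the result is
#' deterministic. Empty clusters are re-seeded from the farthest point.
#'
#' @param fm Feature matrix from [build_features()] (genes x samples,
#'   rows z-scored).
#' @param k Number of clusters (`1 <= k <=` number of genes).
#' @param restarts Random restarts (default 50).
#' @param seed Integer seed (the caller's RNG state is restored on exit).
#' @return A `cluster_model`: list with `k`, `assignment` (named integer
#'   vector), `centroids`, `wcss` (correlation distance),
#'   `wcss_eucl` (Euclidean, z-scale), `aic`.
#' @export
kmeans_corr <- function(fm, k, restarts = 50, seed = 1) {
  n <- nrow(fm); d <- ncol(fm)
  stopifnot(k >= 1, k <= n)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- sample.int(n, k)
    fitr <- .lloyd_once(fm, k, init)
    if (is.null(best) || fitr$wcss < best$wcss) best <- fitr
  }
  wcss_eucl <- 2 * (d - 1) * best$wcss
  model <- list(k = k,
                assignment = stats::setNames(best$assignment, rownames(fm)),
                centroids = best$centroids,
                wcss = best$wcss,
                wcss_eucl = wcss_eucl,
                aic = .kmeans_ic(wcss_eucl, n, d, k))
  class(model) <- "cluster_model"
  model
}

# Spherical-Gaussian information criterion for k-means on n x d z-scored
# data: deviance term n*d*log(wcss/(n*d)) plus a per-cluster penalty.
# Parameter-counting penalties (AIC's 2 per parameter, or BIC's log-n
# weighting) are structurally too weak here: an adaptive split of pure
# noise in correlation geometry gains about n*sqrt(d) of deviance (the
# best data-chosen direction has correlation ~1/sqrt(d) with every row),
# so the penalty must grow at that rate. 2*n*sqrt(d) per extra cluster
# sits about twice the noise-split gain and an order of magnitude below
# the deviance drop of genuinely separated structure.
.kmeans_ic <- function(wcss_eucl, n, d, k, penalty = 2 * n * sqrt(d)) {
  n * d * log(max(wcss_eucl, 1e-300) / (n * d)) + penalty * k
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k=%d, sizes=%s, wcss=%.3f, AIC=%.1f\n",
              x$k, paste(tabulate(x$assignment, x$k), collapse = "/"),
              x$wcss, x$aic))
  invisible(x)
}

#' Choose the number of clusters by AIC
#'
#' Fits [kmeans_corr()] for each candidate `k` and returns the model
#' minimizing an AIC-style information criterion,
#' `n * d * log(wcss_eucl / (n * d)) + 2 * n * sqrt(d) * k`, where
#' `wcss_eucl` is the Euclidean within-cluster sum of squares of the
#' z-scored data. The per-cluster penalty is scaled to the deviance an
#' adaptive split gains on pure noise in correlation geometry (about
#' `n * sqrt(d)`), so unstructured data yields the smallest candidate
#' while separated structure still wins by an order of magnitude.
#' Ties go to the smallest `k`.
#'
#' @param fm Feature matrix from [build_features()].
#' @param k_range Integer vector of candidate cluster counts.
#' @param restarts,seed Passed to [kmeans_corr()] (a distinct seed is
#'   derived per `k`).
#' @return The AIC-best `cluster_model`, with attribute `aic_table`
#'   (data frame of `k`, `wcss`, `aic`).
#' @export
select_k_aic <- function(fm, k_range, restarts = 50, seed = 1) {
  stopifnot(length(k_range) >= 1)
  k_range <- sort(unique(as.integer(k_range)))
  fits <- lapply(seq_along(k_range), function(i) {
    kmeans_corr(fm, k_range[i], restarts = restarts, seed = seed + i)
  })
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- fits[[which.min(aics)]]  # which.min takes first (smallest k) on ties
  attr(best, "aic_table") <- data.frame(
    k = k_range, wcss = vapply(fits, `[[`, numeric(1), "wcss"), aic = aics)
  best
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected pair-counting agreement (Hubert-Arabie) computed from
#' the contingency table: 1 for identical partitions (up to relabeling),
#' expectation 0 under independent random labelings. When the correction
#' denominator is 0 (both partitions trivial), 1 is returned by
#' convention.
#'
#' @param a,b Cluster label vectors over the same elements.
#' @return The ARI.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop("partitions must be over the same element set")
  }
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  sa <- sum(ch2(rowSums(tab)))
  sb <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  expected <- sa * sb / n2
  maxi <- (sa + sb) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

#' Overlap of the top of two ranked gene lists
#'
#' @param list_a,list_b Character vectors ranking the same gene universe.
#' @param top_n How many leading genes to compare.
#' @return Size of the intersection of the two top-`top_n` sets.
#' @export
rank_overlap <- function(list_a, list_b, top_n) {
  if (!setequal(list_a, list_b)) {
    stop("ranked lists must cover the same gene universe")
  }
  if (top_n > length(list_a)) {
    stop("top_n exceeds the size of the gene universe")
  }
  length(intersect(list_a[seq_len(top_n)], list_b[seq_len(top_n)]))
}
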