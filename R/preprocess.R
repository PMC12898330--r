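# Normalization, filtering, transformation and QC preceding network
# construction.

#' Median-of-ratios size factors
#'
#' For the gene set with all-positive counts, each gene's geometric mean is
#' the reference; a sample's size factor is the median over those genes of
#' count / geometric mean, rescaled so the size factors have geometric
#' mean 1.
#'
#' @param cm a [count_matrix()] or a plain counts matrix.
#' @return named positive numeric vector, one per sample.
#' @export
size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has all-positive counts; filter low-count genes first")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)                       # log geometric means
  s <- exp(apply(lg - ref, 2, median))
  s <- s / exp(mean(log(s)))                # geometric mean 1
  if (any(!is.finite(s) | s <= 0)) stop("non-finite size factor")
  s
}

#' Low-count gene filter
#'
#' Keeps genes with `count >= min_count` in at least `min_samples` samples;
#' gene order is preserved.
#'
#' @param cm a [count_matrix()].
#' @param min_count count threshold (>= 0).
#' @param min_samples sample threshold; `NA` means the smaller group size.
#' @return a filtered [count_matrix()].
#' @export
filter_low_counts <- function(cm, min_count = 10, min_samples = NA) {
  if (min_count < 0 || (!is.na(min_samples) && min_samples < 0))
    stop("thresholds must be >= 0")
  if (is.na(min_samples)) min_samples <- min(table(cm$condition))
  keep <- rowSums(cm$counts >= min_count) >= min_samples
  if (!any(keep)) stop("low-count filter removed every gene")
  count_matrix(cm$counts[keep, , drop = FALSE], cm$condition)
}

#' Shifted-log normalized expression
#'
#' Elementwise `log2(count / s + pseudocount)` with per-sample size factors
#' `s`. A variance-stabilizing replacement for dispersion-model transforms:
#' downstream correlation networks only need a monotone, finite transform.
#'
#' @param cm a [count_matrix()].
#' @param s size factors (default [size_factors()]).
#' @param pseudocount positive shift.
#' @return genes x samples numeric matrix.
#' @export
log_normalize <- function(cm, s = size_factors(cm), pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  x <- log2(sweep(cm$counts, 2, s, `/`) + pseudocount)
  if (any(!is.finite(x))) stop("non-finite normalized value")
  x
}

#' Sample outlier detection by clustering height and PCA distance
#'
#' A sample is flagged when (a) its merge height in average-linkage
#' hierarchical clustering of Euclidean sample distances exceeds the median
#' height plus `z_height` MADs, or (b) its distance from the centroid in the
#' first two principal components exceeds the mean distance plus `z_pca`
#' standard deviations. Leaf merge heights are right-skewed even for
#' homogeneous data (the last sample to join any cluster merges high), so
#' the height cutoff defaults to 5 MADs, calibrated so that homogeneous
#' cohorts are flag-free in at least 95 percent of runs while a sample
#' shifted by a few standard deviations on all genes is still far beyond
#' the threshold; the PCA rule keeps the conventional 3.
#'
#' @param expr genes x samples expression matrix (>= 4 samples).
#' @param z_height,z_pca robust z cutoffs (defaults 5 and 3).
#' @return data.frame of class `qc_report`: sample, cluster_height,
#'   pca_distance, flag_height, flag_pca, outlier, rule; thresholds stored as
#'   attributes.
#' @export
detect_outliers <- function(expr, z_height = 5, z_pca = 3) {
  n <- ncol(expr)
  if (n < 4) stop("outlier detection needs >= 4 samples")
  hc <- hclust(dist(t(expr)), method = "average")
  # height at which each leaf first merges
  leaf_h <- numeric(n)
  for (r in seq_len(nrow(hc$merge))) {
    for (leaf in -hc$merge[r, ][hc$merge[r, ] < 0])
      leaf_h[leaf] <- hc$height[r]
  }
  thr_h <- median(leaf_h) + z_height * mad(leaf_h)
  flag_h <- leaf_h > thr_h
  pc <- prcomp(t(expr), center = TRUE, scale. = FALSE)
  sc <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  d <- sqrt(rowSums(sweep(sc, 2, colMeans(sc))^2))
  thr_p <- mean(d) + z_pca * sd(d)
  flag_p <- d > thr_p
  rule <- ifelse(flag_h & flag_p, "height+pca",
                 ifelse(flag_h, "height", ifelse(flag_p, "pca", "")))
  out <- data.frame(sample = colnames(expr), cluster_height = leaf_h,
                    pca_distance = unname(d), flag_height = flag_h,
                    flag_pca = unname(flag_p), outlier = flag_h | flag_p,
                    rule = rule, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(height = thr_h, pca = thr_p,
                               z_height = z_height, z_pca = z_pca)
  class(out) <- c("qc_report", "data.frame")
  out
}
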