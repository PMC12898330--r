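# Site-to-pair significance for miRNA-lncRNA binding: add-one empirical
# p-values from a -logKd null, covariate-weighted FDR for site retention,
# aggregated Cauchy combination per pair, BH across pairs.

#' Add-one empirical upper-tail p-values
#'
#' `p = (1 + #\{null >= observed\}) / (N + 1)`: never exactly 0, exactly
#' `1 / (N + 1)` when the observation exceeds every null value.
#'
#' @param observed numeric vector of observed -logKd values.
#' @param null numeric null sample (N >= 100).
#' @return p-values in (0, 1].
#' @export
empirical_p <- function(observed, null) {
  if (!length(null)) stop("empty null sample")
  if (length(null) < 100) stop("null sample must have >= 100 values")
  n <- length(null)
  vapply(observed, function(o) (1 + sum(null >= o)) / (n + 1), numeric(1))
}

#' Covariate-weighted FDR with cross-fitted quantile-bin weights
#'
#' Sites are binned by covariate quantiles; per-bin weights proportional to
#' the (floored) excess fraction of small p-values are estimated by
#' cross-fitting (each fold's weights come from the other folds only, so a
#' site's own p never informs its weight), normalized to mean 1 within the
#' fold, and weighted BH is applied to `p / w`. With `n_bins = 1` (or
#' constant covariate) the result is element-wise identical to plain BH.
#' Bins with fewer than 10 sites are merged with a warning.
#'
#' @param p raw p-values.
#' @param covariate per-site covariate, independent of p under the null
#'   (e.g. sites per transcript). Must not be a function of p itself.
#' @param n_bins number of quantile bins.
#' @param alpha small-p threshold used in the weight estimate (and the
#'   nominal FDR level downstream).
#' @param n_folds cross-fitting folds (assigned deterministically round
#'   robin in covariate order).
#' @return list: `q` (weighted-BH adjusted values), `w` (per-site weights),
#'   `bin` (per-site bin id).
#' @export
weighted_fdr <- function(p, covariate, n_bins = 5, alpha = 0.05, n_folds = 5) {
  stopifnot(length(p) == length(covariate), n_bins >= 1)
  m <- length(p)
  if (n_bins == 1 || length(unique(covariate)) == 1) {
    return(list(q = p.adjust(p, "BH"), w = rep(1, m), bin = rep(1L, m)))
  }
  br <- unique(quantile(covariate, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- as.integer(cut(covariate, br, include.lowest = TRUE))
  # merge undersized bins into their left neighbour
  repeat {
    sz <- table(factor(bin, levels = seq_len(max(bin))))
    small <- which(sz > 0 & sz < 10)
    if (!length(small) || length(unique(bin)) == 1) break
    warning("merging covariate bin with < 10 sites")
    b <- small[1]
    bin[bin == b] <- if (b > 1) b - 1L else min(bin[bin > b])
  }
  bin <- as.integer(factor(bin))
  if (length(unique(bin)) == 1)
    return(list(q = p.adjust(p, "BH"), w = rep(1, m), bin = bin))
  n_folds <- min(n_folds, m)
  fold <- (rank(covariate, ties.method = "first") - 1L) %% n_folds + 1L
  w <- rep(NA_real_, m)
  for (f in seq_len(n_folds)) {
    hold <- fold == f
    raw <- vapply(sort(unique(bin)), function(b) {
      pb <- p[!hold & bin == b]
      if (!length(pb)) return(0.2)
      0.2 + max(mean(pb < alpha) - alpha, 0)
    }, numeric(1))
    wi <- raw[bin[hold]]
    w[hold] <- wi / mean(wi)                  # mean weight 1 within fold
  }
  q <- p.adjust(pmin(p / w, 1), "BH")
  list(q = q, w = w, bin = bin)
}

#' Aggregated Cauchy combination of p-values
#'
#' `T = sum w_i tan((0.5 - p_i) pi) / sum w_i`;
#' `combined p = 0.5 - atan(T) / pi`. Inputs are clipped to
#' `[1e-15, 1 - 1e-15]`. With all p equal and equal weights the combined p
#' equals the common value.
#'
#' @param p p-values in (0, 1).
#' @param w positive weights (default equal).
#' @return combined p-value in (0, 1).
#' @export
acat <- function(p, w = NULL) {
  if (!length(p)) stop("empty p-value list")
  if (is.null(w)) w <- rep(1, length(p))
  stopifnot(length(w) == length(p), all(w > 0))
  eps <- 1e-15
  p <- pmin(pmax(p, eps), 1 - eps)
  t_stat <- sum(w * tan((0.5 - p) * pi)) / sum(w)
  0.5 - atan(t_stat) / pi
}

#' Site-to-pair significance pipeline
#'
#' Computes add-one empirical p-values per site against the null sample,
#' retains sites with covariate-weighted FDR `q < alpha`, combines each
#' pair's retained sites' *raw* p-values with the aggregated Cauchy method,
#' applies BH across the pairs with at least one retained site, and flags
#' pairs with `q < alpha`. Pairs with no retained site are reported
#' non-significant with `n_sites_retained = 0`.
#'
#' @param sites a [site_kd_table()].
#' @param null null -logKd sample; default: the pooled observed values
#'   (label-shuffle null). Supply a clean external sample when a large
#'   signal fraction would contaminate the pool.
#' @param covariate per-site covariate for [weighted_fdr()]; default: the
#'   number of sites on the site's transcript.
#' @param n_bins,alpha,n_folds see [weighted_fdr()].
#' @return list: `sites` (site table + p, q, weight, retained), `pairs`
#'   (data.frame mirna_id, transcript_id, n_sites, n_sites_retained,
#'   combined_p, q, significant).
#' @export
pair_pipeline <- function(sites, null = NULL, covariate = NULL, n_bins = 5,
                          alpha = 0.05, n_folds = 5) {
  df <- as.data.frame(sites)
  if (is.null(null)) null <- df$neg_log_kd
  if (is.null(covariate))
    covariate <- ave(df$neg_log_kd, df$transcript_id, FUN = length)
  df$p <- empirical_p(df$neg_log_kd, null)
  wf <- weighted_fdr(df$p, covariate, n_bins = n_bins, alpha = alpha,
                     n_folds = n_folds)
  df$q <- wf$q
  df$weight <- wf$w
  df$retained <- df$q < alpha
  key <- interaction(df$mirna_id, df$transcript_id, drop = TRUE)
  pairs <- do.call(rbind, lapply(split(df, key), function(d) {
    ret <- d[d$retained, , drop = FALSE]
    data.frame(mirna_id = d$mirna_id[1], transcript_id = d$transcript_id[1],
               n_sites = nrow(d), n_sites_retained = nrow(ret),
               combined_p = if (nrow(ret)) acat(ret$p) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  tested <- !is.na(pairs$combined_p)
  pairs$q <- NA_real_
  if (any(tested)) pairs$q[tested] <- p.adjust(pairs$combined_p[tested], "BH")
  pairs$significant <- !is.na(pairs$q) & pairs$q < alpha
  list(sites = df, pairs = pairs)
}
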