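# Signed weighted co-expression network, topological overlap, module
# detection with eigengene merging, and module-trait correlation. This is
# the inner engine that the leave-one-out stability procedure re-runs.

#' Soft-threshold power selection by scale-free topology fit
#'
#' For each candidate power the signed adjacency is built, connectivities
#' are binned, and log10 p(k) is regressed on log10 k; the fit index is the
#' regression R-squared signed by the slope (positive only for a decreasing
#' degree distribution). The smallest power reaching `rsq_cut` wins; if none
#' does, the power with the maximal fit index.
#'
#' @param expr genes x samples matrix (>= 8 samples).
#' @param powers candidate powers (>= 2 of them).
#' @param rsq_cut fit threshold, default 0.8.
#' @param n_bins connectivity histogram bins.
#' @return list: `power` (selected), `table` (power, rsq, slope, mean_k).
#' @export
pick_power <- function(expr, powers = 1:20, rsq_cut = 0.8, n_bins = 10) {
  if (length(powers) < 2) stop("need at least 2 candidate powers")
  if (ncol(expr) < 8) stop("power selection needs >= 8 samples")
  sim <- (1 + cor(t(expr))) / 2
  diag(sim) <- 0
  fit_one <- function(beta) {
    k <- rowSums(sim^beta)
    br <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, br, include.lowest = TRUE)
    pk <- tapply(k, bin, length) / length(k)
    mk <- tapply(k, bin, mean)
    ok <- !is.na(pk) & pk > 0 & mk > 0
    if (sum(ok) < 3) return(c(rsq = NA_real_, slope = NA_real_, mean_k = mean(k)))
    fit <- stats::lm(log10(pk[ok]) ~ log10(mk[ok]))
    r2 <- summary(fit)$r.squared
    sl <- stats::coef(fit)[2]
    c(rsq = unname(-sign(sl) * r2), slope = unname(sl), mean_k = mean(k))
  }
  tab <- t(vapply(powers, fit_one, numeric(3)))
  tab <- data.frame(power = powers, tab)
  hit <- which(!is.na(tab$rsq) & tab$rsq >= rsq_cut)
  power <- if (length(hit)) powers[hit[1]] else powers[which.max(tab$rsq)]
  list(power = power, table = tab)
}

#' Signed adjacency and topological overlap network
#'
#' Adjacency `a_ij = ((1 + cor_ij) / 2)^beta` with Pearson correlation
#' across samples (signed network: anti-correlated genes get adjacency near
#' 0). The topological overlap is
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `k_i = sum_{u != i} a_iu`; diagonals are 1.
#'
#' @param expr genes x samples matrix; every gene must have variance > 0.
#' @param beta soft-threshold power.
#' @return object of class `coexpr_network`: list(genes, adjacency, tom,
#'   power).
#' @export
build_network <- function(expr, beta) {
  v <- apply(expr, 1, var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(head(rownames(expr)[v == 0], 5), collapse = ", "),
         " (filter upstream)")
  a <- ((1 + cor(t(expr))) / 2)^beta
  diag(a) <- 1
  k <- rowSums(a) - 1
  num <- a %*% a - 2 * a           # sum_u a_iu a_uj for u != i,j (diag(a)=1)
  num <- num + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2        # kill numeric asymmetry
  structure(list(genes = rownames(expr), adjacency = a, tom = tom,
                 power = beta), class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat("coexpr_network:", length(x$genes), "genes, power", x$power, "\n")
  invisible(x)
}

# first-PC eigengene of a member expression block (genes x samples), unit
# variance, sign-oriented so the mean correlation with members is positive
module_eigengene <- function(block) {
  z <- t(scale(t(block)))
  e <- svd(z, nu = 0, nv = 1)$v[, 1]
  e <- as.vector(scale(e))
  if (mean(cor(e, t(block))) < 0) e <- -e
  e
}

#' Module detection on the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, a static cut at
#' `cut_height` (default: the 0.75 quantile of merge heights, i.e. 0.25 from
#' the top), removal of clusters smaller than `min_size` (label 0 =
#' unassigned), a membership refinement that strips genes whose correlation
#' with their module eigengene is not significantly positive (Student test
#' at `kme_alpha`; the sample-size-adaptive analogue of a fixed kME cut,
#' which keeps the static cut honest when noise genes attach to a cluster),
#' and iterative merging of modules whose eigengene correlation exceeds
#' `1 - merge_cut` (closest pair first, eigengenes recomputed after each
#' merge). Final labels are 1, 2, ... by decreasing module size.
#'
#' @param net a [build_network()] result.
#' @param expr the expression matrix the network was built from.
#' @param cut_height static cut height (NA = data-driven default).
#' @param min_size minimum module size.
#' @param merge_cut eigengene merge cut; 0 disables merging.
#' @param kme_alpha significance level of the membership refinement; 0
#'   disables it.
#' @return object of class `module_set`: list(labels (named integer),
#'   eigengenes (samples x modules matrix), params).
#' @export
detect_modules <- function(net, expr, cut_height = NA, min_size = 30,
                           merge_cut = 0.25, kme_alpha = 0.01) {
  diss <- 1 - net$tom
  hc <- hclust(as.dist(diss), method = "average")
  if (is.na(cut_height)) cut_height <- unname(quantile(hc$height, 0.75))
  params <- list(power = net$power, cut_height = cut_height,
                 min_size = min_size, merge_cut = merge_cut,
                 kme_alpha = kme_alpha)
  empty <- function() {
    warning("no module of size >= ", min_size, " detected")
    structure(list(labels = setNames(rep(0L, length(net$genes)), net$genes),
                   eigengenes = NULL, params = params),
              class = "module_set")
  }
  lab <- cutree(hc, h = cut_height)
  sz <- table(lab)
  keep <- names(sz)[sz >= min_size]
  lab[!lab %in% as.integer(keep)] <- 0L
  if (all(lab == 0)) return(empty())
  # membership refinement: drop members not significantly positively
  # correlated with their module eigengene
  if (kme_alpha > 0) {
    n <- ncol(expr)
    tc <- stats::qt(1 - kme_alpha / 2, df = n - 2)
    r_crit <- tc / sqrt(n - 2 + tc^2)
    for (b in unique(lab[lab > 0])) {
      mem <- lab == b
      e <- module_eigengene(expr[mem, , drop = FALSE])
      r <- as.vector(cor(t(expr[mem, , drop = FALSE]), e))
      idx <- which(mem)
      lab[idx[r < r_crit]] <- 0L
      if (sum(lab == b) < min_size) lab[lab == b] <- 0L
    }
    if (all(lab == 0)) return(empty())
  }
  # compact to 1..K
  ids <- sort(unique(lab[lab > 0]))
  lab <- unname(ifelse(lab == 0, 0L, match(lab, ids)))
  eig <- function(m) module_eigengene(expr[lab == m, , drop = FALSE])
  E <- vapply(seq_along(ids), eig, numeric(ncol(expr)))
  # iterative eigengene merging, closest pair first
  if (merge_cut > 0) {
    repeat {
      K <- ncol(E)
      if (K < 2) break
      ce <- cor(E)
      diag(ce) <- -Inf
      mx <- which(ce == max(ce), arr.ind = TRUE)[1, ]
      if (ce[mx[1], mx[2]] <= 1 - merge_cut) break
      a <- min(mx); b <- max(mx)
      lab[lab == b] <- a
      lab[lab > b] <- lab[lab > b] - 1L
      E <- vapply(seq_len(K - 1),
                  function(m) module_eigengene(expr[lab == m, , drop = FALSE]),
                  numeric(ncol(expr)))
      E <- matrix(E, ncol = K - 1)
    }
  }
  # order by decreasing size
  sz <- table(factor(lab[lab > 0], levels = seq_len(ncol(as.matrix(E)))))
  ord <- order(-as.integer(sz))
  relab <- match(seq_along(ord), ord)
  newlab <- lab
  newlab[lab > 0] <- relab[lab[lab > 0]]
  E <- as.matrix(E)[, ord, drop = FALSE]
  colnames(E) <- paste0("ME", seq_len(ncol(E)))
  rownames(E) <- colnames(expr)
  structure(list(labels = setNames(as.integer(newlab), net$genes),
                 eigengenes = E, params = params),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  k <- if (is.null(x$eigengenes)) 0 else ncol(x$eigengenes)
  cat("module_set:", k, "module(s);", sum(x$labels == 0), "unassigned gene(s)\n")
  invisible(x)
}

#' Gene ids of one module
#' @param modset a [detect_modules()] result.
#' @param m module label.
#' @return character vector of member gene ids.
#' @export
module_genes <- function(modset, m) names(modset$labels)[modset$labels == m]

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with the binary trait and
#' the Student-transformed two-sided p-value,
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param modset a [detect_modules()] result with >= 1 module.
#' @param condition numeric 0/1 trait, one value per sample (n >= 4).
#' @param alpha significance flag level, default 0.05.
#' @return data.frame: module, r, t, p, n, significant.
#' @export
module_trait <- function(modset, condition, alpha = 0.05) {
  if (is.null(modset$eigengenes)) stop("module set is empty")
  n <- length(condition)
  if (n < 4) stop("module-trait correlation needs n >= 4")
  if (nrow(modset$eigengenes) != n) stop("condition length mismatch")
  res <- lapply(seq_len(ncol(modset$eigengenes)), function(m) {
    e <- modset$eigengenes[, m]
    if (sd(e) == 0) stop("constant eigengene in module ", m)
    r <- cor(e, condition)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
    data.frame(module = m, r = r, t = tt, p = p, n = n,
               significant = p < alpha)
  })
  do.call(rbind, res)
}

#' Export a TOM edge list for graph viewers
#'
#' @param net a [build_network()] result.
#' @param modset optional module set to annotate endpoints.
#' @param tom_threshold minimum TOM to keep an edge.
#' @return data.frame gene1, gene2, tom (plus module columns if `modset`).
#' @export
export_edges <- function(net, modset = NULL, tom_threshold = 0.1) {
  idx <- which(upper.tri(net$tom) & net$tom > tom_threshold, arr.ind = TRUE)
  out <- data.frame(gene1 = net$genes[idx[, 1]], gene2 = net$genes[idx[, 2]],
                    tom = net$tom[idx], stringsAsFactors = FALSE)
  if (!is.null(modset)) {
    out$module1 <- modset$labels[out$gene1]
    out$module2 <- modset$labels[out$gene2]
  }
  out[order(-out$tom), ]
}
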