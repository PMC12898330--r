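# Leave-one-out jackknife module stability: re-detect modules with each
# sample removed (identical network parameters, no power re-selection),
# match modules back by Jaccard, and score composition preservation and
# eigengene-trait sign preservation.

#' Jaccard similarity of two gene sets
#'
#' Intersection over union; 1 when both sets are empty (convention).
#'
#' @param a,b character vectors (sets).
#' @return number in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Leave-one-out jackknife stability of co-expression modules
#'
#' Runs the full network + module detection + module-trait analysis, then,
#' for each sample, removes it and reruns network construction and module
#' detection with the *same* soft-threshold power and cut parameters (the
#' full run's data-driven cut height is frozen and reused; the power is not
#' re-selected). Each full-network module is matched to the leave-one-out
#' (LOO) module maximizing Jaccard similarity of gene composition (ties:
#' larger LOO module, then lower label; label 0 never participates). A
#' module's verdict is `stable` iff its eigengene-trait correlation keeps
#' the full-network sign in every iteration and its minimum matched Jaccard
#' is at least `jaccard_threshold`.
#'
#' @param expr genes x samples expression matrix (>= 5 samples).
#' @param condition numeric 0/1 trait per sample; both levels must survive
#'   every single-sample removal (i.e. each group has >= 2 samples).
#' @param beta soft-threshold power (fixed across iterations).
#' @param cut_height,min_size,merge_cut module-detection parameters, see
#'   [detect_modules()]; an `NA` cut height is resolved on the full data and
#'   then frozen.
#' @param kme_alpha membership refinement level, see [detect_modules()].
#' @param jaccard_threshold minimum per-iteration Jaccard, default 0.5.
#' @return object of class `stability_report`: list with `summary`
#'   (data.frame module, full_r, n_iterations, sign_preserved, min_jaccard,
#'   median_jaccard, verdict), `jaccard` and `trait_r` (modules x iterations
#'   matrices), `full` (the full-run module set) and `full_trait`.
#' @export
loo_stability <- function(expr, condition, beta, cut_height = NA,
                          min_size = 30, merge_cut = 0.25, kme_alpha = 0.01,
                          jaccard_threshold = 0.5) {
  n <- ncol(expr)
  if (n < 5) stop("leave-one-out stability needs >= 5 samples")
  if (any(table(condition) < 2))
    stop("a condition level would vanish on single-sample removal")
  net <- build_network(expr, beta)
  full <- detect_modules(net, expr, cut_height = cut_height,
                         min_size = min_size, merge_cut = merge_cut,
                         kme_alpha = kme_alpha)
  if (is.null(full$eigengenes)) {
    warning("no module detected on the full data; empty stability report")
    return(structure(list(
      summary = data.frame(module = integer(0), full_r = numeric(0),
                           n_iterations = integer(0),
                           sign_preserved = logical(0),
                           min_jaccard = numeric(0),
                           median_jaccard = numeric(0),
                           verdict = character(0), stringsAsFactors = FALSE),
      jaccard = matrix(numeric(0), 0, n), trait_r = matrix(numeric(0), 0, n),
      full = full, full_trait = NULL,
      jaccard_threshold = jaccard_threshold), class = "stability_report"))
  }
  cut_height <- full$params$cut_height        # freeze the data-driven cut
  ft <- module_trait(full, condition)
  K <- ncol(full$eigengenes)
  full_sets <- lapply(seq_len(K), function(m) module_genes(full, m))
  jac <- matrix(NA_real_, K, n)
  tr <- matrix(NA_real_, K, n)
  for (i in seq_len(n)) {
    e_i <- expr[, -i, drop = FALSE]
    keep <- apply(e_i, 1, var) > 0
    e_i <- e_i[keep, , drop = FALSE]
    net_i <- build_network(e_i, beta)
    mod_i <- suppressWarnings(
      detect_modules(net_i, e_i, cut_height = cut_height,
                     min_size = min_size, merge_cut = merge_cut,
                     kme_alpha = kme_alpha))
    Ki <- if (is.null(mod_i$eigengenes)) 0 else ncol(mod_i$eigengenes)
    loo_sets <- if (Ki) lapply(seq_len(Ki), function(m) module_genes(mod_i, m))
                else list()
    for (m in seq_len(K)) {
      if (!Ki) { jac[m, i] <- 0; next }
      js <- vapply(loo_sets, jaccard, numeric(1), a = full_sets[[m]])
      sizes <- lengths(loo_sets)
      best <- order(-js, -sizes, seq_along(js))[1]   # ties: larger, lower label
      jac[m, i] <- js[best]
      tr[m, i] <- cor(mod_i$eigengenes[, best], condition[-i])
    }
  }
  sign_ok <- vapply(seq_len(K), function(m) {
    all(!is.na(tr[m, ])) && all(sign(tr[m, ]) == sign(ft$r[m])) &&
      all(tr[m, ] != 0)
  }, logical(1))
  minj <- apply(jac, 1, min)
  summary <- data.frame(
    module = seq_len(K), full_r = ft$r, n_iterations = n,
    sign_preserved = sign_ok, min_jaccard = minj,
    median_jaccard = apply(jac, 1, median),
    verdict = ifelse(sign_ok & minj >= jaccard_threshold, "stable", "unstable"),
    stringsAsFactors = FALSE
  )
  structure(list(summary = summary, jaccard = jac, trait_r = tr,
                 full = full, full_trait = ft,
                 jaccard_threshold = jaccard_threshold),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
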