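# FMO-threshold gating, MDSC subset frequencies with group comparisons, and
# per-event KNN group-enrichment mapping.

#' FMO positivity thresholds
#'
#' The threshold for each marker is a percentile (default 99) of that
#' marker's fluorescence-minus-one control distribution.
#'
#' @param fmo named list of single-group [event_table()]s, one per marker
#'   (each >= 100 events).
#' @param percentile percentile in (0, 100).
#' @return named numeric vector of thresholds.
#' @export
fmo_thresholds <- function(fmo, percentile = 99) {
  vapply(names(fmo), function(m) {
    tab <- fmo[[m]]
    if (nrow(tab$intensities) < 100)
      stop("FMO control for '", m, "' has < 100 events")
    if (!m %in% colnames(tab$intensities))
      stop("FMO table for '", m, "' lacks that marker column")
    unname(quantile(tab$intensities[, m], percentile / 100))
  }, numeric(1))
}

#' Default MDSC gate tree
#'
#' Total MDSC = Lin- HLA-DR-/low CD33+ CD11b+; within it PMN-MDSC =
#' CD15+ CD14-, M-MDSC = CD14+ CD15-, e-MDSC = CD14- CD15-. "Low" is
#' operationalized as below the FMO-derived threshold. Each gate is a list
#' of positive and negative marker predicates plus its parent gate.
#'
#' @return named list of gates (name, parent, pos, neg).
#' @export
mdsc_gate_tree <- function() {
  list(
    mdsc_total = list(parent = NA_character_,
                      pos = c("CD33", "CD11b"), neg = c("Lin", "HLA-DR")),
    pmn_mdsc = list(parent = "mdsc_total", pos = "CD15", neg = "CD14"),
    m_mdsc = list(parent = "mdsc_total", pos = "CD14", neg = "CD15"),
    e_mdsc = list(parent = "mdsc_total", pos = character(0),
                  neg = c("CD14", "CD15"))
  )
}

# events x gates logical membership matrix (child gates intersect parents)
gate_membership <- function(events, gates, thresholds) {
  x <- events$intensities
  for (g in gates) {
    for (m in c(g$pos, g$neg))
      if (!m %in% colnames(x)) stop("gated marker '", m, "' not in panel")
    for (m in c(g$pos, g$neg))
      if (!m %in% names(thresholds)) stop("no threshold for gated marker '", m, "'")
  }
  mem <- matrix(NA, nrow(x), length(gates), dimnames = list(NULL, names(gates)))
  for (gn in names(gates)) {
    g <- gates[[gn]]
    ok <- rep(TRUE, nrow(x))
    for (m in g$pos) ok <- ok & x[, m] > thresholds[[m]]
    for (m in g$neg) ok <- ok & x[, m] <= thresholds[[m]]
    if (!is.na(g$parent)) ok <- ok & mem[, g$parent]
    mem[, gn] <- ok
  }
  mem
}

#' Per-sample gated subset percentages
#'
#' For every gate, the percentage of its parent-gate events (all events for
#' root gates) per sample. Samples with an empty parent gate get `NA` with
#' a warning.
#'
#' @param events an [event_table()].
#' @param gates gate tree, see [mdsc_gate_tree()].
#' @param thresholds named thresholds covering all gated markers, see
#'   [fmo_thresholds()].
#' @return data.frame: sample_id, group, then one percentage column per
#'   gate.
#' @export
gate_frequencies <- function(events, gates = mdsc_gate_tree(), thresholds) {
  mem <- gate_membership(events, gates, thresholds)
  samples <- unique(events$sample_id)
  out <- data.frame(sample_id = samples,
                    group = as.character(events$group)[match(samples, events$sample_id)],
                    stringsAsFactors = FALSE)
  for (gn in names(gates)) {
    par <- gates[[gn]]$parent
    pct <- vapply(samples, function(s) {
      si <- events$sample_id == s
      denom <- if (is.na(par)) sum(si) else sum(mem[si, par])
      if (denom == 0) return(NA_real_)
      100 * sum(mem[si, gn]) / denom
    }, numeric(1))
    if (anyNA(pct)) warning("empty parent gate for '", gn, "' in some sample(s)")
    out[[gn]] <- unname(pct)
  }
  out
}

#' Marker-positivity percentages within gated subsets
#'
#' @param events an [event_table()].
#' @param gates gate tree; positivity is computed within each gate.
#' @param thresholds named thresholds (must cover `markers` too).
#' @param markers markers to score (e.g. checkpoint panel).
#' @return data.frame: sample_id, group, subset, then one percent-positive
#'   column per marker.
#' @export
marker_positivity <- function(events, gates = mdsc_gate_tree(), thresholds,
                              markers = c("CD47", "SIRPa", "Gal-9", "CD73", "PD-L1")) {
  mem <- gate_membership(events, gates, thresholds)
  x <- events$intensities
  samples <- unique(events$sample_id)
  rows <- list()
  for (gn in names(gates)) for (s in samples) {
    idx <- which(events$sample_id == s & mem[, gn])
    row <- data.frame(sample_id = s,
                      group = as.character(events$group)[match(s, events$sample_id)],
                      subset = gn, stringsAsFactors = FALSE)
    for (m in markers)
      row[[m]] <- if (length(idx)) 100 * mean(x[idx, m] > thresholds[[m]]) else NA_real_
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}

#' Group comparison of per-sample percentages
#'
#' Mann-Whitney U by default; in `auto` mode Welch's t-test is used when an
#' F test rejects variance homogeneity at 0.05. Two-sided p-values with
#' significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param values per-sample values (one subset).
#' @param group two-level factor (>= 3 per group).
#' @param test `"auto"`, `"mann_whitney"` or `"welch"`.
#' @return data.frame: test, p, stars.
#' @export
compare_groups <- function(values, group, test = c("auto", "mann_whitney", "welch")) {
  test <- match.arg(test)
  group <- factor(as.character(group))
  ok <- !is.na(values)
  values <- values[ok]; group <- droplevels(group[ok])
  if (nlevels(group) != 2 || any(table(group) < 3))
    stop("need two groups with >= 3 samples each")
  x <- values[group == levels(group)[1]]
  y <- values[group == levels(group)[2]]
  if (all(values == values[1]))           # fully tied: no evidence either way
    return(data.frame(test = if (test == "auto") "mann_whitney" else test,
                      p = 1, stars = "", stringsAsFactors = FALSE))
  if (test == "auto") {
    hetero <- var(x) > 0 && var(y) > 0 && var.test(x, y)$p.value < 0.05
    test <- if (hetero) "welch" else "mann_whitney"
  }
  p <- if (test == "welch") t.test(x, y, var.equal = FALSE)$p.value
  else suppressWarnings(wilcox.test(x, y, exact = NULL, correct = TRUE)$p.value)
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  data.frame(test = test, p = p, stars = stars, stringsAsFactors = FALSE)
}

#' Per-event KNN group-enrichment map
#'
#' After subsampling both groups to equal event counts, each event's
#' enrichment fraction `f` is the share of its k nearest neighbours
#' (Euclidean, self excluded) from the case group (second group level).
#' Events with `f >= tau` are `case_enriched`, with `f <= 1 - tau`
#' `control_enriched`, otherwise `shared`. Distances are computed in
#' z-scaled marker space, or in a supplied 2-D embedding.
#'
#' @param events an [event_table()] with both group levels present.
#' @param case group level treated as the case group (default: the second
#'   level in sorted order).
#' @param k neighbourhood size (`k < n - 1` after balancing).
#' @param tau enrichment cut, default 0.95.
#' @param space `"markers"` (z-scaled panel) or `"embedding"`.
#' @param seed seed for the balancing subsample.
#' @return object of class `enrichment_map`: list with `events` (data.frame
#'   event, sample_id, group, f, flag), `summary` (flagged proportions per
#'   group), `k`, `tau`, `space`.
#' @export
knn_enrichment <- function(events, k = 60, tau = 0.95,
                           space = c("markers", "embedding"), case = NULL,
                           seed = 1) {
  space <- match.arg(space)
  if (nlevels(events$group) != 2 || any(table(events$group) == 0))
    stop("both group levels must be present")
  if (is.null(case)) case <- levels(events$group)[2]
  if (!case %in% levels(events$group)) stop("unknown case level: ", case)
  if (space == "embedding" && is.null(events$embedding))
    stop("no embedding columns available")
  withr::local_seed(seed)
  idx_by_group <- split(seq_along(events$group), events$group)
  n_min <- min(lengths(idx_by_group))
  keep <- sort(unlist(lapply(idx_by_group, function(ii)
    if (length(ii) > n_min) sample(ii, n_min) else ii), use.names = FALSE))
  n <- length(keep)
  if (k >= n - 1) stop("k must be < n - 1 after balancing (n = ", n, ")")
  x <- if (space == "markers") scale(events$intensities[keep, , drop = FALSE])
  else events$embedding[keep, , drop = FALSE]
  grp <- events$group[keep]
  is_case <- grp == case
  d2 <- as.matrix(dist(x))^2
  diag(d2) <- Inf
  f <- vapply(seq_len(n), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]
    mean(is_case[nb])
  }, numeric(1))
  flag <- ifelse(f >= tau, "case_enriched",
                 ifelse(f <= 1 - tau, "control_enriched", "shared"))
  ev <- data.frame(event = keep, sample_id = events$sample_id[keep],
                   group = as.character(grp), f = f, flag = flag,
                   stringsAsFactors = FALSE)
  summary <- data.frame(
    group = c(setdiff(levels(grp), case), case),
    role = c("control", "case"),
    prop_flagged = c(mean(flag[!is_case] == "control_enriched"),
                     mean(flag[is_case] == "case_enriched")),
    stringsAsFactors = FALSE
  )
  structure(list(events = ev, summary = summary, k = k, tau = tau,
                 space = space), class = "enrichment_map")
}

#' @export
print.enrichment_map <- function(x, ...) {
  cat("enrichment_map: k =", x$k, ", tau =", x$tau, ", space =", x$space, "\n")
  print(x$summary)
  invisible(x)
}
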