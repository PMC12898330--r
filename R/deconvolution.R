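# Signature-based immune-cell enrichment scoring with reference-overlap
# filtering, Welch/BH group testing, and the marker-removal sensitivity
# protocol. The scorer is a rank-mean statistic: the analysis treats the
# upstream enrichment engine as a black box, so any monotone-invariant
# per-sample score works; the overlap filter, tests and sensitivity rerun
# are the substance.

#' Read a signature collection from a two-column CSV (cell_type, gene)
#' @param path CSV file.
#' @return named list of character vectors (one gene set per cell type).
#' @export
read_signatures <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene") %in% names(df)))
    stop("signature CSV needs columns cell_type and gene")
  sig <- split(df$gene, df$cell_type)
  lapply(sig, unique)
}

#' Rank-mean signature enrichment scores
#'
#' Per sample, genes are ranked ascending by expression;
#' `score = (mean rank of signature genes - (G + 1) / 2) / (G - 1)` with G
#' the total gene count. Scores lie in [-0.5, 0.5] and have expectation 0
#' under random ranks; being rank-based they are invariant to any monotone
#' transform of a sample's expression values.
#'
#' @param expr genes x samples expression matrix.
#' @param sig named list of gene sets (use [overlap_filter()] first).
#' @return cell types x samples score matrix.
#' @export
signature_score <- function(expr, sig) {
  G <- nrow(expr)
  measured <- lapply(sig, intersect, x = rownames(expr))
  empty <- lengths(measured) == 0
  if (any(empty))
    stop("signature(s) with zero measured genes: ",
         paste(names(sig)[empty], collapse = ", "), " (filter upstream)")
  if (any(G - lengths(measured) < 2))
    stop("need >= 2 genes outside every signature")
  R <- apply(expr, 2, rank)
  out <- t(vapply(measured, function(g)
    (colMeans(R[g, , drop = FALSE]) - (G + 1) / 2) / (G - 1),
    numeric(ncol(expr))))
  rownames(out) <- names(sig)
  out
}

#' Reference-gene overlap filter
#'
#' Retains a cell type iff the fraction of its signature genes present in
#' the measured gene set is strictly greater than `threshold` (default 0.9:
#' a signature at exactly 90 percent overlap is dropped).
#'
#' @param sig named list of gene sets.
#' @param measured character vector of measured gene ids.
#' @param threshold strict lower bound on the overlap fraction.
#' @return list: `sig` (retained, restricted to measured genes), `report`
#'   (data.frame cell_type, n_genes, n_measured, overlap, retained).
#' @export
overlap_filter <- function(sig, measured, threshold = 0.9) {
  ov <- vapply(sig, function(g) length(intersect(g, measured)) / length(g),
               numeric(1))
  report <- data.frame(cell_type = names(sig), n_genes = lengths(sig),
                       n_measured = vapply(sig, function(g)
                         length(intersect(g, measured)), integer(1)),
                       overlap = ov, retained = ov > threshold,
                       row.names = NULL, stringsAsFactors = FALSE)
  kept <- lapply(sig[ov > threshold], intersect, x = measured)
  list(sig = kept, report = report)
}

#' Welch tests with Benjamini-Hochberg correction across cell types
#'
#' @param scores cell types x samples score matrix.
#' @param condition two-level factor (or 0/1) per sample, >= 2 per group.
#' @return data.frame: cell_type, t, p, q (BH over the tested types),
#'   mean_case, mean_control.
#' @export
group_test <- function(scores, condition) {
  condition <- factor(as.character(condition))
  if (nlevels(condition) != 2 || any(table(condition) < 2))
    stop("need two groups with >= 2 samples each")
  ref <- levels(condition)[1]
  res <- lapply(rownames(scores), function(ct) {
    x <- scores[ct, condition != ref]   # case
    y <- scores[ct, condition == ref]   # control / reference
    if (var(x) == 0 && var(y) == 0)
      stop("zero variance in both groups for cell type '", ct, "'")
    tt <- t.test(x, y, var.equal = FALSE)
    data.frame(cell_type = ct, t = unname(tt$statistic), p = tt$p.value,
               mean_case = mean(x), mean_control = mean(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  out[, c("cell_type", "t", "p", "q", "mean_case", "mean_control")]
}

#' Marker-removal sensitivity analysis
#'
#' Reruns the overlap filter, scoring and group tests after deleting the
#' listed genes from both the expression matrix and every signature, and
#' reports per-type score correlations between the two runs. Types whose
#' signature is emptied (or falls under the overlap threshold) after removal
#' are reported as dropped.
#'
#' @param expr genes x samples expression matrix.
#' @param sig named list of gene sets.
#' @param condition two-level labels per sample.
#' @param remove non-empty character vector of genes to delete.
#' @param overlap_threshold see [overlap_filter()].
#' @return list: `before`, `after` (each list(scores, test, report)),
#'   `score_correlation` (per shared type), `dropped_after` (types retained
#'   before but not after).
#' @export
sensitivity_removal <- function(expr, sig, condition, remove,
                                overlap_threshold = 0.9) {
  if (!length(remove)) stop("remove list must be non-empty")
  run <- function(e, s) {
    fl <- overlap_filter(s, rownames(e), overlap_threshold)
    if (!length(fl$sig))
      return(list(scores = NULL, test = NULL, report = fl$report))
    sc <- signature_score(e, fl$sig)
    list(scores = sc, test = group_test(sc, condition), report = fl$report)
  }
  before <- run(expr, sig)
  expr2 <- expr[setdiff(rownames(expr), remove), , drop = FALSE]
  sig2 <- lapply(sig, setdiff, y = remove)
  sig2 <- sig2[lengths(sig2) > 0]
  after <- run(expr2, sig2)
  shared <- intersect(rownames(before$scores), rownames(after$scores))
  sc_cor <- vapply(shared, function(ct)
    cor(before$scores[ct, ], after$scores[ct, ]), numeric(1))
  dropped <- setdiff(rownames(before$scores), rownames(after$scores))
  list(before = before, after = after,
       score_correlation = sc_cor, dropped_after = dropped)
}

#' Default neutrophil marker removal list
#'
#' The ten canonical granule and lineage markers named in the sensitivity
#' protocol (MPO, ELANE, PRTN3, DEFA1/3/4, FCGR3B, CEACAM8, S100A8/A9)
#' completed to 25 with well-established neutrophil granule, receptor and
#' lineage genes. Editable: pass any list to [sensitivity_removal()].
#'
#' @return character vector of 25 gene symbols.
#' @export
neutrophil_removal_genes <- function() {
  c("MPO", "ELANE", "PRTN3", "DEFA1", "DEFA3", "DEFA4", "FCGR3B", "CEACAM8",
    "S100A8", "S100A9",
    "LCN2", "LTF", "CAMP", "CTSG", "AZU1", "BPI", "MMP8", "MMP9", "CD177",
    "CSF3R", "CXCR2", "FPR1", "SIGLEC5", "CEACAM3", "OLFM4")
}
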