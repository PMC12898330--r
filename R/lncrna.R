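# Post-assembly lncRNA discovery stages: dual-route consensus by intron
# chain, the filter cascade, strand-aware genomic-context classification,
# nearest-gene annotation and target prioritization.

# canonical intron-chain key (chrom, strand, ordered intron intervals)
chain_key <- function(tx) {
  intr <- tx_introns(tx)
  paste(tx$chrom, tx$strand,
        paste(intr[, 1], intr[, 2], sep = "-", collapse = ";"), sep = "|")
}

exon_granges <- function(txs) {
  if (!length(txs)) return(GenomicRanges::GRanges())
  ex <- do.call(rbind, lapply(txs, function(tx)
    data.frame(chrom = tx$chrom, start = tx$exons[, 1], end = tx$exons[, 2],
               strand = tx$strand, tx = tx$id, stringsAsFactors = FALSE)))
  GenomicRanges::GRanges(ex$chrom,
                         IRanges::IRanges(ex$start + 1L, ex$end),
                         strand = ex$strand, tx = ex$tx)
}

#' Dual-route assembly consensus by intron chain
#'
#' Retains a route-A transcript iff some route-B transcript on the same
#' chromosome and strand has an identical ordered intron chain (the
#' gffcompare "=" idiom for multi-exon transcripts: terminal exon ends may
#' differ). Single-exon transcripts never match. Output carries the route-A
#' models.
#'
#' @param route_a,route_b [annotation_set()]s on the same genome.
#' @return an [annotation_set()] with the retained route-A transcripts.
#' @export
consensus <- function(route_a, route_b) {
  keys_b <- vapply(route_b$transcripts, function(tx)
    if (nrow(tx$exons) < 2) NA_character_ else chain_key(tx), character(1))
  keys_b <- keys_b[!is.na(keys_b)]
  keep <- vapply(route_a$transcripts, function(tx)
    nrow(tx$exons) >= 2 && chain_key(tx) %in% keys_b, logical(1))
  annotation_set(route_a$genes, route_a$transcripts[keep])
}

#' lncRNA candidate filter cascade
#'
#' Applies, in order: (1) spliced length >= `min_len`; (2) exon count >= 2;
#' (3) no same-strand exonic overlap with the normal-tissue transcript set;
#' (4) no same-strand exonic overlap with known noncoding transcripts;
#' (5) noncoding probability strictly greater than `min_prob`. Removal
#' counts per filter are reported and sum to input minus output.
#'
#' @param cands list of candidates: each a transcript (see
#'   [annotation_set()]) with an extra `noncoding_probability` element in
#'   [0, 1].
#' @param normal_set [annotation_set()] of transcripts detected in normal
#'   tissue.
#' @param known_noncoding [annotation_set()] of previously annotated
#'   noncoding transcripts.
#' @param min_len minimum spliced length (nt), default 200 (a 199 nt
#'   candidate is removed, a 200 nt one survives).
#' @param min_prob strict probability cut, default 0.99 (exactly 0.99 is
#'   removed).
#' @return list: `kept` (candidate list), `counts` (named removals per
#'   filter).
#' @export
filter_cascade <- function(cands, normal_set, known_noncoding,
                           min_len = 200, min_prob = 0.99) {
  counts <- c(short = 0L, single_exon = 0L, normal_overlap = 0L,
              known_noncoding = 0L, low_probability = 0L)
  pass <- cands
  drop_by <- function(pass, bad, which) {
    counts[[which]] <<- sum(bad)
    pass[!bad]
  }
  pass <- drop_by(pass, vapply(pass, tx_length, numeric(1)) < min_len, "short")
  pass <- drop_by(pass, vapply(pass, function(tx) nrow(tx$exons), integer(1)) < 2,
                  "single_exon")
  same_strand_exonic <- function(pass, ref) {
    if (!length(pass) || !length(ref$transcripts))
      return(rep(FALSE, length(pass)))
    q <- exon_granges(pass)
    s <- exon_granges(ref$transcripts)
    hit <- GenomicRanges::findOverlaps(q, s, ignore.strand = FALSE)
    hit_tx <- unique(S4Vectors::mcols(q)$tx[S4Vectors::queryHits(hit)])
    vapply(pass, function(tx) tx$id %in% hit_tx, logical(1))
  }
  pass <- drop_by(pass, same_strand_exonic(pass, normal_set), "normal_overlap")
  pass <- drop_by(pass, same_strand_exonic(pass, known_noncoding), "known_noncoding")
  prob <- vapply(pass, function(tx) tx$noncoding_probability, numeric(1))
  pass <- drop_by(pass, !(prob > min_prob), "low_probability")
  if (!length(pass)) warning("filter cascade removed every candidate")
  list(kept = pass, counts = counts)
}

#' Strand-aware genomic-context classification
#'
#' Precedence: (1) exonic overlap with a same-strand coding gene's exons ->
#' `sense_overlapping`; (2) fully contained within one intron of a
#' same-strand coding transcript -> `sense_intronic`; (3) any span overlap
#' with a coding gene on the opposite strand -> `antisense`; (4) no overlap
#' with any coding gene, but the transcript's start lies within
#' `bidir_window` of an opposite-strand coding gene's transcription start in
#' head-to-head orientation -> `bidirectional`; (5) otherwise `intergenic`.
#' The nearest coding gene (either strand; ties by smaller gap then
#' lexicographic id; distance 0 when overlapping) is reported when within
#' `nearest_window`, otherwise left blank.
#'
#' @param tx one transcript (list with chrom, strand, exons), e.g. an
#'   element of `annotation_set$transcripts`.
#' @param ann an [annotation_set()] whose gene table contains
#'   protein-coding genes (`biotype == "protein_coding"`); coding genes with
#'   transcript models contribute exon/intron structure, genes without
#'   contribute their span.
#' @param bidir_window head-to-head promoter window (nt), default 1000.
#' @param nearest_window report the nearest gene only within this distance.
#' @return data.frame (one row): transcript_id, class, nearest_gene,
#'   nearest_distance.
#' @export
classify_context <- function(tx, ann, bidir_window = 1000,
                             nearest_window = 1e6) {
  coding <- ann$genes[ann$genes$biotype %in% "protein_coding", , drop = FALSE]
  if (!nrow(coding)) stop("annotation contains no protein-coding gene")
  sp <- tx_span(tx)
  on_chrom <- coding[coding$chrom == tx$chrom, , drop = FALSE]
  coding_tx <- Filter(function(t2) !is.na(t2$gene_id) &&
                        t2$gene_id %in% coding$id &&
                        t2$chrom == tx$chrom,
                      ann$transcripts)
  ivl_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  # coding exon intervals on this chromosome (transcript models, else span)
  genes_with_tx <- unique(vapply(coding_tx, function(t2) t2$gene_id, character(1)))
  ex_list <- lapply(coding_tx, function(t2)
    data.frame(start = t2$exons[, 1], end = t2$exons[, 2], strand = t2$strand))
  if (nrow(on_chrom)) {
    no_tx <- on_chrom[!on_chrom$id %in% genes_with_tx, , drop = FALSE]
    if (nrow(no_tx))
      ex_list <- c(ex_list, list(data.frame(start = no_tx$start, end = no_tx$end,
                                            strand = no_tx$strand)))
  }
  exons_c <- if (length(ex_list)) do.call(rbind, ex_list) else
    data.frame(start = numeric(0), end = numeric(0), strand = character(0))
  # (1) same-strand exonic overlap
  same_ex <- exons_c[exons_c$strand == tx$strand, , drop = FALSE]
  hit1 <- FALSE
  if (nrow(same_ex))
    for (j in seq_len(nrow(tx$exons)))
      if (any(ivl_overlap(tx$exons[j, 1], tx$exons[j, 2],
                          same_ex$start, same_ex$end))) { hit1 <- TRUE; break }
  # (2) fully inside one intron of a same-strand coding transcript
  hit2 <- FALSE
  for (t2 in coding_tx) {
    if (t2$strand != tx$strand) next
    intr <- tx_introns(t2)
    if (nrow(intr) &&
        any(intr[, 1] <= sp[1] & sp[2] <= intr[, 2])) { hit2 <- TRUE; break }
  }
  # (3) opposite-strand span overlap
  opp <- on_chrom[on_chrom$strand != tx$strand, , drop = FALSE]
  hit3 <- nrow(opp) > 0 && any(ivl_overlap(sp[1], sp[2], opp$start, opp$end))
  # any span overlap with a coding gene (gates rule 4)
  any_ov <- nrow(on_chrom) > 0 &&
    any(ivl_overlap(sp[1], sp[2], on_chrom$start, on_chrom$end))
  # (4) head-to-head promoter proximity
  hit4 <- FALSE
  if (!any_ov && nrow(opp)) {
    if (tx$strand == "+") {
      tss_g <- opp$end[opp$strand == "-"]
      hit4 <- any(tss_g <= sp[1] & sp[1] - tss_g <= bidir_window)
    } else {
      tss_g <- opp$start[opp$strand == "+"]
      hit4 <- any(tss_g >= sp[2] & tss_g - sp[2] <= bidir_window)
    }
  }
  class <- if (hit1) "sense_overlapping" else if (hit2) "sense_intronic"
    else if (hit3) "antisense" else if (hit4) "bidirectional" else "intergenic"
  # nearest coding gene on either strand
  nearest_gene <- NA_character_; nearest_distance <- NA_real_
  if (nrow(on_chrom)) {
    gap <- pmax(0, pmax(on_chrom$start - sp[2], sp[1] - on_chrom$end))
    ord <- order(gap, on_chrom$id)
    if (gap[ord[1]] <= nearest_window) {
      nearest_gene <- on_chrom$id[ord[1]]
      nearest_distance <- gap[ord[1]]
    }
  }
  data.frame(transcript_id = tx$id, class = class, nearest_gene = nearest_gene,
             nearest_distance = nearest_distance, stringsAsFactors = FALSE)
}

#' Classify every non-coding transcript in an annotation set
#'
#' @param ann an [annotation_set()].
#' @param ids transcript ids to classify (default: all transcripts not
#'   assigned to a protein-coding gene).
#' @inheritParams classify_context
#' @return data.frame, one row per transcript (see [classify_context()]).
#' @export
classify_contexts <- function(ann, ids = NULL, bidir_window = 1000,
                              nearest_window = 1e6) {
  coding_ids <- ann$genes$id[ann$genes$biotype %in% "protein_coding"]
  if (is.null(ids))
    ids <- names(Filter(function(tx)
      is.na(tx$gene_id) || !tx$gene_id %in% coding_ids, ann$transcripts))
  do.call(rbind, lapply(ann$transcripts[ids], classify_context, ann = ann,
                        bidir_window = bidir_window,
                        nearest_window = nearest_window))
}

#' Prioritize interaction targets per lncRNA
#'
#' Candidates are ordered by the number of relevance flags (cancer pathway,
#' immune pathway) descending, then by interaction score ascending (more
#' negative hybridization energy = stronger), and the top 3 are kept.
#'
#' @param candidates data.frame with columns `target`, `cancer_pathway`,
#'   `immune_pathway` (logical) and `score` (finite; e.g. kcal/mol).
#' @return data.frame of at most 3 rows, ordered as kept.
#' @export
prioritize_targets <- function(candidates) {
  if (!nrow(candidates)) {
    warning("no candidate targets")
    return(candidates)
  }
  stopifnot(all(is.finite(candidates$score)))
  flags <- as.integer(candidates$cancer_pathway) +
    as.integer(candidates$immune_pathway)
  ord <- order(-flags, candidates$score)
  head(candidates[ord, , drop = FALSE], 3)
}
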