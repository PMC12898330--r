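#' @importFrom methods as is
#' @importFrom stats cor dist as.dist hclust cutree prcomp mad median quantile
#'   sd var lm coef rnbinom rnorm runif p.adjust pt t.test wilcox.test
#'   var.test ks.test setNames ave
#' @importFrom utils read.delim write.table read.csv write.csv head modifyList
NULL

# ---------------------------------------------------------------------------
# Count matrix ---------------------------------------------------------------

#' Construct a validated count matrix
#'
#' @param counts genes x samples matrix of non-negative integers with unique
#'   row (gene) and column (sample) names.
#' @param condition per-sample labels, coercible to a two-level factor. The
#'   first level in sorted order is the reference (control) level.
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `condition` (factor named by sample).
#' @export
count_matrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene (row) and sample (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-integer count at gene '", rownames(counts)[bad[1, 1]],
         "', sample '", colnames(counts)[bad[1, 2]], "'")
  storage.mode(counts) <- "integer"
  if (length(condition) != ncol(counts))
    stop("condition must have one label per sample")
  condition <- factor(as.character(condition))
  if (nlevels(condition) != 2)
    stop("condition must have exactly two levels, got ", nlevels(condition))
  names(condition) <- colnames(counts)
  structure(list(counts = counts, condition = condition), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples; levels:",
      paste(levels(x$condition), table(x$condition), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# condition recoded 0 (reference = first sorted level) / 1
condition_binary <- function(cm) as.integer(cm$condition == levels(cm$condition)[2])

#' Read a count matrix
#'
#' TSV layout: header row of sample ids, first column of gene ids. MTX layout:
#' MatrixMarket file plus `<stem>_genes.txt` and `<stem>_samples.txt` sidecars
#' (one id per line). Condition labels come from a two-column metadata sidecar
#' (`sample_id`, `condition`), by default `<path>.meta.tsv`.
#'
#' @param path count file.
#' @param format `"tsv"` or `"mtx"`.
#' @param meta path to the sample metadata sidecar.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, format = c("tsv", "mtx"),
                        meta = paste0(path, ".meta.tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (anyDuplicated(tab[[1]]))
      stop("duplicate gene id(s): ",
           paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "))
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
  } else {
    stem <- sub("\\.mtx$", "", path)
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(paste0(stem, "_genes.txt"))
    colnames(m) <- readLines(paste0(stem, "_samples.txt"))
  }
  if (!file.exists(meta)) stop("sample metadata sidecar not found: ", meta)
  md <- read.delim(meta, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(md)))
    stop("metadata sidecar must have columns sample_id and condition")
  miss <- setdiff(colnames(m), md$sample_id)
  if (length(miss)) stop("no condition label for sample(s): ", paste(miss, collapse = ", "))
  cond <- md$condition[match(colnames(m), md$sample_id)]
  count_matrix(m, cond)
}

#' Write a count matrix (TSV plus metadata sidecar)
#' @param cm a [count_matrix()].
#' @param path output TSV; the condition sidecar goes to `<path>.meta.tsv`.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- data.frame(sample_id = colnames(cm$counts),
                   condition = as.character(cm$condition))
  write.table(md, paste0(path, ".meta.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Annotation -----------------------------------------------------------------

#' Construct a validated annotation set
#'
#' Internal coordinates are 0-based half-open everywhere in the package;
#' converters to GTF (1-based closed) and BED (0-based half-open) live only
#' in the readers/writers.
#'
#' @param genes data.frame with columns id, chrom, start, end, strand,
#'   biotype (0-based half-open spans).
#' @param transcripts list of transcripts; each is a list with elements
#'   `id`, `gene_id` (or NA), `chrom`, `strand`, and `exons`, a 2-column
#'   matrix of 0-based half-open (start, end) intervals.
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(genes, transcripts) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "start", "end", "strand", "biotype")
  if (!all(need %in% names(genes)))
    stop("genes must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(genes$id)) stop("duplicate gene id in annotation")
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  if (!all(genes$strand %in% c("+", "-"))) stop("unknown strand symbol in genes")
  names(transcripts) <- vapply(transcripts, `[[`, character(1), "id")
  if (anyDuplicated(names(transcripts))) stop("duplicate transcript id in annotation")
  for (tx in transcripts) {
    ex <- tx$exons
    if (!is.matrix(ex) || ncol(ex) != 2) stop("exons of ", tx$id, " must be a 2-column matrix")
    if (any(ex[, 1] >= ex[, 2])) stop("exon with start >= end in ", tx$id)
    if (is.unsorted(ex[, 1], strictly = TRUE) && nrow(ex) > 1)
      stop("exons of ", tx$id, " must be sorted")
    if (nrow(ex) > 1 && any(ex[-nrow(ex), 2] > ex[-1, 1]))
      stop("overlapping exons in ", tx$id)
    if (!tx$strand %in% c("+", "-")) stop("unknown strand symbol in ", tx$id)
  }
  structure(list(genes = genes, transcripts = transcripts), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$genes), "genes,", length(x$transcripts), "transcripts\n")
  invisible(x)
}

tx_span <- function(tx) c(tx$exons[1, 1], tx$exons[nrow(tx$exons), 2])
tx_length <- function(tx) sum(tx$exons[, 2] - tx$exons[, 1])

# ordered intron intervals (0-based half-open); empty matrix for single exon
tx_introns <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 2) return(matrix(numeric(0), ncol = 2))
  cbind(ex[-nrow(ex), 2], ex[-1, 1])
}

#' Read transcript annotation from GTF or BED12
#'
#' GTF coordinates (1-based closed) and BED coordinates (0-based half-open)
#' are normalized to the internal 0-based half-open convention. GTF parsing
#' goes through `rtracklayer`; `gene` rows populate the gene table and
#' `exon` rows the transcript models. BED12 files carry transcripts only.
#'
#' @param path annotation file.
#' @param dialect `"gtf"` or `"bed12"`.
#' @return an [annotation_set()].
#' @export
read_annotation <- function(path, dialect = c("gtf", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    std <- as.character(GenomicRanges::strand(gr))
    if (any(!std %in% c("+", "-"))) stop("unknown strand symbol in ", path)
    meta <- as.data.frame(S4Vectors::mcols(gr))
    typ <- as.character(meta$type)
    gi <- typ == "gene"
    bty <- if ("gene_biotype" %in% names(meta)) meta$gene_biotype else meta$gene_type
    genes <- data.frame(
      id = meta$gene_id[gi],
      chrom = as.character(GenomicRanges::seqnames(gr))[gi],
      start = GenomicRanges::start(gr)[gi] - 1L,
      end = GenomicRanges::end(gr)[gi],
      strand = std[gi],
      biotype = if (is.null(bty)) rep(NA_character_, sum(gi)) else as.character(bty)[gi],
      stringsAsFactors = FALSE
    )
    ei <- which(typ == "exon")
    txs <- list()
    if (length(ei)) {
      exdf <- data.frame(
        tx = as.character(meta$transcript_id)[ei],
        gene = if (is.null(meta$gene_id)) NA_character_ else as.character(meta$gene_id)[ei],
        chrom = as.character(GenomicRanges::seqnames(gr))[ei],
        strand = std[ei],
        start = GenomicRanges::start(gr)[ei] - 1L,
        end = GenomicRanges::end(gr)[ei],
        stringsAsFactors = FALSE
      )
      tspan <- which(typ == "transcript")
      span <- if (length(tspan))
        data.frame(tx = as.character(meta$transcript_id)[tspan],
                   start = GenomicRanges::start(gr)[tspan] - 1L,
                   end = GenomicRanges::end(gr)[tspan]) else NULL
      txs <- lapply(split(exdf, exdf$tx), function(d) {
        d <- d[order(d$start), ]
        if (!is.null(span)) {
          sp <- span[span$tx == d$tx[1], ]
          if (nrow(sp) && (min(d$start) < sp$start[1] || max(d$end) > sp$end[1]))
            stop("exon outside transcript span in ", d$tx[1])
        }
        list(id = d$tx[1], gene_id = d$gene[1], chrom = d$chrom[1],
             strand = d$strand[1], exons = cbind(d$start, d$end))
      })
    }
    annotation_set(genes, txs)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    std <- as.character(GenomicRanges::strand(gr))
    if (any(!std %in% c("+", "-"))) stop("unknown strand symbol in ", path)
    bl <- S4Vectors::mcols(gr)$blocks
    txs <- lapply(seq_along(gr), function(i) {
      off <- GenomicRanges::start(gr)[i] - 1L             # 0-based chromStart
      if (!is.null(bl)) {
        b <- bl[[i]]
        ex <- cbind(off + IRanges::start(b) - 1L, off + IRanges::end(b))
      } else {
        ex <- cbind(off, GenomicRanges::end(gr)[i])
      }
      list(id = S4Vectors::mcols(gr)$name[i], gene_id = NA_character_,
           chrom = as.character(GenomicRanges::seqnames(gr))[i],
           strand = std[i], exons = ex)
    })
    genes <- data.frame(id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), biotype = character(0))
    annotation_set(genes, txs)
  }
}

#' Write an annotation set
#'
#' @param ann an [annotation_set()].
#' @param path output file.
#' @param dialect `"gtf"` writes gene, transcript and exon rows (1-based
#'   closed); `"bed12"` writes one block-structured row per transcript.
#' @export
write_annotation <- function(ann, path, dialect = c("gtf", "bed12")) {
  dialect <- match.arg(dialect)
  if (dialect == "gtf") {
    lines <- character(0)
    for (i in seq_len(nrow(ann$genes))) {
      g <- ann$genes[i, ]
      lines <- c(lines, sprintf(
        "%s\tctximmune\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"%s\";",
        g$chrom, g$start + 1L, g$end, g$strand, g$id, g$biotype))
    }
    for (tx in ann$transcripts) {
      sp <- tx_span(tx)
      gid <- if (is.na(tx$gene_id)) tx$id else tx$gene_id
      lines <- c(lines, sprintf(
        "%s\tctximmune\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        tx$chrom, sp[1] + 1L, sp[2], tx$strand, gid, tx$id))
      for (j in seq_len(nrow(tx$exons))) {
        lines <- c(lines, sprintf(
          "%s\tctximmune\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          tx$chrom, tx$exons[j, 1] + 1L, tx$exons[j, 2], tx$strand, gid, tx$id))
      }
    }
    writeLines(lines, path)
  } else {
    lines <- vapply(ann$transcripts, function(tx) {
      sp <- tx_span(tx)
      sizes <- tx$exons[, 2] - tx$exons[, 1]
      starts <- tx$exons[, 1] - sp[1]
      sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
              tx$chrom, sp[1], sp[2], tx$id, tx$strand, sp[1], sp[2],
              nrow(tx$exons),
              paste0(paste(sizes, collapse = ","), ","),
              paste0(paste(starts, collapse = ","), ","))
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Site tables and event tables ----------------------------------------------

#' Construct a validated miRNA binding-site table
#'
#' @param df data.frame with columns `mirna_id`, `transcript_id`,
#'   `site_position` (integer) and `neg_log_kd` (finite real).
#' @return data.frame of class `site_kd_table`.
#' @export
site_kd_table <- function(df) {
  need <- c("mirna_id", "transcript_id", "site_position", "neg_log_kd")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$neg_log_kd))) stop("non-finite neg_log_kd value(s)")
  key <- paste(df$mirna_id, df$transcript_id, df$site_position)
  if (anyDuplicated(key))
    stop("duplicate (mirna, transcript, position) row: ", key[duplicated(key)][1])
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("site_kd_table", "data.frame")
  df
}

#' Read / write a site table (CSV)
#' @param path CSV with the four required columns.
#' @return a [site_kd_table()].
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  site_kd_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_site_table
#' @param sites a [site_kd_table()].
#' @export
write_site_table <- function(sites, path) {
  write.csv(as.data.frame(sites), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a validated cytometry event table
#'
#' @param intensities events x markers numeric matrix (unique marker names,
#'   no missing values).
#' @param sample_id per-event sample identifier.
#' @param group per-event group label (exactly two levels overall unless
#'   `single_group = TRUE`, used for FMO control tables).
#' @param embedding optional events x 2 matrix with a precomputed embedding.
#' @param single_group allow a single group level (FMO tables).
#' @return object of class `event_table`.
#' @export
event_table <- function(intensities, sample_id, group, embedding = NULL,
                        single_group = FALSE) {
  intensities <- as.matrix(intensities)
  if (is.null(colnames(intensities)) || anyDuplicated(colnames(intensities)))
    stop("markers must have unique names")
  if (any(!is.finite(intensities))) stop("missing or non-finite intensity value(s)")
  n <- nrow(intensities)
  if (length(sample_id) != n || length(group) != n)
    stop("sample_id and group must have one entry per event")
  group <- factor(as.character(group))
  if (!single_group && nlevels(group) != 2)
    stop("group must have exactly two levels, got ", nlevels(group))
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    if (nrow(embedding) != n || ncol(embedding) != 2)
      stop("embedding must be an events x 2 matrix")
  }
  structure(list(intensities = intensities, sample_id = as.character(sample_id),
                 group = group, embedding = embedding), class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("event_table:", nrow(x$intensities), "events x", ncol(x$intensities),
      "markers;", nlevels(x$group), "group level(s)\n")
  invisible(x)
}

#' Read / write cytometry events (CSV)
#'
#' The CSV needs `sample_id` and `group` columns; optional `umap_1`/`umap_2`
#' columns become the embedding; every other column is a marker.
#'
#' @param path CSV file.
#' @param single_group allow a single group level (FMO exports).
#' @return an [event_table()].
#' @export
read_events <- function(path, single_group = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("sample_id", "group"))
    if (!col %in% names(df)) stop("missing required column: ", col)
  emb <- NULL
  if (all(c("umap_1", "umap_2") %in% names(df)))
    emb <- as.matrix(df[, c("umap_1", "umap_2")])
  markers <- setdiff(names(df), c("sample_id", "group", "umap_1", "umap_2"))
  event_table(as.matrix(df[, markers, drop = FALSE]), df$sample_id, df$group,
              embedding = emb, single_group = single_group)
}

#' @rdname read_events
#' @param events an [event_table()].
#' @export
write_events <- function(events, path) {
  df <- data.frame(sample_id = events$sample_id, group = as.character(events$group),
                   events$intensities, check.names = FALSE)
  if (!is.null(events$embedding)) {
    df$umap_1 <- events$embedding[, 1]
    df$umap_2 <- events$embedding[, 2]
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
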