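# Generators with planted, recoverable ground truth. All are pure functions
# of their arguments (seed included); none touches the global RNG state.

#' Simulate a cohort count matrix with planted co-expression modules
#'
#' Counts are negative binomial. Per sample and module a latent factor
#' f ~ N(0, 1) drives the log2 mean of all member genes; the loading is
#' chosen per gene so that the expected pairwise within-module correlation of
#' log2 counts is `rho` (the negative binomial sampling noise, approximated
#' by the delta method at the gene's baseline mean, is folded into the
#' non-shared variance). The designated disease module gets an additional
#' `group_effect` log2 shift in case samples. Remaining genes are independent
#' background.
#'
#' @param n_genes total genes.
#' @param n_samples_per_group samples per group; length-2 vector
#'   (control, case) or a single integer used for both. Defaults mirror a
#'   14-sample two-group cohort (8 case, 6 control).
#' @param module_sizes sizes of the planted modules (first = disease module).
#' @param rho target expected within-module log-count correlation, in [0, 1).
#' @param group_effect log2 shift of the disease module in case samples.
#' @param nb_dispersion negative binomial dispersion (var = mu + disp * mu^2).
#' @param baseline_log_mean range (log2) of per-gene baseline means.
#' @param gene_noise_sd per-gene-per-sample log2 noise sd outside the shared
#'   factor.
#' @param libsize_sd sd of the per-sample lognormal depth factor (0 = equal
#'   depth).
#' @param seed RNG seed.
#' @return list with `counts` (a [count_matrix()], condition levels "HC" =
#'   control and "PC" = case) and `truth` (data.frame gene_id, module;
#'   module 0 = background; attribute `disease_module` = 1).
#' @export
simulate_counts <- function(n_genes = 500, n_samples_per_group = c(6, 8),
                            module_sizes = c(50, 50), rho = 0.8,
                            group_effect = 1, nb_dispersion = 0.05,
                            baseline_log_mean = c(5, 9), gene_noise_sd = 0.3,
                            libsize_sd = 0, seed = 1) {
  if (length(n_samples_per_group) == 1)
    n_samples_per_group <- rep(n_samples_per_group, 2)
  if (sum(module_sizes) > n_genes) stop("sum of module_sizes exceeds n_genes")
  if (rho < 0 || rho >= 1) stop("infeasible rho: must be in [0, 1)")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  n_ctl <- n_samples_per_group[1]; n_case <- n_samples_per_group[2]
  n <- n_ctl + n_case
  withr::local_seed(seed)
  cond <- c(rep("HC", n_ctl), rep("PC", n_case))   # controls sort first
  module <- rep(0L, n_genes)
  if (length(module_sizes))
    module[seq_len(sum(module_sizes))] <- rep(seq_along(module_sizes), module_sizes)
  b <- runif(n_genes, baseline_log_mean[1], baseline_log_mean[2])
  # delta-method variance of log2 count at the baseline mean
  v_nb <- (1 / 2^b + nb_dispersion) / log(2)^2
  v_noise <- gene_noise_sd^2 + v_nb
  a <- ifelse(module > 0, sqrt(rho / (1 - rho) * v_noise), 0)
  f <- matrix(rnorm(length(module_sizes) * n), nrow = max(1, length(module_sizes)))
  logmu <- matrix(b, n_genes, n) +
    matrix(rnorm(n_genes * n, sd = gene_noise_sd), n_genes, n)
  for (m in seq_along(module_sizes)) {
    idx <- which(module == m)
    logmu[idx, ] <- logmu[idx, ] + outer(a[idx], f[m, ])
  }
  if (length(module_sizes) >= 1 && group_effect != 0) {
    # disease module: latent factor shifted by group_effect in case samples,
    # so gene i gains a_i * group_effect on the log2 scale
    idx <- which(module == 1L)
    logmu[idx, cond == "PC"] <- logmu[idx, cond == "PC"] +
      outer(a[idx], rep(group_effect, sum(cond == "PC")))
  }
  s <- if (libsize_sd > 0) 2^rnorm(n, sd = libsize_sd) else rep(1, n)
  mu <- sweep(2^logmu, 2, s, `*`)
  counts <- matrix(rnbinom(n_genes * n, mu = mu, size = 1 / nb_dispersion),
                   n_genes, n)
  rownames(counts) <- sprintf("g%04d", seq_len(n_genes))
  colnames(counts) <- sprintf("s%02d", seq_len(n))
  truth <- data.frame(gene_id = rownames(counts), module = module,
                      stringsAsFactors = FALSE)
  attr(truth, "disease_module") <- if (length(module_sizes)) 1L else NA_integer_
  list(counts = count_matrix(counts, cond), truth = truth)
}

# default 11-marker MDSC panel; "Lin" is the pooled lymphoid dump channel
default_panel <- function() {
  c("Lin", "HLA-DR", "CD33", "CD11b", "CD14", "CD15",
    "CD47", "SIRPa", "Gal-9", "CD73", "PD-L1")
}

#' Default cytometry mixture: lymphoid, monocyte, background myeloid and a
#' case-exclusive PMN-MDSC-like cluster
#'
#' Marker means are on an arcsinh-like scale: negative populations sit at 0
#' (sd 0.4), positive at `pos` (default 3, sd 0.5). The MDSC-like cluster
#' (Lin-, HLA-DR-, CD33+, CD11b+, CD15+, checkpoint-high) has mixing weight
#' 0 in the control group.
#'
#' @param pos positive-population mean.
#' @param mdsc_weight case-group weight of the MDSC-like cluster.
#' @return list of cluster definitions consumed by [simulate_events()].
#' @export
default_cyto_clusters <- function(pos = 3, mdsc_weight = 0.10) {
  p <- default_panel()
  mk <- function(positive, w_ctl, w_case, name) {
    mu <- setNames(rep(0, length(p)), p)
    mu[positive] <- pos
    list(name = name, mean = mu, sd = setNames(rep(0.45, length(p)), p),
         weight = c(control = w_ctl, case = w_case))
  }
  list(
    mk(c("Lin", "HLA-DR"), 0.55, 0.50, "lymphoid"),
    mk(c("HLA-DR", "CD33", "CD11b", "CD14"), 0.30, 0.25, "monocyte"),
    mk(c("CD33", "CD11b"), 0.15, 0.25 - mdsc_weight, "myeloid_other"),
    mk(c("CD33", "CD11b", "CD15", "CD47", "SIRPa", "Gal-9", "CD73", "PD-L1"),
       0, mdsc_weight, "pmn_mdsc_like")
  )
}

#' Simulate cytometry events with FMO controls and a planted group-exclusive
#' cluster
#'
#' Events are drawn per sample from a per-group Gaussian mixture over the
#' marker panel. FMO control tables are produced per marker by redrawing the
#' mixture with that marker's cluster means reduced by `fmo_shift` and
#' floored at the panel's negative level, i.e. the marker's stain is absent.
#'
#' @param n_events_per_sample events per sample.
#' @param n_samples_per_group length-2 (control, case); defaults 15 control
#'   and 12 case samples.
#' @param clusters cluster definitions as from [default_cyto_clusters()]:
#'   each a list(name, mean, sd, weight = c(control=, case=)). Per-group
#'   weights must sum to 1; all sds > 0.
#' @param fmo_shift mean reduction applied to the FMO'd marker.
#' @param fmo_events events per FMO control table.
#' @param seed RNG seed.
#' @return list: `events` (an [event_table()], groups "HC"/"PC"),
#'   `fmo` (named list of single-group event tables, one per marker), and
#'   `truth` (data.frame event, sample_id, group, cluster).
#' @export
simulate_events <- function(n_events_per_sample = 500,
                            n_samples_per_group = c(15, 12),
                            clusters = default_cyto_clusters(),
                            fmo_shift = 3, fmo_events = 2000, seed = 1) {
  if (length(n_samples_per_group) == 1)
    n_samples_per_group <- rep(n_samples_per_group, 2)
  wc <- vapply(clusters, function(cl) cl$weight[["control"]], numeric(1))
  wx <- vapply(clusters, function(cl) cl$weight[["case"]], numeric(1))
  if (abs(sum(wc) - 1) > 1e-8 || abs(sum(wx) - 1) > 1e-8)
    stop("per-group mixing weights must sum to 1")
  for (cl in clusters) if (any(cl$sd <= 0))
    stop("cluster '", cl$name, "' has a non-positive marker sd")
  panel <- names(clusters[[1]]$mean)
  withr::local_seed(seed)
  draw <- function(n, weights, means_override = NULL) {
    ci <- sample.int(length(clusters), n, replace = TRUE, prob = weights)
    x <- matrix(0, n, length(panel), dimnames = list(NULL, panel))
    for (j in seq_along(clusters)) {
      idx <- which(ci == j)
      if (!length(idx)) next
      mu <- if (is.null(means_override)) clusters[[j]]$mean else means_override[[j]]
      x[idx, ] <- rep(mu, each = length(idx)) +
        matrix(rnorm(length(idx) * length(panel)), length(idx)) *
        rep(clusters[[j]]$sd, each = length(idx))
    }
    list(x = x, cluster = ci)
  }
  groups <- c(rep("HC", n_samples_per_group[1]),
              rep("PC", n_samples_per_group[2]))
  samples <- sprintf("%s_%02d", groups,
                     unlist(lapply(n_samples_per_group, seq_len)))
  xs <- vector("list", length(samples)); cls <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    d <- draw(n_events_per_sample, if (groups[i] == "HC") wc else wx)
    xs[[i]] <- d$x; cls[[i]] <- d$cluster
  }
  x <- do.call(rbind, xs)
  sample_id <- rep(samples, each = n_events_per_sample)
  group <- rep(groups, each = n_events_per_sample)
  truth <- data.frame(event = seq_len(nrow(x)), sample_id = sample_id,
                      group = group,
                      cluster = vapply(clusters, `[[`, character(1), "name")[unlist(cls)],
                      stringsAsFactors = FALSE)
  # FMO controls: marker m redrawn with its stain absent
  neg_level <- apply(vapply(clusters, `[[`, numeric(length(panel)), "mean"), 1, min)
  fmo <- lapply(seq_along(panel), function(m) {
    means_m <- lapply(clusters, function(cl) {
      mu <- cl$mean
      mu[m] <- max(mu[m] - fmo_shift, neg_level[m])
      mu
    })
    d <- draw(fmo_events, (wc + wx) / 2, means_override = means_m)
    event_table(d$x, rep("FMO", fmo_events), rep("fmo", fmo_events),
                single_group = TRUE)
  })
  names(fmo) <- panel
  list(events = event_table(x, sample_id, group), fmo = fmo, truth = truth)
}

#' Simulate a toy annotation with one planted transcript per genomic-context
#' class
#'
#' For each class in antisense, sense_overlapping, sense_intronic,
#' bidirectional and intergenic, `n_per_class` transcripts are constructed on
#' their own chromosomes to satisfy exactly that class definition under the
#' classifier's precedence rules (exonic same-strand overlap >
#' intron containment > opposite-strand span overlap > head-to-head promoter
#' proximity > intergenic). All planted transcripts have two exons and
#' spliced length >= 200 nt so they survive the discovery filters.
#'
#' @param seed RNG seed (jitters positions and exon sizes).
#' @param n_per_class transcripts planted per class.
#' @param bidir_window head-to-head window used for the bidirectional
#'   construction (keep equal to the classifier's).
#' @return list: `annotation` (an [annotation_set()] containing the coding
#'   genes and the planted transcripts) and `truth` (data.frame
#'   transcript_id, class).
#' @export
simulate_annotation <- function(seed = 1, n_per_class = 3, bidir_window = 1000) {
  withr::local_seed(seed)
  classes <- c("antisense", "sense_overlapping", "sense_intronic",
               "bidirectional", "intergenic")
  genes <- list(); txs <- list(); truth <- list()
  gnum <- 0; tnum <- 0
  two_exons <- function(start, total_span) {
    e1 <- 100 + sample.int(100, 1)          # first exon length
    e2 <- 120 + sample.int(100, 1)          # second exon length
    gap <- total_span - e1 - e2
    cbind(c(start, start + e1 + gap), c(start + e1, start + e1 + gap + e2))
  }
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      gnum <- gnum + 1; tnum <- tnum + 1
      chrom <- sprintf("chr_%s_%d", cl, i)
      base <- 10000 + sample.int(5000, 1)
      tid <- sprintf("TX%04d", tnum)
      if (cl == "antisense") {
        # coding gene on -, transcript on + overlapping the gene span
        gid <- sprintf("PCG%03d", gnum)
        genes[[gid]] <- data.frame(id = gid, chrom = chrom, start = base,
                                   end = base + 4000, strand = "-",
                                   biotype = "protein_coding")
        ex <- two_exons(base + 500 + sample.int(1000, 1), 1500)
        txs[[tid]] <- list(id = tid, gene_id = NA_character_, chrom = chrom,
                           strand = "+", exons = ex)
      } else if (cl == "sense_overlapping") {
        gid <- sprintf("PCG%03d", gnum)
        genes[[gid]] <- data.frame(id = gid, chrom = chrom, start = base,
                                   end = base + 4000, strand = "+",
                                   biotype = "protein_coding")
        # coding gene exons: [base, base+1500) and [base+3000, base+4000)
        gtx <- sprintf("%s_t1", gid)
        txs[[gtx]] <- list(id = gtx, gene_id = gid, chrom = chrom, strand = "+",
                           exons = cbind(c(base, base + 3000),
                                         c(base + 1500, base + 4000)))
        ex <- two_exons(base + 200 + sample.int(400, 1), 900)  # inside exon 1
        txs[[tid]] <- list(id = tid, gene_id = NA_character_, chrom = chrom,
                           strand = "+", exons = ex)
      } else if (cl == "sense_intronic") {
        gid <- sprintf("PCG%03d", gnum)
        genes[[gid]] <- data.frame(id = gid, chrom = chrom, start = base,
                                   end = base + 6000, strand = "+",
                                   biotype = "protein_coding")
        gtx <- sprintf("%s_t1", gid)
        # intron spans [base+1000, base+5000)
        txs[[gtx]] <- list(id = gtx, gene_id = gid, chrom = chrom, strand = "+",
                           exons = cbind(c(base, base + 5000),
                                         c(base + 1000, base + 6000)))
        ex <- two_exons(base + 1200 + sample.int(1000, 1), 1200)
        txs[[tid]] <- list(id = tid, gene_id = NA_character_, chrom = chrom,
                           strand = "+", exons = ex)
      } else if (cl == "bidirectional") {
        # gene on -, TSS at its end coordinate; transcript on + starting
        # within bidir_window downstream of that TSS, no overlap
        gid <- sprintf("PCG%03d", gnum)
        genes[[gid]] <- data.frame(id = gid, chrom = chrom, start = base - 3000,
                                   end = base, strand = "-",
                                   biotype = "protein_coding")
        gap <- sample.int(bidir_window - 100, 1)
        ex <- two_exons(base + gap, 1200)
        txs[[tid]] <- list(id = tid, gene_id = NA_character_, chrom = chrom,
                           strand = "+", exons = ex)
      } else { # intergenic: own chromosome, no coding gene at all
        ex <- two_exons(base, 1400)
        txs[[tid]] <- list(id = tid, gene_id = NA_character_, chrom = chrom,
                           strand = sample(c("+", "-"), 1), exons = ex)
      }
      truth[[tid]] <- data.frame(transcript_id = tid, class = cl,
                                 stringsAsFactors = FALSE)
    }
  }
  ann <- annotation_set(do.call(rbind, genes), txs)
  list(annotation = ann, truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Simulate a miRNA binding-site table with planted true pairs
#'
#' Null site scores (-logKd) are Gaussian(`null_mean`, `null_sd`); sites of
#' the designated true pairs are shifted upward by `effect_shift`. A clean
#' reference sample from the null distribution is returned alongside the
#' table for use as the empirical-p null.
#'
#' @param n_pairs number of (miRNA, transcript) pairs.
#' @param n_true_pairs how many pairs carry the planted shift.
#' @param sites_per_pair integer range (length 2) of sites per pair.
#' @param null_mean,null_sd null -logKd distribution parameters.
#' @param effect_shift upward shift (same units) of true-pair sites; >= 0.
#' @param n_null size of the returned clean null reference sample. Keep it
#'   large relative to the site count: add-one empirical p-values are
#'   floored at `1 / (n_null + 1)`, and a floor above `alpha * rank / m`
#'   makes even maximally significant sites unable to clear BH.
#' @param seed RNG seed.
#' @return list: `sites` (a [site_kd_table()]), `truth` (data.frame mirna_id,
#'   transcript_id, true), `null_sample` (numeric vector).
#' @export
simulate_sites <- function(n_pairs = 50, n_true_pairs = 5,
                           sites_per_pair = c(3, 6), null_mean = 2,
                           null_sd = 0.5, effect_shift = 1.5, n_null = 10000,
                           seed = 1) {
  if (effect_shift < 0) stop("effect_shift must be >= 0")
  if (n_true_pairs > n_pairs) stop("n_true_pairs exceeds n_pairs")
  if (any(sites_per_pair < 1)) stop("at least one site per pair required")
  withr::local_seed(seed)
  mirna <- sprintf("miR-%03d", seq_len(n_pairs))
  lnc <- sprintf("LNC%03d", seq_len(n_pairs))
  is_true <- seq_len(n_pairs) <= n_true_pairs
  k_range <- seq(sites_per_pair[1], sites_per_pair[2])
  rows <- lapply(seq_len(n_pairs), function(i) {
    k <- k_range[sample.int(length(k_range), 1)]
    val <- rnorm(k, null_mean, null_sd) + if (is_true[i]) effect_shift else 0
    data.frame(mirna_id = mirna[i], transcript_id = lnc[i],
               site_position = sort(sample.int(2000, k)),
               neg_log_kd = val, stringsAsFactors = FALSE)
  })
  list(sites = site_kd_table(do.call(rbind, rows)),
       truth = data.frame(mirna_id = mirna, transcript_id = lnc, true = is_true,
                          stringsAsFactors = FALSE),
       null_sample = rnorm(n_null, null_mean, null_sd))
}
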