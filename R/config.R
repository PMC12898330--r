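#' Run configuration
#'
#' Collects every tunable used across the workflow with validated defaults.
#' Unknown keys are rejected so that a typo in a config cannot silently fall
#' back to a default.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details Defaults:
#' \describe{
#'   \item{seed}{integer seed handed to every randomized operation; no
#'     function in the package touches the global random state without it.}
#'   \item{pseudocount}{added before the log2 transform (must be > 0); 1.}
#'   \item{min_count, min_samples}{low-count filter: keep genes with
#'     `count >= min_count` in at least `min_samples` samples; `min_samples =
#'     NA` means "smallest group size".}
#'   \item{z_height, z_pca}{robust z cutoffs for the two sample-outlier
#'     rules (clustering merge height, default 5; PC1-2 centroid distance,
#'     default 3).}
#'   \item{powers}{candidate soft-threshold powers, 1:20.}
#'   \item{rsq_cut}{scale-free fit R-squared needed to accept a power; 0.8.}
#'   \item{cut_height}{static tree-cut height on the 1 - TOM dendrogram;
#'     `NA` means the 0.75 quantile of merge heights (0.25 from the top).}
#'   \item{min_module_size}{clusters smaller than this become unassigned; 30.}
#'   \item{merge_cut}{modules with eigengene correlation > 1 - merge_cut are
#'     merged; 0.25.}
#'   \item{jaccard_threshold}{minimum per-iteration Jaccard for a module to
#'     be called stable under the leave-one-out jackknife; 0.5.}
#'   \item{overlap_threshold}{signature retention needs a measured-gene
#'     overlap fraction strictly greater than this; 0.9.}
#'   \item{min_len, min_prob}{lncRNA filters: spliced length >= 200 nt and
#'     noncoding probability strictly > 0.99.}
#'   \item{bidir_window}{head-to-head promoter window for the bidirectional
#'     class, 1000 nt.}
#'   \item{nearest_window}{nearest coding gene reported only within this
#'     distance, 1e6 nt.}
#'   \item{n_bins}{covariate quantile bins for weighted FDR; 5.}
#'   \item{fdr_alpha}{FDR level used for site retention and pair calls; 0.05.}
#'   \item{fmo_percentile}{FMO positivity threshold percentile; 99.}
#'   \item{knn_k, knn_tau}{neighborhood size (60) and enrichment cut (0.95)
#'     for the per-event KNN group-enrichment map.}
#' }
#'
#' @return a named list of class `ctx_config`.
#' @export
ctx_config <- function(...) {
  defaults <- list(
    seed = 1L,
    pseudocount = 1,
    min_count = 10L,
    min_samples = NA_integer_,
    z_height = 5,
    z_pca = 3,
    powers = 1:20,
    rsq_cut = 0.8,
    cut_height = NA_real_,
    min_module_size = 30L,
    merge_cut = 0.25,
    jaccard_threshold = 0.5,
    overlap_threshold = 0.9,
    min_len = 200L,
    min_prob = 0.99,
    bidir_window = 1000L,
    nearest_window = 1e6,
    n_bins = 5L,
    fdr_alpha = 0.05,
    fmo_percentile = 99,
    knn_k = 60L,
    knn_tau = 0.95
  )
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(!nzchar(names(over)))))
    stop("all configuration overrides must be named")
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  validate_config(cfg)
  structure(cfg, class = "ctx_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid configuration: ", msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && cfg$seed == round(cfg$seed),
      "seed must be a single integer")
  chk(cfg$pseudocount > 0, "pseudocount must be > 0")
  chk(cfg$min_count >= 0, "min_count must be >= 0")
  chk(is.na(cfg$min_samples) || cfg$min_samples >= 0, "min_samples must be >= 0 or NA")
  chk(cfg$z_height > 0 && cfg$z_pca > 0, "outlier z cutoffs must be > 0")
  chk(length(cfg$powers) >= 2 && all(cfg$powers > 0), "powers must be >= 2 positive values")
  chk(cfg$rsq_cut > 0 && cfg$rsq_cut <= 1, "rsq_cut must be in (0, 1]")
  chk(is.na(cfg$cut_height) || (cfg$cut_height >= 0), "cut_height must be >= 0 or NA")
  chk(cfg$min_module_size >= 1, "min_module_size must be >= 1")
  chk(cfg$merge_cut >= 0 && cfg$merge_cut < 1, "merge_cut must be in [0, 1)")
  chk(cfg$jaccard_threshold >= 0 && cfg$jaccard_threshold <= 1,
      "jaccard_threshold must be in [0, 1]")
  chk(cfg$overlap_threshold >= 0 && cfg$overlap_threshold <= 1,
      "overlap_threshold must be in [0, 1]")
  chk(cfg$min_len >= 0, "min_len must be >= 0")
  chk(cfg$min_prob >= 0 && cfg$min_prob <= 1, "min_prob must be in [0, 1]")
  chk(cfg$bidir_window >= 0, "bidir_window must be >= 0")
  chk(cfg$nearest_window > 0, "nearest_window must be > 0")
  chk(cfg$n_bins >= 1, "n_bins must be >= 1")
  chk(cfg$fdr_alpha > 0 && cfg$fdr_alpha < 1, "fdr_alpha must be in (0, 1)")
  chk(cfg$fmo_percentile > 0 && cfg$fmo_percentile < 100,
      "fmo_percentile must be in (0, 100)")
  chk(cfg$knn_k >= 1, "knn_k must be >= 1")
  chk(cfg$knn_tau > 0.5 && cfg$knn_tau <= 1, "knn_tau must be in (0.5, 1]")
  invisible(cfg)
}
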