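mk_events <- function(x, sample_id, group) {
  event_table(x, sample_id, group)
}

test_that("FMO thresholds are the stated percentile of the control
           distribution", {
  zeros <- event_table(matrix(0, 200, 1, dimnames = list(NULL, "m")),
                       rep("f", 200), rep("fmo", 200), single_group = TRUE)
  expect_equal(unname(fmo_thresholds(list(m = zeros))), 0)
  withr::with_seed(100, {
    big <- event_table(matrix(rnorm(1e5), ncol = 1,
                              dimnames = list(NULL, "m")),
                       rep("f", 1e5), rep("fmo", 1e5), single_group = TRUE)
  })
  thr99 <- fmo_thresholds(list(m = big), percentile = 99)
  expect_lt(abs(thr99 - qnorm(0.99)), 0.05)
  # monotone in the percentile
  expect_gte(fmo_thresholds(list(m = big), 99.5), thr99)
  small <- event_table(matrix(0, 10, 1, dimnames = list(NULL, "m")),
                       rep("f", 10), rep("fmo", 10), single_group = TRUE)
  expect_error(fmo_thresholds(list(m = small)), "100 events")
})

test_that("gate frequencies equal manual enumeration on a hand-built table", {
  markers <- c("Lin", "HLA-DR", "CD33", "CD11b", "CD14", "CD15")
  # 20 events, 1 sample; threshold 1 for every marker
  x <- matrix(0, 20, 6, dimnames = list(NULL, markers))
  x[1:8, c("CD33", "CD11b")] <- 2          # 8 MDSC candidates
  x[1:3, "CD15"] <- 2                      # 3 PMN
  x[4:5, "CD14"] <- 2                      # 2 M
  x[9:10, "Lin"] <- 2                      # lymphoid, not MDSC
  ev <- mk_events(x, rep("s1", 20), rep(c("HC", "PC"), 10))
  thr <- setNames(rep(1, 6), markers)
  gf <- suppressWarnings(gate_frequencies(ev, mdsc_gate_tree(), thr))
  expect_equal(gf$mdsc_total, 100 * 8 / 20)
  expect_equal(gf$pmn_mdsc, 100 * 3 / 8)
  expect_equal(gf$m_mdsc, 100 * 2 / 8)
  expect_equal(gf$e_mdsc, 100 * 3 / 8)
  # the CD14/CD15 split partitions the parent
  expect_equal(gf$pmn_mdsc + gf$m_mdsc + gf$e_mdsc, 100)
  # all events below every threshold: all subset percentages 0
  ev0 <- mk_events(matrix(0, 10, 6, dimnames = list(NULL, markers)),
                   rep("s1", 10), rep(c("HC", "PC"), 5))
  gf0 <- suppressWarnings(gate_frequencies(ev0, mdsc_gate_tree(), thr))
  expect_equal(gf0$mdsc_total, 0)
  expect_true(is.na(gf0$pmn_mdsc))         # empty parent gate
})

test_that("gate frequencies match brute-force predicate evaluation on
           simulated data", {
  sim <- simulate_events(n_events_per_sample = 150,
                         n_samples_per_group = c(2, 2), fmo_events = 500,
                         seed = 101)
  thr <- fmo_thresholds(sim$fmo)
  gf <- gate_frequencies(sim$events, mdsc_gate_tree(), thr)
  x <- sim$events$intensities
  for (s in unique(sim$events$sample_id)) {
    si <- sim$events$sample_id == s
    tot <- x[si, "CD33"] > thr["CD33"] & x[si, "CD11b"] > thr["CD11b"] &
      x[si, "Lin"] <= thr["Lin"] & x[si, "HLA-DR"] <= thr["HLA-DR"]
    pmn <- tot & x[si, "CD15"] > thr["CD15"] & x[si, "CD14"] <= thr["CD14"]
    expect_equal(gf$mdsc_total[gf$sample_id == s], 100 * mean(tot))
    expect_equal(gf$pmn_mdsc[gf$sample_id == s], 100 * sum(pmn) / sum(tot))
  }
})

test_that("marker positivity is computed within each subset", {
  sim <- simulate_events(n_events_per_sample = 300,
                         n_samples_per_group = c(2, 2), seed = 102)
  thr <- fmo_thresholds(sim$fmo)
  mp <- marker_positivity(sim$events, mdsc_gate_tree(), thr)
  expect_true(all(c("CD47", "PD-L1") %in% names(mp)))
  pc <- mp[mp$subset == "mdsc_total" & mp$group == "PC", "CD47"]
  hc <- mp[mp$subset == "mdsc_total" & mp$group == "HC", "CD47"]
  expect_gt(mean(pc, na.rm = TRUE), mean(hc, na.rm = TRUE))
})

test_that("group comparison reproduces the exact Mann-Whitney p for
           separated triplets", {
  res <- compare_groups(c(1, 2, 3, 10, 11, 12),
                        rep(c("HC", "PC"), each = 3), test = "mann_whitney")
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  expect_equal(res$stars, "")
  # identical groups under full ties: p = 1
  res2 <- compare_groups(rep(5, 8), rep(c("HC", "PC"), each = 4),
                         test = "mann_whitney")
  expect_equal(res2$p, 1)
  # auto switches to Welch under gross variance heterogeneity
  withr::with_seed(103, {
    v <- c(rnorm(10, sd = 0.01), rnorm(10, sd = 5))
  })
  res3 <- compare_groups(v, rep(c("HC", "PC"), each = 10), test = "auto")
  expect_equal(res3$test, "welch")
})

test_that("group comparison detects a 2-SD shift at the study group sizes", {
  withr::with_seed(104, {
    hits <- replicate(100, {
      v <- c(rnorm(15), rnorm(12) + 2)
      compare_groups(v, rep(c("HC", "PC"), c(15, 12)))$p < 0.05
    })
  })
  expect_gte(mean(hits), 0.8)
})

test_that("KNN enrichment flags a planted case-exclusive cluster", {
  sim <- simulate_events(n_events_per_sample = 250,
                         n_samples_per_group = c(6, 6), fmo_events = 0,
                         seed = 105)
  km <- knn_enrichment(sim$events, k = 60, tau = 0.95, seed = 1)
  planted <- which(sim$truth$cluster == "pmn_mdsc_like")
  idx <- match(planted, km$events$event)
  idx <- idx[!is.na(idx)]
  expect_gte(mean(km$events$flag[idx] == "case_enriched"), 0.9)
  expect_true(all(km$events$f >= 0 & km$events$f <= 1))
})

test_that("KNN flags are rare under label permutation", {
  sim <- simulate_events(n_events_per_sample = 120,
                         n_samples_per_group = c(5, 5), fmo_events = 0,
                         seed = 106)
  ev <- sim$events
  withr::with_seed(107, {
    rates <- replicate(25, {
      perm <- sample(length(ev$group))
      evp <- event_table(ev$intensities, ev$sample_id, ev$group[perm])
      km <- knn_enrichment(evp, k = 60, tau = 0.95, seed = 1)
      mean(km$events$flag != "shared")
    })
  })
  expect_lte(mean(rates), 0.01)
})

test_that("KNN flags are invariant under Euclidean isometry and flip
           polarity under group swap", {
  sim <- simulate_events(n_events_per_sample = 150,
                         n_samples_per_group = c(3, 3), fmo_events = 0,
                         seed = 108)
  ev0 <- sim$events
  emb <- ev0$intensities[, c("CD15", "CD14")]
  ev <- event_table(ev0$intensities, ev0$sample_id, ev0$group,
                    embedding = emb)
  km <- knn_enrichment(ev, k = 30, space = "embedding", seed = 2)
  # rotate + translate the 2-D embedding: distances are unchanged
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  evr <- event_table(ev0$intensities, ev0$sample_id, ev0$group,
                     embedding = sweep(emb %*% rot, 2, c(5, -3), `+`))
  kmr <- knn_enrichment(evr, k = 30, space = "embedding", seed = 2)
  expect_equal(km$events$flag, kmr$events$flag)
  # swapping which level is "case" flips polarity exactly
  km_hc <- knn_enrichment(ev, k = 30, space = "embedding", case = "HC",
                          seed = 2)
  swap <- c(case_enriched = "control_enriched",
            control_enriched = "case_enriched", shared = "shared")
  expect_equal(unname(swap[km$events$flag]), km_hc$events$flag)
})

test_that("KNN preconditions are enforced", {
  sim <- simulate_events(n_events_per_sample = 50,
                         n_samples_per_group = c(2, 2), fmo_events = 0,
                         seed = 110)
  expect_error(knn_enrichment(sim$events, k = 1000), "k must be")
  expect_error(knn_enrichment(sim$events, space = "embedding"),
               "no embedding")
  one <- event_table(sim$events$intensities,
                     sim$events$sample_id,
                     rep("PC", length(sim$events$group)), single_group = TRUE)
  expect_error(knn_enrichment(one), "both group levels")
})
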