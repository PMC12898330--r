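test_that("signed adjacency matches closed forms at cor -1, 0, +1", {
  # two perfectly correlated, two anti-correlated, two orthogonal profiles
  base <- c(1, 2, 3, 4, 5, 6, 7, 8)
  orth <- c(1, -1, -1, 1, 1, -1, -1, 1)   # exactly uncorrelated with base
  expr <- rbind(a = base, b = 2 * base + 3, c = -base, d = orth)
  colnames(expr) <- sprintf("s%d", 1:8)
  net <- build_network(expr, beta = 6)
  expect_equal(net$adjacency["a", "b"], 1, tolerance = 1e-12)
  expect_equal(net$adjacency["a", "c"], 0, tolerance = 1e-12)
  expect_equal(net$adjacency["a", "d"], 0.5^6, tolerance = 1e-12)
})

test_that("TOM equals the brute-force triple loop on random matrices", {
  withr::with_seed(40, {
    for (i in 1:5) {
      n <- sample(8:20, 1)
      expr <- matrix(rnorm(n * 10), n, 10,
                     dimnames = list(sprintf("g%02d", 1:n), sprintf("s%d", 1:10)))
      net <- build_network(expr, beta = sample(c(2, 6, 12), 1))
      expect_equal(max(abs(net$tom - tom_brute(net$adjacency))), 0,
                   tolerance = 1e-10)
      expect_true(all(net$tom >= -1e-12 & net$tom <= 1 + 1e-12))
      expect_equal(max(abs(net$tom - t(net$tom))), 0, tolerance = 1e-12)
    }
  })
})

test_that("TOM of two perfect 3-cliques is 1 within and 0 across blocks", {
  base1 <- c(3, 1, 4, 1, 5, 9, 2, 6)
  base2 <- c(2, 7, 1, 8, 2, 8, 1, 8)
  expr <- rbind(a1 = base1, a2 = 2 * base1, a3 = base1 + 5,
                b1 = base2, b2 = 3 * base2, b3 = base2 - 1)
  colnames(expr) <- sprintf("s%d", 1:8)
  # force the cross-block adjacency to exact 0/1 pattern by brute assertion
  net <- build_network(expr, beta = 40)   # high power crushes cross terms
  within <- net$tom[1:3, 1:3]
  across <- net$tom[1:3, 4:6]
  expect_equal(unname(within), matrix(1, 3, 3), tolerance = 1e-6)
  expect_equal(unname(across), matrix(0, 3, 3), tolerance = 1e-6)
})

test_that("zero-variance genes are rejected by name", {
  expr <- rbind(g1 = c(1, 1, 1, 1), g2 = c(1, 2, 3, 4))
  colnames(expr) <- sprintf("s%d", 1:4)
  expect_error(build_network(expr, 6), "g1")
})

test_that("power selection returns a power with adequate scale-free fit", {
  sim <- simulate_counts(n_genes = 600, n_samples_per_group = c(15, 15),
                         module_sizes = c(50, 30), rho = 0.9,
                         group_effect = 1, seed = 3)
  x <- log_normalize(sim$counts)
  pp <- pick_power(x, 1:20)
  sel <- pp$table[pp$table$power == pp$power, ]
  expect_gte(sel$rsq, 0.8)
  # smallest qualifying power is returned
  qual <- pp$table$power[!is.na(pp$table$rsq) & pp$table$rsq >= 0.8]
  expect_equal(pp$power, min(qual))
  # deterministic
  expect_equal(pick_power(x, 1:20)$power, pp$power)
  expect_error(pick_power(x, 6), "at least 2")
})

test_that("planted modules are recovered with high Jaccard", {
  sim <- simulate_counts(n_genes = 500, n_samples_per_group = c(30, 30),
                         module_sizes = c(50, 50), rho = 0.9,
                         group_effect = 1, seed = 4)
  x <- log_normalize(sim$counts)
  net <- build_network(x, 12)
  mods <- detect_modules(net, x, min_size = 30)
  expect_equal(ncol(mods$eigengenes), 2)
  for (pm in 1:2) {
    planted <- sim$truth$gene_id[sim$truth$module == pm]
    js <- vapply(1:2, function(m) jaccard(module_genes(mods, m), planted),
                 numeric(1))
    expect_gte(max(js), 0.9)
  }
})

test_that("module labels are invariant under gene permutation", {
  sim <- simulate_counts(n_genes = 200, n_samples_per_group = c(7, 7),
                         module_sizes = c(40), rho = 0.9, group_effect = 1,
                         seed = 6)
  x <- log_normalize(sim$counts)
  mods <- detect_modules(build_network(x, 6), x, min_size = 30)
  withr::with_seed(1, perm <- sample(nrow(x)))
  xp <- x[perm, ]
  modsp <- detect_modules(build_network(xp, 6), xp, min_size = 30)
  expect_equal(ncol(modsp$eigengenes), ncol(mods$eigengenes))
  for (m in seq_len(ncol(mods$eigengenes))) {
    js <- vapply(seq_len(ncol(modsp$eigengenes)), function(m2)
      jaccard(module_genes(mods, m), module_genes(modsp, m2)), numeric(1))
    expect_equal(max(js), 1)
  }
})

test_that("merge_cut = 0 disables merging and rank-1 modules give the
           standardized common profile as eigengene", {
  base <- c(0.5, 2, 1, 3, 2.5, 4, 1.5, 5)
  expr <- rbind(a = base, b = base, c = base, d = base,
                e = rev(base) * 2, f = rev(base) * 2, g = rev(base) * 2,
                h = rev(base) * 2)
  colnames(expr) <- sprintf("s%d", 1:8)
  net <- build_network(expr, 6)
  mods <- detect_modules(net, expr, min_size = 2, merge_cut = 0,
                         kme_alpha = 0)
  expect_gte(ncol(mods$eigengenes), 2)
  m_a <- mods$labels[["a"]]
  e <- mods$eigengenes[, m_a]
  expect_equal(abs(cor(e, base)), 1, tolerance = 1e-10)
  expect_equal(unname(e), unname(as.vector(scale(base))), tolerance = 1e-10)
})

test_that("module-trait correlation follows the Student transform", {
  withr::with_seed(50, {
    cond <- rep(c(0, 1), each = 6)
    sim <- simulate_counts(n_genes = 150, n_samples_per_group = c(6, 6),
                           module_sizes = c(40), rho = 0.9, group_effect = 2,
                           seed = 50)
    x <- log_normalize(sim$counts)
    mods <- detect_modules(build_network(x, 6), x, min_size = 30)
    mt <- module_trait(mods, cond)
    r <- mt$r[1]; n <- 12
    expect_equal(mt$t[1], r * sqrt((n - 2) / (1 - r^2)), tolerance = 1e-12)
    expect_equal(mt$p[1], 2 * pt(-abs(mt$t[1]), n - 2), tolerance = 1e-12)
  })
  # an eigengene proportional to the condition vector gives r = 1
  cond <- rep(c(0, 1), each = 4)
  modset <- structure(list(
    labels = setNames(rep(1L, 3), c("a", "b", "c")),
    eigengenes = matrix(as.vector(scale(cond)), 8, 1,
                        dimnames = list(sprintf("s%d", 1:8), "ME1")),
    params = list()), class = "module_set")
  mt <- module_trait(modset, cond)
  expect_equal(mt$r, 1, tolerance = 1e-10)
  expect_lt(mt$p, 1e-6)
})

test_that("the cohort-scale correlations reach significance as reported", {
  # r = 0.66 at n = 11 is significant at 0.05; r = -0.81 at 0.01
  p1 <- 2 * pt(-abs(0.66 * sqrt(9 / (1 - 0.66^2))), 9)
  p2 <- 2 * pt(-abs(-0.81 * sqrt(9 / (1 - 0.81^2))), 9)
  expect_lt(p1, 0.05)
  expect_lt(p2, 0.01)
})

test_that("edge export respects the TOM threshold", {
  sim <- simulate_counts(n_genes = 80, n_samples_per_group = c(5, 5),
                         module_sizes = c(30), rho = 0.9, seed = 7)
  x <- log_normalize(sim$counts)
  net <- build_network(x, 6)
  ed <- export_edges(net, tom_threshold = 0.2)
  expect_true(all(ed$tom > 0.2))
  i <- match(ed$gene1[1], net$genes); j <- match(ed$gene2[1], net$genes)
  expect_equal(ed$tom[1], net$tom[i, j])
})
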